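test_that("noiseless expectation-valued ratios recover the generating point", {
  truth <- dfe_model("fixed", gamma = -5)
  r <- noiseless_ratios(truth, rho = 0.35, n = 50)
  grid <- build_grid(50, folded = TRUE)
  fit <- sfr_fit(r, "fixed", grid = grid, n_starts = 2, seed = 1)
  expect_equal(fit$rho_hat, 0.35, tolerance = 1e-3)
  expect_equal(fit$model$params$gamma, -5, tolerance = 1e-2)
  expect_true(fit$converged)
})

test_that("neutral simulated pairs give rho near 1 and gamma near 0", {
  cfg <- sim_config(n = 100, theta = 500, rho = 1,
                    model = dfe_model("fixed", gamma = 0),
                    folded = TRUE, reps = 5, seed = 31)
  grid <- build_grid(100, folded = TRUE)
  pairs <- simulate_pair(cfg)
  fits <- lapply(seq_along(pairs), function(k) {
    r <- suppressWarnings(make_ratios(pairs[[k]]$selected,
                                      pairs[[k]]$neutral))
    sfr_fit(r, "fixed", grid = grid, n_starts = 2, seed = k)
  })
  rho <- vapply(fits, `[[`, 0, "rho_hat")
  gam <- vapply(fits, function(f) f$model$params$gamma, 0)
  expect_lt(abs(mean(rho) - 1), 0.05)
  expect_lt(abs(mean(gam)), 0.5)
})

test_that("fixing rho drops one parameter and keeps recovery", {
  truth <- dfe_model("fixed", gamma = -5)
  r <- noiseless_ratios(truth, rho = 0.35, n = 50)
  grid <- build_grid(50, folded = TRUE)
  free <- sfr_fit(r, "fixed", grid = grid, n_starts = 2, seed = 1)
  fixed <- sfr_fit_fixed_rho(r, "fixed", rho_fixed = 0.35, grid = grid,
                             n_starts = 2, seed = 1)
  expect_equal(fixed$K, free$K - 1)
  expect_true(fixed$rho_fixed)
  expect_equal(fixed$model$params$gamma, -5, tolerance = 1e-2)
  # a badly wrong fixed rho still converges, with biased gamma
  wrong <- sfr_fit_fixed_rho(r, "fixed", rho_fixed = 3.5, grid = grid,
                             n_starts = 2, seed = 1)
  expect_true(abs(wrong$model$params$gamma - (-5)) > 0.5)
})

test_that("the LRT rejects strong selection and never prefers the null", {
  grid <- build_grid(100, folded = TRUE)
  cfg <- sim_config(n = 100, theta = 500, rho = 1,
                    model = dfe_model("fixed", gamma = -20),
                    folded = TRUE, seed = 41)
  pr <- simulate_pair(cfg)
  r <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
  lrt <- lrt_neutral(r, grid = grid, seed = 41)
  expect_lt(lrt$p_value, 1e-3)
  expect_true(all(lrt$reject_at))
  expect_gte(lrt$alt_fit$loglik, lrt$null_loglik)
  expect_gte(lrt$stat, 0)
})

test_that("lambda estimation follows rho_hat * Y / X", {
  expect_equal(estimate_lambda(0.35, X = 20, Y = 100), 1.75)
  expect_equal(estimate_lambda(20 / 100, X = 20, Y = 100), 1)
  expect_equal(estimate_lambda(0.42, X = 77, Y = 77), 0.42)
  expect_error(estimate_lambda(0.35, 0, 10), "positive")
})

test_that("profile intervals bracket the estimate and shrink with data", {
  truth <- dfe_model("fixed", gamma = -4)
  grid <- build_grid(60, folded = TRUE)
  mk <- function(theta, seed) {
    cfg <- sim_config(n = 60, theta = theta, rho = 0.5, model = truth,
                      folded = TRUE, seed = seed)
    pr <- simulate_pair(cfg)
    suppressWarnings(make_ratios(pr$selected, pr$neutral))
  }
  f_small <- sfr_fit(mk(2000, 5), "fixed", grid = grid, n_starts = 2, seed = 5)
  f_big <- sfr_fit(mk(20000, 6), "fixed", grid = grid, n_starts = 2, seed = 6)
  ci_small <- profile_ci(f_small, "rho")
  ci_big <- profile_ci(f_big, "rho")
  expect_true(ci_small[1] < f_small$rho_hat && f_small$rho_hat < ci_small[2])
  expect_true(ci_big[1] < f_big$rho_hat && f_big$rho_hat < ci_big[2])
  expect_lt(diff(ci_big), diff(ci_small))
  expect_error(profile_ci(f_small, "nonsense"), "unknown parameter")
})

test_that("model comparison ranks by AIC and rejects mixed data", {
  truth <- dfe_model("lognormal", mu = 1.5, sigma = 1)
  cfg <- sim_config(n = 50, theta = 3000, rho = 0.5, model = truth,
                    folded = TRUE, seed = 77)
  pr <- simulate_pair(cfg)
  r <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
  grid <- build_grid(50, folded = TRUE)
  f1 <- sfr_fit(r, "lognormal", grid = grid, n_starts = 2, seed = 1)
  f2 <- sfr_fit(r, "fixed", grid = grid, n_starts = 2, seed = 1)
  tab <- compare_models(list(f1, f2))
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$aic) >= 0))
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(nrow(compare_models(list(f1))), 1)

  other <- noiseless_ratios(truth, 0.5, 50)
  f3 <- sfr_fit(other, "fixed", grid = grid, n_starts = 2, seed = 1)
  expect_error(compare_models(list(f1, f3)), "different ratio spectra")
})

test_that("a point mass at zero is recovered and favored when genuine", {
  truth <- dfe_model("lognormal", mu = 2, sigma = 1, max = 1, p_plus = 0.3)
  r <- noiseless_ratios(truth, rho = 0.5, n = 50)
  grid <- build_grid(50, folded = TRUE)
  f <- sfr_fit(r, "lognormal", point_mass = TRUE, grid = grid,
               n_starts = 3, seed = 2)
  expect_equal(f$K, 4)
  expect_equal(f$rho_hat, 0.5, tolerance = 1e-3)
  expect_equal(f$model$params$mu, 2, tolerance = 1e-3)
  expect_equal(f$model$p_plus, 0.3, tolerance = 1e-3)
  ci <- profile_ci(f, "p_plus")
  expect_true(ci[1] <= f$model$p_plus && f$model$p_plus <= ci[2])
  # the pure lognormal cannot match the mixture: the mixture ranks first
  pure <- sfr_fit(r, "lognormal", grid = grid, n_starts = 3, seed = 2)
  tab <- compare_models(list(f, pure))
  expect_equal(tab$dfe[1], "lognormal p+")
  expect_gt(tab$delta_aic[2], 2)
})

test_that("aic and lambda identities hold on every fit", {
  truth <- dfe_model("fixed", gamma = -2)
  r <- noiseless_ratios(truth, rho = 0.8, n = 30)
  grid <- build_grid(30, folded = TRUE)
  f <- sfr_fit(r, "fixed", grid = grid, n_starts = 2, seed = 3)
  expect_equal(f$aic, 2 * f$K - 2 * f$loglik)
  expect_equal(f$lambda_hat, f$rho_hat * r$Y / r$X)
  expect_equal(f$mean_2Ns, dfe_mean(f$model))
})
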