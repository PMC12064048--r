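test_that("the ratio density normalizes and peaks near beta", {
  for (beta in c(0.2, 1, 5)) for (delta in c(0.01, 0.1)) {
    # integrate in two pieces split at the mode so the adaptive rule
    # cannot miss a narrow peak
    mass <- integrate(ratio_density, -Inf, beta, beta = beta,
                      delta = delta, rel.tol = 1e-8)$value +
      integrate(ratio_density, beta, Inf, beta = beta, delta = delta,
                rel.tol = 1e-8)$value
    expect_equal(mass, 1, tolerance = 1e-4)
    zg <- seq(beta * 0.8, beta * 1.2, length.out = 2001)
    mode <- zg[which.max(ratio_density(zg, beta, delta))]
    expect_equal(mode, beta, tolerance = 0.05 * beta + 3 * delta)
  }
  expect_error(ratio_density(1, -1, 0.1), "positive")
})

test_that("the ratio density matches Monte-Carlo ratios of gaussians", {
  beta <- 0.7; delta <- 0.05
  M <- 1 / delta^2          # gaussian pair convention: denominator mean M
  set.seed(3)
  z <- rnorm(2e5, beta * M, sqrt(beta * M)) / rnorm(2e5, M, sqrt(M))
  ks <- ks_against_density(z, function(g) ratio_density(g, beta, delta),
                           0.2, 1.4)
  expect_lt(ks, 0.02)
})

test_that("as delta -> 0 the ratio density becomes gaussian with mean beta", {
  beta <- 0.6; delta <- 1e-3
  z <- seq(beta - 6 * delta, beta + 6 * delta, length.out = 301)
  sdz <- delta * sqrt(beta * (1 + beta))
  expect_lt(max(abs(ratio_density(z, beta, delta) - dnorm(z, beta, sdz))) *
              sdz, 0.01)
})

test_that("theta integration: mean-value bounds and self-convergence", {
  grid <- build_grid(10, nodes = 201)
  m <- dfe_model("fixed", gamma = -2)
  th <- 800
  Fg <- dfe_bin_expectations(grid, m)
  for (i in c(1, 4, 8)) {
    z <- 0.4
    p24 <- integrated_ratio_density(z, i, m, 0.5, th, grid, G = 24)
    p96 <- integrated_ratio_density(z, i, m, 0.5, th, grid, G = 96)
    expect_lt(abs(p24 / p96 - 1), 1e-4)
    beta <- 0.5 * Fg[i] / grid$N[i]
    thetas <- exp(seq(log(th / 10), log(th * 10), length.out = 25))
    dens <- vapply(thetas, function(t)
      ratio_density(z, beta, 1 / sqrt(grid$N[i] * t / 2)), 0)
    expect_gte(p24, min(dens)); expect_lte(p24, max(dens))
  }
})

test_that("log-likelihood sums over valid bins only and stays finite", {
  sel <- sfs(c(120, 40, 0, 20), 5)
  neu <- sfs(c(200, 100, 0, 60), 5)
  r <- suppressWarnings(make_ratios(sel, neu))
  grid <- build_grid(5, nodes = 101)
  m <- dfe_model("fixed", gamma = -1)
  ll <- sfr_loglik(r, m, 0.6, grid)
  expect_true(is.finite(ll))
  # manual sum over the three valid bins
  Fg <- dfe_bin_expectations(grid, m)
  manual <- sum(vapply(which(r$valid_mask), function(i)
    log(integrated_ratio_density(r$z[i], i, m, 0.6, r$theta_hat, grid)), 0))
  expect_equal(ll, manual, tolerance = 1e-12)
  expect_error(sfr_loglik(r, m, 0.6, build_grid(6, nodes = 101)), "match")
})

test_that("doubling all counts changes the likelihood only through theta_hat", {
  sel <- sfs(c(300, 150, 80), 4)
  neu <- sfs(c(500, 260, 130), 4)
  r1 <- make_ratios(sel, neu)
  r2 <- make_ratios(sfs(sel$counts * 2, 4), sfs(neu$counts * 2, 4))
  expect_equal(r2$z, r1$z)
  expect_equal(r2$theta_hat, 2 * r1$theta_hat)
  grid <- build_grid(4, nodes = 101)
  m <- dfe_model("fixed", gamma = -1)
  # same ratios evaluated with the doubled theta_hat reproduce r2's logL
  r1_mod <- r1; r1_mod$theta_hat <- r2$theta_hat
  expect_equal(sfr_loglik(r2, m, 0.6, grid), sfr_loglik(r1_mod, m, 0.6, grid))
})

test_that("likelihood surface is continuous over a (rho, gamma) slice", {
  cfg <- sim_config(n = 20, theta = 500, rho = 0.5,
                    model = dfe_model("fixed", gamma = -3),
                    folded = TRUE, seed = 13)
  pr <- simulate_pair(cfg)
  r <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
  grid <- build_grid(20, folded = TRUE, nodes = 201)
  lls <- outer(seq(0.1, 2, length.out = 20),
               seq(-20, 0.9, length.out = 20),
               Vectorize(function(rho, g)
                 sfr_loglik(r, dfe_model("fixed", gamma = g), rho, grid)))
  expect_true(all(is.finite(lls)))
})

test_that("Poisson PRF log-likelihood matches direct pmf evaluation", {
  grid <- build_grid(4, nodes = 101)
  m <- dfe_model("fixed", gamma = 0)
  thetaS <- 60
  k <- c(31, 16, 9)
  x <- sfs(k, 4)
  expect_equal(prf_loglik(x, m, thetaS, grid),
               sum(dpois(k, (1 / (1:3)) * thetaS / 2, log = TRUE)))
  # empty spectrum
  expect_equal(prf_loglik(sfs(c(0, 0, 0), 4), m, thetaS, grid),
               -thetaS / 2 * sum(1 / (1:3)))
  # score equation: expectation-valued counts maximize at the true thetaS
  kexp <- (1 / (1:3)) * thetaS / 2
  opt <- optimize(function(t) -prf_loglik(sfs(kexp, 4), m, t, grid),
                  c(10, 300))
  expect_equal(opt$minimum, thetaS, tolerance = 1e-3)
})
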