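# The site-frequency-ratio likelihood.
#
# Per-bin selected and neutral counts are Poisson; both are approximated by
# gaussians with expectation equal to variance, so the observed ratio z_i
# follows the ratio-of-two-gaussians density (Diaz-Frances & Rubio 2013,
# Hinkley 1969) specialized to mean = variance. With expected ratio
# beta = rho * Fg_i / N_i and noise scale delta = (N_i * theta)^(-1/2), the
# matching gaussian pair is numerator N(beta*M, beta*M) over denominator
# N(M, M) with M = 1/delta^2 (the convention under which the specialized
# Hinkley density reproduces the beta/delta substitution; verified against
# Monte-Carlo ratios of gaussians in the test suite).

# vectorized over z (beta, delta recycled); log-space handling of the
# exp * erf product keeps the density finite down to delta ~ 1e-4
.ratio_density_core <- function(z, beta, delta) {
  M <- delta ^ -2
  a2 <- (z ^ 2 + beta) / (beta * M)      # a(z)^2
  b <- 1 + z
  cc <- M * (1 + beta)
  log_sxy <- log(M) + 0.5 * log(beta)    # log(sigma_x sigma_y)
  log_t2 <- -cc / 2 - log(a2) - log(pi) - log_sxy
  arg <- abs(b) / sqrt(2 * a2)
  erfc_v <- 2 * stats::pnorm(-sqrt(2) * arg)
  log_erf <- ifelse(erfc_v < 1e-12, -erfc_v, log1p(-erfc_v))
  log_t1 <- log(abs(b)) - 1.5 * log(a2) - 0.5 * log(2 * pi) - log_sxy +
    (b ^ 2 / (2 * a2) - cc / 2) + log_erf
  out <- exp(log_t2) + sign(b) * exp(log_t1)
  out[!is.finite(out)] <- 0
  pmax(out, 0)
}

#' Density of an observed selected/neutral count ratio
#'
#' The ratio-of-two-gaussians density specialized to
#' expectation = variance in both numerator and denominator, parameterized
#' by the expected ratio `beta` and the noise scale `delta`, where
#' `1/delta^2` is the mean (= variance) of the denominator gaussian.
#' The density integrates to 1 over the
#' whole real line, peaks near `beta`, and tends to a gaussian with mean
#' `beta` as `delta` tends to zero.
#'
#' @param z observed ratio(s); any real value.
#' @param beta expected ratio, > 0.
#' @param delta noise scale, > 0.
#' @return nonnegative density values (0 on extreme underflow).
#' @export
ratio_density <- function(z, beta, delta) {
  if (any(beta <= 0) || any(delta <= 0))
    stop("'beta' and 'delta' must be positive")
  .ratio_density_core(z, beta, delta)
}

# Noise-scale convention. For a candidate value of the neutral mutation
# parameter theta, the neutral count in bin i has expectation (and
# variance) N_i * theta / 2 -- the model's own count convention -- so the
# matching gaussian denominator has mean M = N_i * theta / 2 and the
# density's noise scale is delta = M^(-1/2) = (N_i * theta / 2)^(-1/2).
# (The alternative reading, denominator mean N_i * theta, makes the
# likelihood-ratio statistic anticonservative under the neutral null:
# rejection ~0.14 at the 0.05 chi-square cutoff versus ~0.05 for this
# convention, which the null-calibration acceptance check enforces.)
.delta_of <- function(N, theta) 1 / sqrt(N * theta / 2)

# log-spaced theta nodes spanning [theta_hat/10, 10*theta_hat] with
# normalized composite-Simpson weights (uniform prior on log theta);
# G is rounded up to an odd node count
.theta_rule <- function(theta_hat, G = 25L) {
  G <- as.integer(G)
  if (G %% 2L == 0L) G <- G + 1L
  lt <- seq(log(theta_hat / 10), log(theta_hat * 10), length.out = G)
  w <- rep(c(2, 4), length.out = G)
  w[1] <- 1; w[G] <- 1
  list(theta = exp(lt), w = w / sum(w))
}

#' Ratio density integrated over the mutation-rate nuisance
#'
#' The noise scale of [ratio_density()] depends on the neutral mutation
#' parameter theta, a nuisance. It is removed by numerical integration
#' against a uniform density on log theta spanning two orders of magnitude
#' around Watterson's estimate, `[theta_hat/10, 10*theta_hat]`, using a
#' fixed `G`-node composite Simpson rule (G rounded up to odd). The
#' two-decade window is wide enough to cover the generating theta even
#' though Watterson's estimator, under this package's count convention,
#' centers on theta/2.
#'
#' @param z observed ratio.
#' @param i bin index.
#' @param model a `dfe_model`.
#' @param rho mutation-rate ratio, > 0.
#' @param theta_hat Watterson's estimate of the neutral theta.
#' @param grid an `expectation_grid` matching the data layout.
#' @param G number of theta nodes (default 24).
#' @return the integrated density `p'(z | phi, rho)`.
#' @export
integrated_ratio_density <- function(z, i, model, rho, theta_hat, grid,
                                     G = 24L) {
  stopifnot(theta_hat > 0, rho > 0)
  Fg <- dfe_bin_expectations(grid, model)
  beta <- rho * Fg[i] / grid$N[i]
  tr <- .theta_rule(theta_hat, G)
  delta <- .delta_of(grid$N[i], tr$theta)
  sum(tr$w * .ratio_density_core(z, beta, delta))
}

# matrix of p'(z_i) for all bins at once: bins x theta nodes, vectorized
.pprime_bins <- function(z, beta, Nvec, theta_hat, G = 24L) {
  tr <- .theta_rule(theta_hat, G)
  nb <- length(z); ng <- length(tr$theta)
  Z <- matrix(z, nb, ng)
  B <- matrix(beta, nb, ng)
  D <- outer(Nvec, tr$theta, .delta_of)  # bins x theta nodes
  P <- .ratio_density_core(Z, B, D)
  as.vector(P %*% tr$w)
}

# bins entering the likelihood: the ratio must be defined (neutral count
# > 0, the valid_mask) AND the numerator gaussian approximation must not
# have failed outright (selected count > 0). A continuous ratio density
# cannot represent the atom at z = 0 that a zero Poisson numerator
# produces; left in, those bins reward beta -> 0 without bound (the
# density at z = 0 grows like beta^(-1/2)) and drag fitted selection
# strengths to the search boundary.
.active_bins <- function(ratios) {
  ratios$valid_mask & ratios$selected_counts > 0
}

#' Log-likelihood of a ratio spectrum under a DFE and rho
#'
#' Sums `log p'(z_i | phi, rho)` over the informative bins: those with a
#' nonzero neutral count (the ratio is undefined otherwise) and a nonzero
#' selected count (the continuous ratio density cannot represent the
#' discrete atom at z = 0, and such bins would otherwise reward
#' arbitrarily strong selection). For folded data the expected ratio uses
#' the folded expectations
#' `beta_i = rho (Fg_i + Fg_{n-i}) / (N_i + N_{n-i})` (central bin
#' unpaired), as encoded in a folded `expectation_grid`.
#'
#' @param ratios a `ratio_spectrum`.
#' @param model a `dfe_model`.
#' @param rho mutation-rate ratio, > 0.
#' @param grid an `expectation_grid` with the same `n` and `folded` flag.
#' @param G number of theta nodes for the nuisance integration.
#' @return a finite scalar log-likelihood.
#' @export
sfr_loglik <- function(ratios, model, rho, grid, G = 24L) {
  stopifnot(inherits(ratios, "ratio_spectrum"),
            inherits(grid, "expectation_grid"))
  if (grid$n != ratios$n || grid$folded != ratios$folded)
    stop("grid does not match the ratio spectrum's n/folded layout")
  if (rho <= 0) stop("'rho' must be positive")
  keep <- .active_bins(ratios)
  if (!any(keep)) stop("no informative bins: every bin has a zero count")
  Fg <- dfe_bin_expectations(grid, model)
  beta <- rho * Fg[keep] / grid$N[keep]
  pp <- .pprime_bins(ratios$z[keep], beta, grid$N[keep], ratios$theta_hat, G)
  sum(log(pmax(pp, 1e-300)))
}

#' Classic Poisson random field log-likelihood of an SFS
#'
#' The Wright-Fisher PRF likelihood used for comparison with the ratio
#' likelihood: per-bin counts `k_i` are independent Poisson with mean
#' `Fg_i * thetaS / 2`. Real-valued counts are accepted (the factorial
#' uses the log-gamma function).
#'
#' @param counts an `sfs` of selected counts.
#' @param model a `dfe_model`.
#' @param thetaS selected-class mutation parameter, > 0.
#' @param grid an `expectation_grid` matching the SFS layout.
#' @return the log-likelihood.
#' @export
prf_loglik <- function(counts, model, thetaS, grid) {
  stopifnot(inherits(counts, "sfs"), inherits(grid, "expectation_grid"))
  if (grid$n != counts$n || grid$folded != counts$folded)
    stop("grid does not match the SFS layout")
  if (thetaS <= 0) stop("'thetaS' must be positive")
  k <- counts$counts
  mu <- dfe_bin_expectations(grid, model) * thetaS / 2
  sum(k * log(mu) - mu - lgamma(k + 1))
}
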