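# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths (brute-force enumeration, dense trapezoid
# quadrature, closed forms) so that agreement is evidence, not tautology.

# Brute-force hypergeometric projection: enumerate every m-subset of the n
# chromosomes and tabulate derived counts. Feasible for n <= 10.
brute_project <- function(counts, n, m) {
  out <- numeric(m - 1L)
  subsets <- utils::combn(n, m)
  for (i in seq_len(n - 1L)) {
    if (counts[i] == 0) next
    # chromosomes 1..i carry the derived allele
    for (s in seq_len(ncol(subsets))) {
      j <- sum(subsets[, s] <= i)
      if (j >= 1 && j <= m - 1)
        out[j] <- out[j] + counts[i] / ncol(subsets)
    }
  }
  out
}

# Dense-trapezoid evaluation of the bin-expectation integral
trapezoid_binexp <- function(gamma, i, n, points = 1e6) {
  x <- seq(1e-9, 1 - 1e-9, length.out = points)
  r <- if (gamma == 0) 1 - x else if (gamma < 0) {
    exp(2 * gamma * x) * expm1(2 * gamma * (1 - x)) / expm1(2 * gamma)
  } else {
    expm1(-2 * gamma * (1 - x)) / expm1(-2 * gamma)
  }
  f <- r * exp(lchoose(n, i) + (i - 1) * log(x) + (n - i - 1) * log(1 - x))
  sum((f[-1] + f[-length(f)]) / 2) * (x[2] - x[1])
}

# Direct adaptive quadrature of the DFE-integrated expectation, on the
# log(m - gamma) scale, with the package's fixed-gamma integrals evaluated
# per point (slow; use on small n only)
direct_dfe_binexp <- function(model, n, i) {
  m <- model$max
  stats::integrate(function(u) {
    x <- exp(u)
    d <- dfe_pdf(model, m - x)
    d * x * vapply(m - x, function(g) bin_expectation(g, i, n), 0)
  }, log(1e-9), log(2e5), rel.tol = 1e-10, subdivisions = 800)$value
}

# Closed-form unnormalized truncated first moment of a lognormal variable
# (upper truncation at U): E[X; X <= U] = exp(mu + s^2/2) Phi((ln U - mu - s^2)/s)
lnorm_trunc_moment <- function(mu, s, U) {
  exp(mu + s^2 / 2) * stats::pnorm((log(U) - mu - s^2) / s)
}

# Empirical KS distance between draws and a density known on a fine grid
ks_against_density <- function(draws, dens_fn, lo, hi, grid_points = 4001) {
  g <- seq(lo, hi, length.out = grid_points)
  pdf <- dens_fn(g)
  cdf <- c(0, cumsum((pdf[-1] + pdf[-length(pdf)]) / 2 * diff(g)))
  cdf <- cdf / cdf[length(cdf)]
  zs <- sort(draws[draws >= lo & draws <= hi])
  Fz <- stats::approx(g, cdf, zs)$y
  k <- length(zs)
  max(abs(Fz - seq_len(k) / k), abs(Fz - (seq_len(k) - 1) / k))
}

# Paired neutral/selected spectra whose ratio bins equal the model
# expectation exactly (no sampling noise); big counts make the nuisance
# noise scale delta negligible
noiseless_ratios <- function(model, rho, n, theta = 1e8, folded = TRUE) {
  grid <- build_grid(n, folded)
  Fg <- suppressWarnings(dfe_bin_expectations(grid, model))
  neu <- grid$N * theta / 2
  sel <- rho * Fg / grid$N * neu
  suppressWarnings(make_ratios(
    sfs(sel, n, folded = folded), sfs(neu, n, folded = folded)))
}
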