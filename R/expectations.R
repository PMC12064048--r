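# Wright-Fisher Poisson-random-field expectations.
#
# The per-bin expected SNP count for selection strength gamma = 2Ns is
#   F(gamma)_i = int_0^1 htilde(gamma, x) C(n,i) x^i (1-x)^(n-i) dx
# where htilde is the dimensionless sojourn density of derived alleles at
# population frequency x. The mutation-rate factor thetaS/2 is kept OUT of
# htilde so that F(0)_i = 1/i and the expected ratio beta = rho * F_i / N_i
# reduces to rho under neutrality; expected counts are F_i * thetaS / 2.

# relative sojourn factor r(gamma, x) = (1 - e^{-2g(1-x)}) / (1 - e^{-2g}),
# so htilde = r / (x (1 - x)). Stable for |gamma| up to 1e5: for g < 0 it is
# rewritten as e^{2gx} expm1(2g(1-x)) / expm1(2g); the neutral limit is 1 - x.
.sojourn_factor <- function(g, x) {
  if (abs(g) < 1e-12) return(1 - x)
  if (g < 0) exp(2 * g * x) * expm1(2 * g * (1 - x)) / expm1(2 * g)
  else expm1(-2 * g * (1 - x)) / expm1(-2 * g)
}

#' Dimensionless sojourn density of derived alleles
#'
#' The expected density of derived alleles at population frequency `x`
#' under selection strength `gamma = 2Ns`, with the mutation-rate factor
#' removed: `htilde(gamma, x) = (1 - e^{-2g(1-x)}) / ((1 - e^{-2g}) x (1-x))`.
#' The neutral limit (`gamma = 0`) is `1/x`. Evaluation is numerically
#' stable for `|gamma|` up to `1e5` via `expm1` and a log-space rewriting
#' on the negative side.
#'
#' @param gamma selection strength 2Ns (scalar).
#' @param x population frequency, in (0, 1); may be a vector.
#' @return nonnegative density values.
#' @export
sojourn_density <- function(gamma, x) {
  if (any(x <= 0 | x >= 1)) stop("'x' must lie strictly within (0, 1)")
  .sojourn_factor(gamma, x) / (x * (1 - x))
}

# 24-point Gauss-Legendre base rule on [0, 1], computed once
.gl_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gl <- pracma::gaussLegendre(24, 0, 1)
      cache <<- gl
    }
    cache
  }
})

# All unfolded bin expectations F(gamma)_i, i = 1..n-1, by composite
# Gauss-Legendre quadrature. The integrand C(n,i) x^(i-1) (1-x)^(n-i-1) r
# is smooth and bounded; for strongly deleterious gamma the factor
# e^{2 gamma x} forms a boundary layer of width ~ 1/(2|gamma|) at x = 0,
# resolved by geometrically refined panels.
.binexp_all <- function(gamma, n, panels_scale = 1) {
  if (gamma < -5) {
    w0 <- min(0.5, 1 / (2 * abs(gamma)))
    bp <- unique(pmin(c(0, w0 * 2 ^ (0:ceiling(log2(1 / w0))), 1), 1))
  } else {
    bp <- seq(0, 1, length.out = 9)
  }
  if (panels_scale > 1) {  # refinement used in self-convergence checks
    bp <- sort(unique(c(bp, (bp[-1] + bp[-length(bp)]) / 2)))
  }
  gl <- .gl_base()
  widths <- diff(bp)
  xs <- as.vector(outer(gl$x, widths) + rep(bp[-length(bp)], each = 24))
  ws <- as.vector(outer(gl$w, widths))
  r <- .sojourn_factor(gamma, xs)
  i <- seq_len(n - 1L)
  K <- exp(outer(i - 1, log(xs)) + outer(n - i - 1, log(1 - xs)) +
             lchoose(n, i))
  v <- as.vector(K %*% (ws * r))
  pmax(v, 1e-300)  # guard underflow at extreme gamma: keep strictly positive
}

.fold_vec <- function(v, n) {
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half))
    out[i] <- if (i < n - i) v[i] + v[n - i] else v[i]
  out
}

#' Expected SNP count factor for one frequency bin
#'
#' `F(gamma)_i`, the dimensionless expectation factor for bin `i` at
#' selection strength `gamma`; the expected count of selected SNPs in the
#' bin is `F(gamma)_i * thetaS / 2`. At `gamma = 0` this equals the
#' neutral `1/i`. For a folded spectrum the paired bins are summed
#' (`F_i + F_{n-i}`), with the central bin `i = n/2` unpaired.
#'
#' @param gamma selection strength 2Ns.
#' @param i bin index (derived copies if unfolded, minor copies if folded).
#' @param n sample size in chromosomes.
#' @param folded logical.
#' @return a positive scalar.
#' @export
bin_expectation <- function(gamma, i, n, folded = FALSE) {
  half <- n %/% 2L
  hi <- if (folded) half else n - 1L
  if (length(i) != 1 || i < 1 || i > hi || i != round(i))
    stop(sprintf("bin index must be an integer in 1..%d", hi))
  v <- .binexp_all(gamma, n)
  if (!folded) v[i] else .fold_vec(v, n)[i]
}

#' Cached grid of bin expectations over selection strengths
#'
#' Precomputes `F(gamma)_i` for all bins on a deterministic quadrature grid
#' of `gamma` values so that DFE-integrated expectations reduce to a
#' weighted sum, re-evaluated cheaply for every candidate parameter vector
#' during fitting. Nodes are log-spaced in `|gamma|` on both sides of 0
#' (from `1e-3` out to the range limits) plus a node at 0, with trapezoid
#' weights on the resulting irregular grid.
#'
#' @param n sample size in chromosomes.
#' @param folded logical; build folded-bin expectations?
#' @param gamma_lo,gamma_hi grid range (defaults -1e5 and 1).
#' @param nodes total number of gamma nodes (>= 32; default 1501, at which
#'   DFE-integrated expectations agree with direct adaptive quadrature to
#'   about 1e-4 relative for the supported families).
#' @return an object of class `expectation_grid` with fields
#'   `gamma_nodes`, `gamma_weights`, `F` (bins x nodes), `N` (neutral
#'   expectations), `n`, `folded`.
#' @export
build_grid <- function(n, folded = FALSE, gamma_lo = -1e5, gamma_hi = 1,
                       nodes = 1501) {
  if (nodes < 32) stop("'nodes' must be at least 32")
  if (gamma_lo >= 0 || gamma_hi <= 0)
    stop("grid must straddle gamma = 0")
  inner <- 1e-3
  l_neg <- log10(abs(gamma_lo)) - log10(inner)
  l_pos <- log10(gamma_hi) - log10(inner)
  n_neg <- base::max(16L, round((nodes - 1L) * l_neg / (l_neg + l_pos)))
  n_pos <- base::max(16L, nodes - 1L - n_neg)
  g_neg <- -10 ^ seq(log10(abs(gamma_lo)), log10(inner), length.out = n_neg)
  g_pos <- 10 ^ seq(log10(inner), log10(gamma_hi), length.out = n_pos)
  gam <- sort(unique(c(g_neg, 0, g_pos)))
  # trapezoid weights built per side of zero: the inner window
  # (-inner, inner) is excluded from the quadrature and handled
  # analytically at integration time (DFE densities may have an
  # integrable singularity at their support maximum, e.g. the gamma
  # family with shape < 1), with F ~ N across the window
  trap <- function(g) {
    if (length(g) < 2) return(rep(0, length(g)))
    d <- diff(g)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  }
  j0 <- which(gam == 0)
  w <- numeric(length(gam))
  w[seq_len(j0 - 1L)] <- trap(gam[seq_len(j0 - 1L)])
  w[(j0 + 1L):length(gam)] <- trap(gam[(j0 + 1L):length(gam)])
  i_un <- seq_len(n - 1L)
  Fm <- vapply(gam, .binexp_all, numeric(n - 1L), n = n)
  N <- 1 / i_un
  if (folded) {
    Fm <- apply(Fm, 2, .fold_vec, n = n)
    if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1L)
    N <- .fold_vec(N, n)
  }
  structure(list(n = as.integer(n), folded = isTRUE(folded),
                 gamma_nodes = gam, gamma_weights = w,
                 F = Fm, N = N, inner = inner,
                 gamma_lo = gamma_lo, gamma_hi = gamma_hi),
            class = "expectation_grid")
}

#' @export
print.expectation_grid <- function(x, ...) {
  cat(sprintf(
    "Expectation grid: n=%d, %s, %d bins, %d gamma nodes in [%g, %g]\n",
    x$n, if (x$folded) "folded" else "unfolded", nrow(x$F),
    length(x$gamma_nodes), x$gamma_lo, x$gamma_hi))
  invisible(x)
}

#' DFE-integrated bin expectations
#'
#' Integrates the fixed-`gamma` expectations over a DFE:
#' `Fg_i = int g(gamma; phi) F(gamma)_i dgamma`, evaluated as a weighted
#' sum over the grid nodes for continuous families, plus the point-mass
#' contribution `p_plus * N_i` (a neutral atom at `gamma = 0` contributes
#' the neutral expectation). For the `fixed` family the delta function is
#' evaluated exactly via [bin_expectation()] rather than on the grid.
#' A warning is issued when the continuous part places more than `1e-6`
#' of its mass outside the grid range.
#'
#' @param grid an `expectation_grid`.
#' @param model a `dfe_model` with support within the grid range.
#' @return vector of strictly positive expectations, one per bin.
#' @export
dfe_bin_expectations <- function(grid, model) {
  stopifnot(inherits(grid, "expectation_grid"), inherits(model, "dfe_model"))
  nb <- nrow(grid$F)
  if (model$family == "fixed") {
    g <- model$params$gamma
    v <- .binexp_all(g, grid$n)
    if (grid$folded) v <- .fold_vec(v, grid$n)
    return(model$p_minus * v + model$p_plus * grid$N)
  }
  out_mass <- .mass_outside(model, grid$gamma_lo, grid$gamma_hi)
  if (out_mass > 1e-6)
    warning(sprintf(
      "DFE places %.3g of its continuous mass outside the grid range [%g, %g]",
      out_mass, grid$gamma_lo, grid$gamma_hi))
  gdens <- dfe_pdf(model, grid$gamma_nodes)  # already scaled by p_minus
  # continuous mass in the excluded inner window contributes ~ N_i
  w_mass <- .mass_window(model, -grid$inner, grid$inner)
  Fg <- as.vector(grid$F %*% (grid$gamma_weights * gdens)) +
    (model$p_plus + model$p_minus * w_mass) * grid$N
  pmax(Fg, 1e-300)
}

# analytic continuous-part mass inside (lo, hi), unscaled CDF difference
.mass_window <- function(model, lo, hi) {
  p <- model$params
  cdf_above <- function(g) {  # P(gamma > g) of the continuous part / p_minus
    switch(model$family,
      lognormal = if (g >= model$max) 0 else
        stats::plnorm(model$max - g, p$mu, p$sigma),
      gamma = if (g >= model$max) 0 else
        stats::pgamma(model$max - g, shape = p$shape, scale = p$scale),
      normal = stats::pnorm(g, p$norm_mean, p$norm_sd, lower.tail = FALSE),
      fixed = as.numeric(p$gamma > g))
  }
  base::max(cdf_above(lo) - cdf_above(hi), 0)
}

# analytic continuous-part mass outside [lo, hi], on the x = m - gamma scale
.mass_outside <- function(model, lo, hi) {
  p <- model$params
  switch(model$family,
    lognormal = stats::plnorm(model$max - lo, p$mu, p$sigma,
                              lower.tail = FALSE) +
      (if (model$max > hi) stats::plnorm(model$max - hi, p$mu, p$sigma) else 0),
    gamma = stats::pgamma(model$max - lo, shape = p$shape, scale = p$scale,
                          lower.tail = FALSE) +
      (if (model$max > hi) stats::pgamma(model$max - hi, shape = p$shape,
                                         scale = p$scale) else 0),
    normal = stats::pnorm(lo, p$norm_mean, p$norm_sd) +
      stats::pnorm(hi, p$norm_mean, p$norm_sd, lower.tail = FALSE),
    fixed = 0)
}
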