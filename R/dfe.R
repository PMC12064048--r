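#' Distribution of fitness effects (DFE) models for 2Ns
#'
#' Constructs a model for the population-scaled selection coefficient
#' `gamma = 2Ns` of new mutations. Continuous families are "inverted", i.e.
#' they extend to minus infinity with an upper support limit `m`
#' (`max`): for `lognormal`, `log(m - gamma)` is normal with parameters
#' `mu` and `sigma`; for `gamma`, `m - gamma` is gamma-distributed, given
#' either as (`mean`, `shape`) with `mean` the expectation of `gamma`
#' itself (so scale = `(m - mean)/shape`), or directly as (`shape`,
#' `scale`). The `normal` family is an ordinary gaussian on `gamma`, and
#' `fixed` is a single point value.
#'
#' Any model can carry a point mass `p_plus` at `gamma_plus` (default
#' location 0, i.e. strictly neutral mutations); the continuous part then
#' has weight `p_minus` (default `1 - p_plus`). Model fitting restricts
#' `p_plus` to at most 0.5 of the total density; the constructor accepts
#' the full `[0, 1]` range so that degenerate pure-point-mass models can be
#' built for testing identities.
#'
#' @param family one of `"lognormal"`, `"gamma"`, `"normal"`, `"fixed"`.
#' @param mu,sigma lognormal parameters of `log(m - gamma)`.
#' @param mean,shape,scale gamma-family parameters; give `mean` + `shape`
#'   or `shape` + `scale`.
#' @param norm_mean,norm_sd normal-family parameters.
#' @param gamma fixed-family point value of 2Ns.
#' @param max upper support limit `m` (default 1 for lognormal and normal
#'   is not truncated; default 0 for gamma).
#' @param p_plus point-mass weight, in `[0, 1]`.
#' @param gamma_plus point-mass location (default 0).
#' @param p_minus weight of the continuous part; defaults to
#'   `1 - p_plus`. Override only for partial mixtures whose weights do
#'   not sum to one (e.g. externally reported DFEs).
#' @return an object of class `dfe_model`.
#' @examples
#' dfe_model("lognormal", mu = 3, sigma = 1.2)
#' dfe_model("gamma", shape = 0.35, scale = 2111.2, max = 0)
#' dfe_model("fixed", gamma = -5)
#' @export
dfe_model <- function(family = c("lognormal", "gamma", "normal", "fixed"),
                      mu = NULL, sigma = NULL,
                      mean = NULL, shape = NULL, scale = NULL,
                      norm_mean = NULL, norm_sd = NULL,
                      gamma = NULL, max = NULL,
                      p_plus = 0, gamma_plus = 0, p_minus = NULL) {
  family <- match.arg(family)
  if (length(p_plus) != 1 || !is.finite(p_plus) || p_plus < 0 || p_plus > 1)
    stop("'p_plus' must be a single value in [0, 1]")
  if (is.null(p_minus)) p_minus <- 1 - p_plus
  if (p_minus < 0 || p_minus > 1) stop("'p_minus' must be in [0, 1]")
  params <- switch(family,
    lognormal = {
      if (is.null(max)) max <- 1
      if (is.null(mu) || is.null(sigma)) stop("lognormal needs 'mu' and 'sigma'")
      if (sigma <= 0) stop("'sigma' must be > 0")
      list(mu = mu, sigma = sigma)
    },
    gamma = {
      if (is.null(max)) max <- 0
      if (!is.null(mean) && !is.null(shape)) {
        if (mean >= max) stop("gamma 'mean' must be below 'max'")
        if (shape <= 0) stop("'shape' must be > 0")
        list(mean = mean, shape = shape, scale = (max - mean) / shape)
      } else if (!is.null(shape) && !is.null(scale)) {
        if (shape <= 0 || scale <= 0) stop("'shape' and 'scale' must be > 0")
        list(mean = max - shape * scale, shape = shape, scale = scale)
      } else stop("gamma needs ('mean','shape') or ('shape','scale')")
    },
    normal = {
      if (is.null(max)) max <- Inf
      if (is.null(norm_mean) || is.null(norm_sd))
        stop("normal needs 'norm_mean' and 'norm_sd'")
      if (norm_sd <= 0) stop("'norm_sd' must be > 0")
      list(norm_mean = norm_mean, norm_sd = norm_sd)
    },
    fixed = {
      if (is.null(gamma)) stop("fixed needs 'gamma'")
      if (is.null(max)) max <- Inf
      list(gamma = gamma)
    })
  structure(list(family = family, params = params, max = max,
                 p_plus = p_plus, gamma_plus = gamma_plus,
                 p_minus = p_minus),
            class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  pv <- paste(names(x$params), signif(unlist(x$params), 6),
              sep = "=", collapse = ", ")
  cat(sprintf("DFE model: %s(%s), max=%g", x$family, pv, x$max))
  if (x$p_plus > 0)
    cat(sprintf(", point mass %.4g at %g", x$p_plus, x$gamma_plus))
  cat("\n")
  invisible(x)
}

#' Continuous-part density of a DFE model
#'
#' Evaluates the continuous part of the 2Ns density, scaled by its mixture
#' weight (`p_minus`, by default `1 - p_plus`). The point mass is a
#' discrete atom and is never returned as a density value. For the
#' `fixed` family there is no continuous part and evaluation is an error.
#'
#' @param model a `dfe_model`.
#' @param gamma numeric vector of 2Ns values.
#' @return density values, zero above the support maximum.
#' @export
dfe_pdf <- function(model, gamma) {
  stopifnot(inherits(model, "dfe_model"))
  if (model$family == "fixed")
    stop("the fixed family is a point mass and has no continuous density")
  p <- model$params
  d <- switch(model$family,
    lognormal = ifelse(gamma < model$max,
                       stats::dlnorm(model$max - gamma, p$mu, p$sigma), 0),
    gamma = ifelse(gamma < model$max,
                   stats::dgamma(model$max - gamma, shape = p$shape,
                                 scale = p$scale), 0),
    normal = stats::dnorm(gamma, p$norm_mean, p$norm_sd))
  model$p_minus * d
}

#' Truncated-range expectation of 2Ns
#'
#' Integrates `gamma * pdf(gamma)` over `[lo, hi]` (the continuous part,
#' scaled by its mixture weight) WITHOUT renormalizing over the truncated
#' range, then adds point-mass contributions as weight times location.
#' For heavy-tailed DFEs the untruncated expectation can be orders of
#' magnitude larger than this truncated integral; reporting the
#' unnormalized truncated value is the convention used when summarizing
#' fitted DFEs over a finite 2Ns window.
#'
#' @param model a `dfe_model`.
#' @param lo,hi integration range for the continuous part
#'   (default `-1e5` to `1e-4`).
#' @return the truncated mean, a single number.
#' @export
dfe_mean <- function(model, lo = -1e5, hi = 1e-4) {
  stopifnot(inherits(model, "dfe_model"))
  if (lo >= hi) stop("'lo' must be below 'hi'")
  point <- model$p_plus * model$gamma_plus
  if (model$family == "fixed") {
    g <- model$params$gamma
    cont <- if (g >= lo && g <= hi) model$p_minus * g else 0
    return(cont + point)
  }
  # integrate on the x = m - gamma scale for the inverted families; split
  # the range at distribution quantiles so adaptive quadrature finds the
  # mass even when it is concentrated far from the endpoints
  p <- model$params
  if (model$family %in% c("lognormal", "gamma")) {
    m <- model$max
    xlo <- base::max(m - hi, 0)
    xhi <- m - lo
    qf <- if (model$family == "lognormal") {
      function(q) stats::qlnorm(q, p$mu, p$sigma)
    } else {
      function(q) stats::qgamma(q, shape = p$shape, scale = p$scale)
    }
    dens <- if (model$family == "lognormal") {
      function(x) stats::dlnorm(x, p$mu, p$sigma)
    } else {
      function(x) stats::dgamma(x, shape = p$shape, scale = p$scale)
    }
    cuts <- sort(unique(pmin(pmax(
      c(xlo, qf(c(0.001, 0.1, 0.5, 0.9, 0.999)), xhi), xlo), xhi)))
    val <- 0
    for (k in seq_len(length(cuts) - 1L)) {
      if (cuts[k + 1] <= cuts[k]) next
      val <- val + stats::integrate(function(x) (m - x) * dens(x),
                                    cuts[k], cuts[k + 1],
                                    rel.tol = 1e-9, abs.tol = 1e-12,
                                    subdivisions = 400L)$value
    }
    return(model$p_minus * val + point)
  }
  # normal family: direct closed-form truncated first moment
  mu <- p$norm_mean; s <- p$norm_sd
  za <- (lo - mu) / s; zb <- (hi - mu) / s
  cont <- mu * (stats::pnorm(zb) - stats::pnorm(za)) -
    s * (stats::dnorm(zb) - stats::dnorm(za))
  model$p_minus * cont + point
}

#' Draw 2Ns values from a DFE model
#'
#' Reproducible sampling given a seed: with probability `p_plus` a draw is
#' the point-mass location, otherwise it comes from the continuous part.
#' The caller's RNG state is preserved.
#'
#' @param model a `dfe_model`.
#' @param k number of draws.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return numeric vector of `k` values of 2Ns.
#' @export
dfe_sample <- function(model, k, seed = NULL) {
  stopifnot(inherits(model, "dfe_model"), k >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  p <- model$params
  atom <- stats::runif(k) < model$p_plus
  out <- rep(model$gamma_plus, k)
  nk <- sum(!atom)
  if (nk > 0) {
    out[!atom] <- switch(model$family,
      lognormal = model$max - stats::rlnorm(nk, p$mu, p$sigma),
      gamma = model$max - stats::rgamma(nk, shape = p$shape, scale = p$scale),
      normal = stats::rnorm(nk, p$norm_mean, p$norm_sd),
      fixed = rep(p$gamma, nk))
  }
  out
}

#' Parse a compact DFE model specification string
#'
#' Accepts strings such as `"lognormal:mu=3.0,sigma=1.2,max=1,pzero=0.05"`,
#' `"gamma:shape=0.35,scale=2111.2,max=0"`, `"normal:mean=-5,sd=2"` or
#' `"fixed:gamma=-10"`. `pzero` maps to the point-mass weight at zero.
#'
#' @param spec a specification string.
#' @return a `dfe_model`.
#' @export
parse_dfe_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  kv <- list()
  if (length(parts) > 1 && nzchar(parts[2])) {
    for (tok in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      eq <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(eq) != 2) stop("malformed DFE spec token: ", tok)
      kv[[eq[1]]] <- as.numeric(eq[2])
    }
  }
  args <- list(family = family)
  remap <- c(mu = "mu", sigma = "sigma", mean = "mean", shape = "shape",
             scale = "scale", sd = "norm_sd", gamma = "gamma",
             max = "max", pzero = "p_plus")
  for (nm in names(kv)) {
    key <- if (nm == "mean" && family == "normal") "norm_mean" else remap[[nm]]
    if (is.null(key)) stop("unknown DFE spec key: ", nm)
    args[[key]] <- kv[[nm]]
  }
  do.call(dfe_model, args)
}

#' Format a DFE model as a specification string
#' @param model a `dfe_model`.
#' @return a string in the `parse_dfe_spec` dialect.
#' @export
format_dfe_spec <- function(model) {
  p <- model$params
  core <- switch(model$family,
    lognormal = sprintf("mu=%.10g,sigma=%.10g,max=%.10g", p$mu, p$sigma, model$max),
    gamma = sprintf("shape=%.10g,scale=%.10g,max=%.10g", p$shape, p$scale, model$max),
    normal = sprintf("mean=%.10g,sd=%.10g", p$norm_mean, p$norm_sd),
    fixed = sprintf("gamma=%.10g", p$gamma))
  if (model$p_plus > 0) core <- paste0(core, sprintf(",pzero=%.10g", model$p_plus))
  paste0(model$family, ":", core)
}
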