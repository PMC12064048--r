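# Poisson-random-field simulator of paired selected/neutral spectra.
#
# Per-bin counts are independent Poisson draws around the model
# expectations a_i * N_i * theta / 2 (neutral) and
# a_i * Fg_i * rho * theta / 2 (selected), where the shared per-bin
# factors a_i stand in for non-selective distortions (demography, linked
# selection) common to both spectra; the ratio method's central claim is
# that such shared factors cancel. Named distortion generators provide
# qualitative expansion-like, bottleneck-like and smooth random shapes.

#' Simulation configuration
#'
#' @param n sample size in chromosomes.
#' @param theta neutral mutation parameter (> 0).
#' @param rho true mutation-rate ratio (> 0); the selected-class
#'   parameter is `thetaS = rho * theta`.
#' @param model a `dfe_model` describing the selected-class DFE (use
#'   `dfe_model("fixed", gamma = 0)` for neutral pairs).
#' @param folded fold the simulated spectra after drawing?
#' @param distortion `"none"`, `"smooth"` (seeded correlated log-gaussian),
#'   `"expansion"` (factors enriched toward singletons) or
#'   `"bottleneck"` (factors depleted at intermediate frequencies).
#' @param reps replicate count.
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n, theta, rho, model, folded = TRUE,
                       distortion = c("none", "smooth", "expansion",
                                      "bottleneck"),
                       reps = 1L, seed = 1L) {
  distortion <- match.arg(distortion)
  stopifnot(n >= 2, theta > 0, rho > 0, inherits(model, "dfe_model"),
            reps >= 1)
  structure(list(n = as.integer(n), theta = theta, rho = rho, model = model,
                 folded = isTRUE(folded), distortion = distortion,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-bin distortion factors
#'
#' Generates the shared positive multipliers `a_i` for the `n - 1`
#' unfolded bins. `"expansion"` inflates rare-allele bins, as an excess of
#' recent mutations would; `"bottleneck"` depletes intermediate
#' frequencies; `"smooth"` draws a correlated log-gaussian profile
#' (values within [0.2, 5]).
#'
#' @param kind distortion name.
#' @param n sample size.
#' @param seed seed used by the `"smooth"` generator.
#' @return positive numeric vector of length `n - 1`.
#' @export
distortion_factors <- function(kind, n, seed = 1L) {
  i <- seq_len(n - 1L)
  switch(kind,
    none = rep(1, n - 1L),
    expansion = 0.5 + 2.5 * exp(-3 * (i - 1) / base::max(n - 2L, 1L)),
    bottleneck = 1 - 0.6 * exp(-((i - n / 2) / (n / 6)) ^ 2),
    smooth = {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      zr <- stats::rnorm(n - 1L)
      w <- base::max(3L, round((n - 1L) / 10))
      z <- stats::filter(zr, rep(1 / w, w), sides = 2, circular = TRUE)
      pmin(pmax(exp(0.4 * as.numeric(z) / stats::sd(as.numeric(z))), 0.2), 5)
    },
    stop("unknown distortion kind: ", kind))
}

# unfolded expectation vectors for a config (before distortion)
.sim_means <- function(config, grid_unfolded = NULL) {
  n <- config$n
  if (config$model$family == "fixed" && config$model$p_plus == 0) {
    Fg <- .binexp_all(config$model$params$gamma, n)
  } else {
    if (is.null(grid_unfolded))
      grid_unfolded <- build_grid(n, folded = FALSE)
    Fg <- dfe_bin_expectations(grid_unfolded, config$model)
  }
  Nv <- 1 / seq_len(n - 1L)
  list(neutral = Nv * config$theta / 2,
       selected = Fg * config$rho * config$theta / 2)
}

#' Simulate a paired selected/neutral SFS
#'
#' Draws independent Poisson counts for every unfolded bin around the
#' distorted expectations, then folds if requested. With `reps > 1` a
#' list of pairs is returned; replicate r uses the deterministic seed
#' `seed + r - 1`.
#'
#' @param config a `sim_config`.
#' @param grid_unfolded optional precomputed unfolded `expectation_grid`
#'   for `config$n` (reused across replicates for continuous DFEs).
#' @return a list with elements `selected` and `neutral` (`sfs` objects),
#'   or a list of such pairs when `config$reps > 1`.
#' @export
simulate_pair <- function(config, grid_unfolded = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mu <- .sim_means(config, grid_unfolded)
  a <- distortion_factors(config$distortion, config$n, config$seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  one <- function(r) {
    set.seed(config$seed + r - 1L)
    sel <- stats::rpois(config$n - 1L, a * mu$selected)
    neu <- stats::rpois(config$n - 1L, a * mu$neutral)
    s <- sfs(sel, config$n, label = "simulated selected")
    u <- sfs(neu, config$n, label = "simulated neutral")
    if (config$folded) {
      s <- fold_sfs(s); u <- fold_sfs(u)
    }
    list(selected = s, neutral = u)
  }
  if (config$reps == 1L) one(1L) else lapply(seq_len(config$reps), one)
}

#' Power of the selection LRT over a grid of selection strengths
#'
#' For each fixed 2Ns value, simulates `reps` paired spectra and records
#' the fraction of replicates in which [lrt_neutral()] rejects at each
#' significance level.
#'
#' @param gammas vector of 2Ns values (0 gives the size of the test).
#' @param config base `sim_config`; its `model` is replaced by each
#'   fixed-gamma model in turn.
#' @param alphas significance levels.
#' @param reps replicates per gamma value.
#' @return a data.frame with one row per (gamma, alpha).
#' @export
power_curve <- function(gammas, config, alphas = c(0.05, 0.01, 0.001),
                        reps = 100L) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  grid <- build_grid(config$n, config$folded)
  rows <- list()
  for (g in gammas) {
    cfg <- config
    cfg$model <- dfe_model("fixed", gamma = g)
    cfg$reps <- as.integer(reps)
    cfg$seed <- config$seed + round(1000 * abs(g))
    pairs <- simulate_pair(cfg)
    pvals <- vapply(pairs, function(pr) {
      r <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
      lrt_neutral(r, grid = grid, n_starts = 2, seed = cfg$seed)$p_value
    }, 0)
    for (a in alphas)
      rows[[length(rows) + 1L]] <-
        data.frame(gamma = g, alpha = a, power = base::mean(pvals < a),
                   reps = reps)
  }
  do.call(rbind, rows)
}

#' ROC analysis of the selection LRT statistic
#'
#' Simulates null replicates (2Ns = 0) and alternative replicates with
#' 2Ns drawn uniformly from `gamma_range`, scores each by the LRT
#' statistic, and returns the ROC curve with its trapezoid AUC.
#'
#' @param config base `sim_config` (its model is overridden).
#' @param n_null,n_alt replicate counts for the two arms.
#' @param gamma_range range of the uniform alternative draw
#'   (default `c(-100, 1)`).
#' @return a list with `roc` (data.frame of FPR/TPR), `auc`, and the
#'   statistic vectors.
#' @export
roc_analysis <- function(config, n_null = 100L, n_alt = 100L,
                         gamma_range = c(-100, 1)) {
  stopifnot(inherits(config, "sim_config"))
  grid <- build_grid(config$n, config$folded)
  stat_of <- function(cfg) {
    pr <- simulate_pair(cfg)
    r <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
    lrt_neutral(r, grid = grid, n_starts = 2, seed = cfg$seed)$stat
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  galt <- stats::runif(n_alt, gamma_range[1], gamma_range[2])
  s_null <- vapply(seq_len(n_null), function(r) {
    cfg <- config; cfg$model <- dfe_model("fixed", gamma = 0)
    cfg$reps <- 1L; cfg$seed <- config$seed + r
    stat_of(cfg)
  }, 0)
  s_alt <- vapply(seq_len(n_alt), function(r) {
    cfg <- config; cfg$model <- dfe_model("fixed", gamma = galt[r])
    cfg$reps <- 1L; cfg$seed <- config$seed + n_null + r
    stat_of(cfg)
  }, 0)
  thr <- sort(unique(c(-Inf, s_null, s_alt, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) base::mean(s_alt >= t), 0)
  fpr <- vapply(thr, function(t) base::mean(s_null >= t), 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       stat_null = s_null, stat_alt = s_alt)
}

#' Null calibration of the LRT statistic against chi-square(1)
#'
#' Simulates `reps` neutral paired spectra, computes the LRT statistic
#' for each, and compares its empirical distribution with the chi-square
#' distribution with 1 df: Kolmogorov-Smirnov distance and tail rejection
#' fractions at the usual cutoffs.
#'
#' @param config a `sim_config` (the model is forced to fixed 2Ns = 0).
#' @param reps replicate count (>= 200 recommended).
#' @param alphas significance levels for the tail check.
#' @return a list with `stats` (the 2*LLR values), `ks_distance`,
#'   `rejection` (named by alpha) and `ecdf_table`.
#' @export
null_calibration <- function(config, reps = 500L,
                             alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$model <- dfe_model("fixed", gamma = 0)
  cfg$rho <- config$rho
  cfg$reps <- as.integer(reps)
  grid <- build_grid(cfg$n, cfg$folded)
  grid_un <- NULL
  pairs <- simulate_pair(cfg)
  stats_v <- vapply(seq_along(pairs), function(r) {
    pr <- pairs[[r]]
    rt <- suppressWarnings(make_ratios(pr$selected, pr$neutral))
    lrt_neutral(rt, grid = grid, n_starts = 2, seed = cfg$seed + r)$stat
  }, 0)
  emp <- stats::ecdf(stats_v)
  qs <- sort(stats_v)
  ks <- base::max(abs(emp(qs) - stats::pchisq(qs, 1)),
                  abs(emp(qs) - 1 / reps - stats::pchisq(qs, 1)))
  rej <- vapply(alphas, function(a)
    base::mean(stats_v > stats::qchisq(1 - a, 1)), 0)
  list(stats = stats_v, ks_distance = ks,
       rejection = stats::setNames(rej, alphas),
       ecdf_table = data.frame(stat = qs,
                               empirical = emp(qs),
                               chisq1 = stats::pchisq(qs, 1)))
}
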