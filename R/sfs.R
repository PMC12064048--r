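#' Site frequency spectrum container
#'
#' Builds an `sfs` object holding per-bin counts of polymorphic sites for a
#' sample of `n` chromosomes. Unfolded spectra are indexed by derived-allele
#' copies `i = 1..n-1`; folded spectra by minor-allele copies
#' `i = 1..floor(n/2)`. Counts may be real valued: hypergeometric projection
#' returns expected (fractional) counts, and all downstream likelihoods use a
#' gaussian approximation that does not require integers.
#'
#' @param counts numeric vector of per-bin site counts, finite and >= 0.
#' @param n sample size in chromosomes (integer >= 2).
#' @param folded logical; is `counts` indexed by minor-allele copies?
#' @param label free-text label carried through IO and reports.
#' @return an object of class `sfs`.
#' @examples
#' sfs(c(5, 3, 2), n = 4)
#' sfs(c(7, 3), n = 4, folded = TRUE)
#' @export
sfs <- function(counts, n, folded = FALSE, label = "") {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  n <- as.integer(n)
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  expected <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != expected)
    stop(sprintf("expected %d count bins for n=%d %s, got %d",
                 expected, n, if (folded) "folded" else "unfolded",
                 length(counts)))
  structure(list(counts = counts, n = n, folded = isTRUE(folded),
                 label = as.character(label)[1]),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("SFS: n=%d chromosomes, %s, %d bins, %.6g segregating sites\n",
              x$n, if (x$folded) "folded" else "unfolded",
              length(x$counts), sum(x$counts)))
  if (nzchar(x$label)) cat("label:", x$label, "\n")
  print(utils::head(x$counts, 12), ...)
  if (length(x$counts) > 12) cat("...\n")
  invisible(x)
}

#' Fold an unfolded SFS
#'
#' Collapses derived-allele bins to minor-allele bins: folded bin `i` gets
#' `counts[i] + counts[n-i]` for `i < n/2`; when `n` is even the central bin
#' `i = n/2` maps to itself and is not doubled. The total site count is
#' conserved exactly.
#'
#' @param x an unfolded `sfs`.
#' @return a folded `sfs`.
#' @examples
#' fold_sfs(sfs(c(5, 3, 2), n = 4))  # counts 7, 3
#' @export
fold_sfs <- function(x) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) stop("SFS is already folded")
  n <- x$n
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (i < n - i) x$counts[i] + x$counts[n - i] else x$counts[i]
  }
  sfs(out, n = n, folded = TRUE, label = x$label)
}

#' Project an SFS to a smaller sample size
#'
#' Expected hypergeometric down-projection: bin `j` of the target receives
#' `sum_i counts[i] * P(j of m | i of n)` where the kernel is the
#' hypergeometric probability of drawing `j` derived alleles in a subsample
#' of `m` chromosomes. Mass projected to the monomorphic classes `j = 0` and
#' `j = m` is discarded, so the output is real valued and its total is at
#' most the input total.
#'
#' @param x an unfolded `sfs`.
#' @param m target sample size, `2 <= m < n`.
#' @return an unfolded `sfs` with `m - 1` bins.
#' @export
project_sfs <- function(x, m) {
  stopifnot(inherits(x, "sfs"))
  if (x$folded) stop("projection requires an unfolded SFS")
  if (length(m) != 1L || !is.finite(m) || m != round(m) || m < 2)
    stop("'m' must be a single integer >= 2")
  if (m >= x$n) stop("target sample size 'm' must be smaller than n")
  n <- x$n
  out <- numeric(m - 1L)
  for (j in seq_len(m - 1L)) {
    i <- seq_len(n - 1L)
    # P(j of m | i of n): hypergeometric, choosing m of n chromosomes
    p <- exp(lchoose(i, j) + lchoose(n - i, m - j) - lchoose(n, m))
    out[j] <- sum(x$counts * p)
  }
  sfs(out, n = m, folded = FALSE, label = x$label)
}

#' Watterson's estimate of the population mutation rate
#'
#' Returns `theta_hat = S / a_n` with `S` the total number of segregating
#' sites and `a_n = sum_{i=1}^{n-1} 1/i`. The harmonic denominator depends
#' only on the sample size, so folded and unfolded storage of the same
#' spectrum give the same estimate.
#'
#' @param x an `sfs` with at least one segregating site.
#' @return the Watterson estimate, a positive number.
#' @export
watterson_theta <- function(x) {
  stopifnot(inherits(x, "sfs"))
  S <- sum(x$counts)
  if (S <= 0)
    stop("Watterson's theta undefined: no segregating sites")
  S / sum(1 / seq_len(x$n - 1L))
}

#' Per-bin selected/neutral count ratios
#'
#' Builds a `ratio_spectrum` from a selected and a neutral SFS sharing the
#' same sample size and folding. Ratio bins with a zero neutral count are
#' masked invalid (the ratio is undefined there and the gaussian
#' approximation to the Poisson count has already failed); the likelihood
#' skips masked bins. Watterson's theta is estimated from the neutral
#' spectrum, which carries the neutral mutation parameter.
#'
#' A warning reports the number of bins in which either count is below 10,
#' the rough threshold below which the gaussian approximation to a Poisson
#' count degrades.
#'
#' @param selected,neutral `sfs` objects with equal `n` and `folded`.
#' @return an object of class `ratio_spectrum` with fields `z`,
#'   `selected_counts`, `neutral_counts`, `n`, `folded`, `valid_mask`,
#'   `X`, `Y` (total selected/neutral sites) and `theta_hat`.
#' @export
make_ratios <- function(selected, neutral) {
  stopifnot(inherits(selected, "sfs"), inherits(neutral, "sfs"))
  if (selected$n != neutral$n)
    stop("selected and neutral SFS have different sample sizes")
  if (selected$folded != neutral$folded)
    stop("selected and neutral SFS have different folded flags")
  sc <- selected$counts
  nc <- neutral$counts
  valid <- nc > 0
  z <- rep(NA_real_, length(sc))
  z[valid] <- sc[valid] / nc[valid]
  low <- sum(sc < 10 | nc < 10)
  if (low > 0)
    warning(sprintf(paste0("%d bin(s) have a selected or neutral count ",
                           "below 10; the gaussian approximation may be ",
                           "poor there"), low))
  structure(list(z = z, selected_counts = sc, neutral_counts = nc,
                 n = selected$n, folded = selected$folded,
                 valid_mask = valid, X = sum(sc), Y = sum(nc),
                 theta_hat = watterson_theta(neutral)),
            class = "ratio_spectrum")
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat(sprintf(
    "Ratio spectrum: n=%d, %s, %d bins (%d valid)\nX=%.6g selected, Y=%.6g neutral sites, Watterson theta=%.6g\n",
    x$n, if (x$folded) "folded" else "unfolded", length(x$z),
    sum(x$valid_mask), x$X, x$Y, x$theta_hat))
  print(utils::head(round(x$z, 4), 12), ...)
  invisible(x)
}

#' Read / write the plain-text SFS format
#'
#' The format is two lines: a header
#' `#sfs n=<int> folded=<0|1> label=<text>` followed by one line of
#' whitespace-separated counts (decimals allowed). A bare single line of
#' counts is also accepted on input and interpreted as an unfolded spectrum
#' with `n = length + 1`.
#'
#' @param path file path.
#' @return `read_sfs` returns an `sfs`; `write_sfs` invisibly returns `path`.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty SFS file: ", path)
  parse_counts <- function(s, lineno) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    if (any(is.na(v)))
      stop(sprintf("%s, line %d: non-numeric count", path, lineno))
    if (any(v < 0))
      stop(sprintf("%s, line %d: negative count", path, lineno))
    v
  }
  if (grepl("^#sfs\\b", lines[1])) {
    get <- function(key) {
      m <- regmatches(lines[1],
                      regexpr(sprintf("%s=\\S+", key), lines[1]))
      if (length(m) == 0)
        stop(sprintf("%s, line 1: malformed header, missing '%s='",
                     path, key))
      sub(sprintf("%s=", key), "", m)
    }
    n <- suppressWarnings(as.integer(get("n")))
    folded <- get("folded")
    if (is.na(n) || !folded %in% c("0", "1"))
      stop(path, ", line 1: malformed header")
    lab <- regmatches(lines[1], regexpr("label=.*$", lines[1]))
    lab <- if (length(lab)) sub("^label=", "", lab) else ""
    if (length(lines) < 2) stop(path, ", line 2: missing counts")
    counts <- parse_counts(lines[2], 2L)
    expected <- if (folded == "1") n %/% 2L else n - 1L
    if (length(counts) != expected)
      stop(sprintf("%s, line 2: %d counts but header implies %d",
                   path, length(counts), expected))
    sfs(counts, n = n, folded = folded == "1", label = lab)
  } else {
    counts <- parse_counts(lines[1], 1L)
    sfs(counts, n = length(counts) + 1L, folded = FALSE)
  }
}

#' @rdname read_sfs
#' @param x an `sfs` to write.
#' @export
write_sfs <- function(x, path) {
  stopifnot(inherits(x, "sfs"))
  header <- sprintf("#sfs n=%d folded=%d label=%s",
                    x$n, as.integer(x$folded), x$label)
  writeLines(c(header, paste(format(x$counts, digits = 17, trim = TRUE,
                                    scientific = FALSE),
                             collapse = " ")), path)
  invisible(path)
}
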