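# Construction of mutational-context-matched neutral control SNP sets.
#
# Each candidate selected SNP (e.g. nonsynonymous) is paired with the
# nearest short-intron SNP sharing its mutational context: the two
# reference bases flanking the site plus the unordered ref/alt allele
# pair. With 16 flank combinations and 6 unordered base pairs there are
# 96 contexts. Pairing is without replacement, so each intron SNP is used
# at most once and the paired design guarantees X = Y downstream (hence
# lambda_hat = rho_hat).

#' Canonical mutational context of a SNP
#'
#' Builds the context string `left[p1/p2]right` where `p1 <= p2` is the
#' lexicographically sorted unordered allele pair. Reference/alternate
#' order is ignored (folded spectra make it meaningless) and reverse
#' complements are NOT merged.
#'
#' @param ref,alt single reference and alternate bases (A/C/G/T).
#' @param left,right flanking reference bases.
#' @return context strings; `NA` where any base is not A/C/G/T.
#' @export
mutation_context <- function(ref, alt, left, right) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    left %in% c("A", "C", "G", "T") & right %in% c("A", "C", "G", "T") &
    ref != alt
  p1 <- ifelse(ref <= alt, ref, alt)
  p2 <- ifelse(ref <= alt, alt, ref)
  out <- paste0(left, "[", p1, "/", p2, "]", right)
  out[!ok] <- NA_character_
  out
}

#' Enumerate all 96 mutational contexts
#' @return character vector of the 96 canonical context strings.
#' @export
all_contexts <- function() {
  b <- c("A", "C", "G", "T")
  pairs <- apply(utils::combn(b, 2), 2, paste, collapse = "/")
  as.vector(outer(outer(b, pairs, function(l, p) paste0(l, "[", p, "]")),
                  b, paste0))
}

#' Annotate site records with their mutational context
#'
#' Looks up the two flanking bases in the reference sequence and attaches
#' a `context` column. Sites whose flanks are missing or ambiguous (N)
#' are reported and get `NA`.
#'
#' @param sites a data.frame of site records with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param reference a named `Biostrings::DNAStringSet` (names matching
#'   `chrom`), or a path to a FASTA file.
#' @return `sites` with an added `context` column.
#' @export
context_of <- function(sites, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  nm <- sub("\\s.*$", "", names(reference))
  left <- right <- rep(NA_character_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    j <- match(ch, nm)
    if (is.na(j)) stop("chromosome not in reference: ", ch)
    seq_len_ch <- Biostrings::width(reference)[j]
    idx <- which(sites$chrom == ch)
    p <- sites$pos[idx]
    okl <- p - 1 >= 1; okr <- p + 1 <= seq_len_ch
    lb <- rep(NA_character_, length(idx))
    rb <- rep(NA_character_, length(idx))
    if (any(okl))
      lb[okl] <- as.character(Biostrings::extractAt(
        reference[[j]], IRanges::IRanges(p[okl] - 1, p[okl] - 1)))
    if (any(okr))
      rb[okr] <- as.character(Biostrings::extractAt(
        reference[[j]], IRanges::IRanges(p[okr] + 1, p[okr] + 1)))
    left[idx] <- lb; right[idx] <- rb
  }
  ctx <- mutation_context(sites$ref, sites$alt, left, right)
  nskip <- sum(is.na(ctx))
  if (nskip > 0)
    message(nskip, " site(s) skipped: ambiguous or missing flanking base")
  sites$context <- ctx
  sites
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair selected SNPs with their nearest unused matched intron SNP
#'
#' Greedy matching: selected sites are processed in genomic order
#' (chromosome, then position); each is paired with the nearest (absolute
#' genomic distance, same chromosome) intron SNP of identical mutational
#' context that has not already been used. Equidistant candidates are
#' broken toward the lower coordinate. Selected sites with no available
#' match are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param selected,introns data.frames with columns `chrom`, `pos`,
#'   `context`, `derived_count`, `genotyped_n` (as from [context_of()] on
#'   [load_vcf_sites()] output).
#' @return a data.frame of pairs (`sel_*` and `int_*` columns) with
#'   attribute `n_dropped`.
#' @export
pair_nearest <- function(selected, introns) {
  need <- c("chrom", "pos", "context")
  stopifnot(all(need %in% names(selected)))
  if (nrow(introns) == 0) {
    warning("empty intron list: no pairs formed")
    out <- data.frame()
    attr(out, "n_dropped") <- nrow(selected)
    return(out)
  }
  stopifnot(all(need %in% names(introns)))
  selected <- selected[!is.na(selected$context), , drop = FALSE]
  introns <- introns[!is.na(introns$context), , drop = FALSE]
  selected <- selected[order(selected$chrom, selected$pos), , drop = FALSE]
  used <- rep(FALSE, nrow(introns))
  key_i <- paste(introns$chrom, introns$context)
  pairs <- vector("list", nrow(selected))
  dropped <- 0L
  for (s in seq_len(nrow(selected))) {
    cand <- which(key_i == paste(selected$chrom[s], selected$context[s]) &
                    !used)
    if (length(cand) == 0) { dropped <- dropped + 1L; next }
    d <- abs(introns$pos[cand] - selected$pos[s])
    best <- cand[order(d, introns$pos[cand])][1]
    used[best] <- TRUE
    pairs[[s]] <- data.frame(
      sel_chrom = selected$chrom[s], sel_pos = selected$pos[s],
      sel_context = selected$context[s],
      sel_count = selected$derived_count[s] %||% NA_integer_,
      sel_n = selected$genotyped_n[s] %||% NA_integer_,
      int_chrom = introns$chrom[best], int_pos = introns$pos[best],
      int_count = introns$derived_count[best] %||% NA_integer_,
      int_n = introns$genotyped_n[best] %||% NA_integer_,
      distance = d[order(d, introns$pos[cand])][1])
  }
  out <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "n_dropped") <- dropped
  out
}

# expected hypergeometric projection of a single site's allele count from
# gn to target_n chromosomes, polymorphic classes only
.project_site <- function(count, gn, target_n) {
  j <- seq_len(target_n - 1L)
  exp(lchoose(count, j) + lchoose(gn - count, target_n - j) -
        lchoose(gn, target_n))
}

#' Paired folded spectra at a uniform sample size
#'
#' Down-samples every site's allele count to the expected SFS at
#' `target_n` chromosomes by hypergeometric projection (discarding mass
#' projected to the monomorphic classes), sums site contributions, and
#' folds. Pairs in which either member has fewer than `target_n`
#' genotyped chromosomes are dropped whole, preserving the equality of
#' contributing selected and intron site numbers.
#'
#' @param pairs output of [pair_nearest()] (needs the count/n columns).
#' @param target_n uniform sample size to project to.
#' @return a list with folded `selected` and `neutral` `sfs` objects and
#'   `n_pairs_used`, `n_pairs_dropped`.
#' @export
build_paired_sfs <- function(pairs, target_n) {
  stopifnot(nrow(pairs) > 0, target_n >= 2)
  ok <- pairs$sel_n >= target_n & pairs$int_n >= target_n
  ndrop <- sum(!ok)
  if (ndrop > 0)
    message(ndrop, " pair(s) dropped: fewer than ", target_n,
            " genotyped chromosomes in at least one member")
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no pairs left after the sample-size filter")
  acc <- function(counts, gns) {
    tot <- numeric(target_n - 1L)
    for (k in seq_along(counts))
      tot <- tot + .project_site(counts[k], gns[k], target_n)
    tot
  }
  sel <- sfs(acc(pairs$sel_count, pairs$sel_n), target_n,
             label = "selected (paired, projected)")
  neu <- sfs(acc(pairs$int_count, pairs$int_n), target_n,
             label = "neutral (paired short-intron, projected)")
  list(selected = fold_sfs(sel), neutral = fold_sfs(neu),
       n_pairs_used = nrow(pairs), n_pairs_dropped = ndrop)
}

#' Load biallelic SNP records from a VCF file
#'
#' Reads a VCF (v4) with `vcfR`, keeps biallelic single-base SNPs
#' genotyped in at least `min_call_fraction` of chromosomes, and assigns
#' each site a class from `class_map`. Multi-allelic, non-SNP and
#' low-call sites are dropped with a reported count.
#'
#' @param path VCF file path.
#' @param class_map either a data.frame with columns `chrom`, `pos`,
#'   `class` (per-site assignment), or with columns `chrom`, `start`,
#'   `end`, `class` (0-based half-open intervals, BED convention). Sites
#'   not covered get class `NA` and are dropped.
#' @param min_call_fraction minimum fraction of chromosomes genotyped
#'   (default 0.5).
#' @return a data.frame of site records: `chrom`, `pos`, `ref`, `alt`,
#'   `site_class`, `derived_count`, `genotyped_n`.
#' @export
load_vcf_sites <- function(path, class_map, min_call_fraction = 0.5) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  n_in <- nrow(fix)
  bases <- c("A", "C", "G", "T")
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% bases & fix$ALT %in% bases
  alleles_per <- 1L + lengths(regmatches(gt[1, ], gregexpr("[/|]", gt[1, ])))
  total_chrom <- sum(ifelse(is.na(gt[1, ]), base::max(alleles_per, na.rm = TRUE),
                            alleles_per))
  count_site <- function(row) {
    toks <- unlist(strsplit(gt[row, ], "[/|]"))
    called <- toks[!is.na(toks) & toks != "."]
    c(alt = sum(called == "1"), n = length(called))
  }
  stats_m <- vapply(seq_len(nrow(fix)), count_site, c(alt = 0, n = 0))
  called_frac <- stats_m["n", ] / total_chrom
  keep <- biallelic & called_frac >= min_call_fraction
  dropped <- n_in - sum(keep)
  if (dropped > 0)
    message(dropped, " site(s) dropped: multi-allelic, non-SNP, or below ",
            sprintf("%.0f%%", 100 * min_call_fraction), " call rate")
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    derived_count = as.integer(stats_m["alt", keep]),
                    genotyped_n = as.integer(stats_m["n", keep]),
                    stringsAsFactors = FALSE)
  # class assignment
  if (all(c("pos", "class") %in% names(class_map)) &&
      !("start" %in% names(class_map))) {
    key <- paste(class_map$chrom, class_map$pos)
    out$site_class <- class_map$class[match(paste(out$chrom, out$pos), key)]
  } else if (all(c("start", "end", "class") %in% names(class_map))) {
    out$site_class <- NA_character_
    for (k in seq_len(nrow(class_map))) {
      hit <- out$chrom == class_map$chrom[k] &
        out$pos > class_map$start[k] & out$pos <= class_map$end[k]
      out$site_class[hit] <- class_map$class[k]
    }
  } else stop("'class_map' needs columns (chrom,pos,class) or (chrom,start,end,class)")
  nona <- !is.na(out$site_class)
  if (any(!nona))
    message(sum(!nona), " site(s) dropped: no class assignment")
  out[nona, , drop = FALSE]
}
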