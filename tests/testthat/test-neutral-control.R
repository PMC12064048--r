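test_that("mutational contexts are unordered in the allele pair and number 96", {
  expect_equal(mutation_context("C", "T", "A", "A"),
               mutation_context("T", "C", "A", "A"))
  expect_equal(mutation_context("C", "T", "A", "G"), "A[C/T]G")
  expect_true(is.na(mutation_context("C", "T", "N", "A")))
  expect_true(is.na(mutation_context("C", "C", "A", "A")))
  ctx <- all_contexts()
  expect_length(unique(ctx), 96)
  # every constructible site context is one of the 96
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = b, alt = b, l = b, r = b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  expect_true(all(with(grid, mutation_context(ref, alt, l, r)) %in% ctx))
})

test_that("context annotation reads flanks from the reference", {
  fa <- withr::local_tempfile(fileext = ".fa")
  #         123456789012
  write_fixture_fasta(fa, "chr1", "ACGTACGTNCGT")
  sites <- data.frame(chrom = "chr1", pos = c(2, 5, 10, 1),
                      ref = c("C", "A", "C", "A"),
                      alt = c("T", "G", "A", "C"))
  expect_message(out <- context_of(sites, fa), "skipped")
  expect_equal(out$context[1], "A[C/T]G")
  expect_equal(out$context[2], "T[A/G]C")
  expect_true(is.na(out$context[3]))  # N flank
  expect_true(is.na(out$context[4]))  # no left flank
})

test_that("nearest-context pairing is greedy, without replacement, deterministic", {
  sel <- data.frame(chrom = "chr1", pos = c(1000, 2000),
                    context = c("A[C/T]G", "A[C/T]G"),
                    derived_count = c(3, 4), genotyped_n = c(10, 10))
  intr <- data.frame(chrom = "chr1", pos = c(1100, 1500, 9000),
                     context = c("A[C/T]G", "A[C/T]G", "T[A/G]A"),
                     derived_count = c(1, 2, 5), genotyped_n = c(10, 10, 10))
  pr <- pair_nearest(sel, intr)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$int_pos, c(1100, 1500))  # nearest first, then next unused
  expect_equal(attr(pr, "n_dropped"), 0)

  # shared single eligible intron: second selected site is dropped
  pr2 <- pair_nearest(sel, intr[1, , drop = FALSE])
  expect_equal(nrow(pr2), 1)
  expect_equal(attr(pr2, "n_dropped"), 1)

  # equidistant tie breaks toward the lower coordinate
  sel3 <- data.frame(chrom = "chr1", pos = 500, context = "A[C/T]G",
                     derived_count = 1, genotyped_n = 10)
  intr3 <- data.frame(chrom = "chr1", pos = c(400, 600), context = "A[C/T]G",
                      derived_count = c(1, 1), genotyped_n = c(10, 10))
  expect_equal(pair_nearest(sel3, intr3)$int_pos, 400)

  expect_warning(empty <- pair_nearest(sel, intr[0, ]), "empty intron")
  expect_equal(nrow(empty), 0)
})

test_that("a ten-by-ten fixture pairs exactly as hand enumeration says", {
  ctxs <- rep(c("A[C/T]A", "G[A/G]C"), each = 5)
  sel <- data.frame(chrom = "chr1", pos = seq(100, 1000, by = 100),
                    context = ctxs, derived_count = 1, genotyped_n = 4)
  # introns laid out so each selected site's nearest unused match is known:
  # A-context introns at 90, 130, 420, 460, 550; G-context at 590, 640,
  # 810, 870, 1040
  intr <- data.frame(chrom = "chr1",
                     pos = c(90, 130, 420, 460, 550, 590, 640, 810, 870, 1040),
                     context = rep(c("A[C/T]A", "G[A/G]C"), each = 5),
                     derived_count = 1, genotyped_n = 4)
  pr <- pair_nearest(sel, intr)
  # selected (in order 100..500 A-ctx, 600..1000 G-ctx) pair with:
  # 100->90 (d10), 200->130 (d70), 300->420 (d120), 400->460 (d60... used?
  # greedy order: 300 processed before 400: 300->420(d120) vs 460(d160);
  # then 400->460 (d60), 500->550 (d50)
  expect_equal(pr$int_pos[pr$sel_pos %in% c(100, 200, 300, 400, 500)],
               c(90, 130, 420, 460, 550))
  expect_equal(pr$int_pos[pr$sel_pos %in% c(600, 700, 800, 900, 1000)],
               c(590, 640, 810, 870, 1040))
  # the matching is injective on both sides
  expect_equal(anyDuplicated(pr$int_pos), 0)
  expect_equal(anyDuplicated(pr$sel_pos), 0)
})

test_that("paired spectra project, fold, and preserve the X = Y design", {
  # single site, 2 derived of 4, target 2: folded bin 1 gets P(1 of 2) = 2/3
  pr <- data.frame(sel_chrom = "chr1", sel_pos = 1, sel_context = "A[C/T]A",
                   sel_count = 2, sel_n = 4,
                   int_chrom = "chr1", int_pos = 2, int_count = 2, int_n = 4,
                   distance = 1)
  out <- build_paired_sfs(pr, 2)
  expect_equal(out$selected$counts, 2 / 3, tolerance = 1e-12)
  expect_equal(out$neutral$counts, 2 / 3, tolerance = 1e-12)

  # sites already at target_n: plain tabulation then folding
  pr2 <- data.frame(sel_chrom = "chr1", sel_pos = 1:3,
                    sel_context = "A[C/T]A",
                    sel_count = c(1, 3, 2), sel_n = 4,
                    int_chrom = "chr1", int_pos = 4:6,
                    int_count = c(1, 1, 2), int_n = 4, distance = 1)
  out2 <- build_paired_sfs(pr2, 4)
  expect_equal(out2$selected$counts, c(2, 1))  # bins (1+3 folded, 2)
  expect_equal(out2$neutral$counts, c(2, 1))
  expect_equal(sum(out2$selected$counts), sum(out2$neutral$counts))

  # undersampled member drops the whole pair
  pr3 <- pr2; pr3$int_n <- c(4, 2, 4)
  expect_message(out3 <- build_paired_sfs(pr3, 4), "dropped")
  expect_equal(out3$n_pairs_used, 2)
  expect_equal(sum(out3$selected$counts), sum(out3$neutral$counts))
})

test_that("VCF loading filters call rate, ploidy-counts alleles, assigns classes", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gts <- rbind(gt_row(3, 3, 5),   # 60% called, kept
               gt_row(2, 2, 5),   # 40% called, dropped
               gt_row(1, 5, 5),   # tri-allelic below, dropped
               gt_row(4, 5, 5))   # kept
  write_fixture_vcf(vcf, rep("chr1", 4), c(10, 20, 30, 40),
                    c("A", "C", "G", "T"), c("G", "T", "A,C", "C"), gts)
  cm <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                   class = c("nonsynonymous", "nonsynonymous",
                             "short_intron", "short_intron"))
  expect_message(sites <- load_vcf_sites(vcf, cm), "dropped")
  expect_equal(sites$pos, c(10, 40))
  expect_equal(sites$derived_count, c(3, 4))
  expect_equal(sites$genotyped_n, c(6, 10))
  expect_equal(sites$site_class, c("nonsynonymous", "short_intron"))

  # interval (BED-convention) class map
  cm2 <- data.frame(chrom = "chr1", start = c(0, 35), end = c(15, 45),
                    class = c("nonsynonymous", "short_intron"))
  expect_message(sites2 <- load_vcf_sites(vcf, cm2), "dropped")
  expect_equal(sites2$site_class, c("nonsynonymous", "short_intron"))
})

test_that("a fully neutral paired design yields rho near 1 downstream", {
  # selected and intron counts drawn from the same neutral SFS law
  set.seed(71)
  n_sites <- 6000; gn <- 30; target <- 20
  pbin <- (1 / 1:(gn - 1)) / sum(1 / 1:(gn - 1))
  draw <- function() sample(seq_len(gn - 1), n_sites, TRUE, pbin)
  pr <- data.frame(sel_chrom = "chr1", sel_pos = seq_len(n_sites),
                   sel_context = "A[C/T]A",
                   sel_count = draw(), sel_n = gn,
                   int_chrom = "chr1", int_pos = seq_len(n_sites) + 1e6,
                   int_count = draw(), int_n = gn, distance = 1)
  out <- build_paired_sfs(pr, target)
  expect_equal(out$n_pairs_used, n_sites)
  r <- suppressWarnings(make_ratios(out$selected, out$neutral))
  # paired design: equal site numbers, so X/Y = 1 up to projection loss
  expect_equal(r$X / r$Y, 1, tolerance = 0.01)
  fit <- sfr_fit(r, "fixed", n_starts = 2, seed = 3,
                 grid = build_grid(target, folded = TRUE))
  expect_equal(fit$rho_hat, 1, tolerance = 0.05)
  expect_equal(fit$lambda_hat, fit$rho_hat, tolerance = 0.01)
  expect_lt(abs(fit$model$params$gamma), 1)
})
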