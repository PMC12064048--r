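# Minimal VCF v4.2 writer for fixtures: diploid genotypes, one ALT allele
# unless 'alt' contains a comma. 'gts' is a character matrix sites x samples
# with entries like "0/1" or "./.".
write_fixture_vcf <- function(path, chrom, pos, ref, alt, gts) {
  ns <- ncol(gts)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("s", seq_len(ns))),
                    collapse = "\t"))
  body <- vapply(seq_along(pos), function(k)
    paste(c(chrom[k], pos[k], ".", ref[k], alt[k], ".", "PASS", ".", "GT",
            gts[k, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

# FASTA writer for a single named sequence
write_fixture_fasta <- function(path, name, seq) {
  writeLines(c(paste0(">", name), seq), path)
  path
}

# diploid genotype strings giving 'alt_n' alt alleles over 'called' called
# samples out of 'total' (the rest are ./.)
gt_row <- function(alt_n, called, total) {
  g <- rep("./.", total)
  full <- alt_n %/% 2; half <- alt_n %% 2
  pat <- c(rep("1/1", full), rep("0/1", half),
           rep("0/0", called - full - half))
  g[seq_len(called)] <- pat
  g
}
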