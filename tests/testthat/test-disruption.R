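# A tiny hand-built locus used by several blocks: one strong motif planted
# in a short random genome, a SNP at its most informative column.
tiny_locus <- function(seed = 5) {
  withr::with_seed(seed, {
    p <- random_pwms("TFA", 10, dominance = 0.95, seed = seed)[[1]]
    flank <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    genome <- c(chr1 = paste0(flank, consensus_seq(p), flank))
    start <- 120L                       # motif occupies [120, 130)
    col <- which.max(apply(p$probs, 1, max))
    pos <- start + col - 1L
    ref <- substr(genome[["chr1"]], pos + 1L, pos + 1L)
    alt <- BASES_worst(p, col)
    list(pwm = p, genome = genome, start = start, pos = pos,
         ref = ref, alt = alt)
  })
}
BASES_worst <- function(p, col) c("A", "C", "G", "T")[which.min(p$probs[col, ])]

test_that("summit-window pairing applies the +/-50 bp rule exactly", {
  peaks <- data.frame(contig = "chr1", start = 900, end = 1100,
                      summit_offset = 100, neg_log10_q = 3,
                      tf_name = "TFA", peak_id = "p1",
                      stringsAsFactors = FALSE)   # summit at 1000
  snps <- data.frame(snp_id = c("in", "edge", "out", "othercontig"),
                     contig = c("chr1", "chr1", "chr1", "chr2"),
                     position = c(1000, 1050, 1051, 1000),
                     ref = "A", alt = "G", maf = NA_real_,
                     locus_id = NA_character_, stringsAsFactors = FALSE)
  pairs <- snps_in_summit_windows(snps, peaks, flank = 50)
  expect_setequal(pairs$snp_id, c("in", "edge"))
  expect_equal(nrow(snps_in_summit_windows(snps[0, ], peaks)), 0)
})

test_that("allele_context builds centred sequences and validates the reference", {
  tl <- tiny_locus()
  snp <- list(snp_id = "s", contig = "chr1", position = tl$pos,
              ref = tl$ref, alt = tl$alt)
  ctx <- allele_context(tl$genome, snp, flank = 20)
  expect_equal(nchar(ctx$ref_seq), 41)
  expect_equal(nchar(ctx$alt_seq), 41)
  diff_at <- which(strsplit(ctx$ref_seq, "")[[1]] !=
                     strsplit(ctx$alt_seq, "")[[1]])
  expect_equal(diff_at, 21)            # 0-based index 20
  expect_equal(ctx$snp_index, 20)

  bad <- snp
  bad$ref <- setdiff(c("A", "C", "G", "T"), c(tl$ref, tl$alt))[1]
  expect_error(allele_context(tl$genome, bad), class = "regsnpscan_ref_mismatch")
  near_end <- list(snp_id = "e", contig = "chr1", position = 3,
                   ref = "A", alt = "G")
  expect_error(allele_context(tl$genome, near_end, flank = 20),
               class = "regsnpscan_boundary")
  # degenerate flank: sequences are the bare alleles
  ctx0 <- allele_context(tl$genome, snp, flank = 0)
  expect_equal(ctx0$ref_seq, tl$ref)
  expect_equal(ctx0$alt_seq, tl$alt)
})

test_that("disruption verdict follows the one-or-more-alleles rule", {
  tl <- tiny_locus()
  lom <- build_log_odds(tl$pwm)
  d <- exact_pvalue_table(lom)
  snp <- list(snp_id = "s", contig = "chr1", position = tl$pos,
              ref = tl$ref, alt = tl$alt)
  ctx <- allele_context(tl$genome, snp)
  call <- call_disruption(lom, d, ctx$ref_seq, ctx$alt_seq, ctx$snp_index)
  expect_lt(call$ref$best_pvalue, 1e-3)
  expect_true(call$disrupts)
  expect_gt(call$delta_llr, 0)
  expect_lte(call$ref$n_windows_scored, 2 * tl$pwm$width)

  # verdict symmetry: swapping ref and alt leaves disrupts unchanged
  swapped <- call_disruption(lom, d, ctx$alt_seq, ctx$ref_seq, ctx$snp_index)
  expect_equal(swapped$disrupts, call$disrupts)
  expect_equal(swapped$delta_llr, -call$delta_llr)

  # degenerate uniform matrix: every p-value is 1, no disruption
  ulom <- build_log_odds(pwm("u", matrix(0.25, 10, 4)))
  ud <- exact_pvalue_table(ulom)
  ucall <- call_disruption(ulom, ud, ctx$ref_seq, ctx$alt_seq, ctx$snp_index)
  expect_equal(ucall$ref$best_pvalue, 1)
  expect_false(ucall$disrupts)
  expect_equal(ucall$delta_llr, 0)
})

test_that("screen pairs a SNP with every overlapping TF and deduplicates", {
  tl <- tiny_locus()
  pwms <- list(TFA = tl$pwm,
               TFB = random_pwms("TFB", 8, seed = 9)[[1]])
  peaks <- data.frame(
    contig = "chr1", start = c(80, 90, 100),
    end = c(180, 190, 160),
    summit_offset = c(tl$pos - 80, tl$pos - 90, tl$pos - 100 + 4),
    neg_log10_q = 3, tf_name = c("TFA", "TFA", "TFB"),
    peak_id = c("a1", "a2", "b1"), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "s1", contig = "chr1", position = tl$pos,
                     ref = tl$ref, alt = tl$alt, maf = 0.2,
                     locus_id = NA_character_, stringsAsFactors = FALSE)
  calls <- run_disruption_screen(tl$genome, snps, peaks, pwms)
  # two TFA peaks collapse to one call; TFB produces its own
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$tf_name, c("TFA", "TFB"))
  expect_true(calls$disrupts[calls$tf_name == "TFA"])
  expect_equal(nrow(run_disruption_screen(tl$genome, snps[0, ], peaks, pwms)), 0)
})

test_that("per-TF summary counts distinct SNPs and co-disruptions", {
  calls <- data.frame(
    snp_id = c("s1", "s2", "s3", "s1", "s1"),
    tf_name = c("TF1", "TF1", "TF1", "TF2", "TF2"),
    disrupts = TRUE, stringsAsFactors = FALSE)   # s1/TF2 duplicated
  s <- summarize_by_tf(calls)
  expect_equal(s$per_tf$n_disrupting_snps[s$per_tf$tf_name == "TF1"], 3)
  expect_equal(s$per_tf$n_disrupting_snps[s$per_tf$tf_name == "TF2"], 1)
  expect_equal(s$co_disruption$n_snps, 1)
  empty <- summarize_by_tf(calls[calls$snp_id == "none", ])
  expect_equal(nrow(empty$per_tf), 0)
})

test_that("genomic context follows the documented precedence", {
  gm <- data.frame(
    contig = "chr1",
    start = c(1000, 1000, 1100), end = c(3000, 1100, 1200),
    type = c("gene", "UTR", "exon"), gene = "g1", strand = "+",
    stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = c("exonic", "UTR", "intronic", "upstream", "downstream",
               "intergenic"),
    contig = "chr1",
    position = c(1150, 1050, 2000, 500, 3500, 8000),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  ctx <- genomic_context(snps, gm, margin = 1000)
  expect_equal(ctx$category, ctx$snp_id)   # ids were named by expectation
  expect_equal(sum(attr(ctx, "fractions")), 1)
})
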