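test_that("genome generator hits the requested GC and is reproducible", {
  g <- make_genome(length_bp = 2e5, gc = 0.5, seed = 4)[[1]]
  gc <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  expect_identical(make_genome(length_bp = 1e4, seed = 9),
                   make_genome(length_bp = 1e4, seed = 9))
  only_gc <- make_genome(length_bp = 5e3, gc = 1, seed = 2)[[1]]
  expect_false(grepl("[AT]", only_gc))
})

test_that("planted sites and peaks have the stated geometry", {
  pwms <- random_pwms(c("TFA", "TFB"), c(8, 10), seed = 6)
  genome <- make_genome(length_bp = 3e5, seed = 6)
  out <- plant_motifs_and_peaks(genome, pwms, n_sites_per_tf = 5,
                                summit_jitter_bp = 0, seed = 6)
  expect_equal(nrow(out$peaks), 10)
  expect_equal(nrow(out$sites), 10)
  # jitter 0: every summit exactly at the site centre
  summit <- out$peaks$start + out$peaks$summit_offset
  centre <- out$sites$start + out$sites$width %/% 2
  expect_equal(summit, centre)
  # the planted consensus (or its reverse complement) is in the genome
  for (i in seq_len(nrow(out$sites))) {
    s <- out$sites[i, ]
    written <- genome_fetch(out$genome, s$contig, s$start, s$start + s$width)
    cons <- consensus_seq(pwms[[s$tf]])
    expect_equal(if (s$strand == "+") written else revcomp(written), cons)
  }
})

test_that("scanning the edited genome recovers the planted sites", {
  pwms <- random_pwms(c("TFA", "TFB"), c(8, 10), seed = 14)
  genome <- make_genome(length_bp = 3e5, seed = 14)
  out <- plant_motifs_and_peaks(genome, pwms, n_sites_per_tf = 8, seed = 14)
  found <- 0
  for (tf in names(pwms)) {
    lom <- build_log_odds(pwms[[tf]])
    d <- exact_pvalue_table(lom)
    hits <- scan_sequence(lom, d, out$genome[[1]], alpha = 1e-3)
    planted <- out$sites$start[out$sites$tf == tf]
    found <- found + sum(planted %in% hits$window_start)
  }
  expect_gte(found / nrow(out$sites), 0.95)
})

test_that("planted SNP classes have the promised geometry and effect", {
  fx <- acceptance_fixture()
  truth <- fx$sim$truth
  snps <- fx$sim$snps
  expect_length(truth$disrupting, 50)
  expect_length(truth$benign_in_peak, 75)
  expect_length(truth$outside_peak, 75)
  # outside-peak SNPs are never paired with any summit window
  pairs <- snps_in_summit_windows(snps, fx$sim$peaks, flank = 50)
  expect_length(intersect(truth$outside_peak, pairs$snp_id), 0)
  # every disrupting SNP lies inside a planted site
  sites <- fx$sim$sites
  for (id in truth$disrupting[1:10]) {
    s <- snps[snps$snp_id == id, ]
    inside <- any(sites$contig == s$contig & s$position >= sites$start &
                    s$position < sites$start + sites$width)
    expect_true(inside)
  }
})

test_that("annotation generator plants recoverable consensus SNPs", {
  gen <- make_annotation_scores(n_loci = 40, planted_fraction = 1, seed = 12)
  expect_silent(regdb_rating_key(gen$rows$regulomedb))   # grammar respected
  res <- consensus(gen$rows)
  hit <- vapply(names(gen$truth), function(L) {
    gen$truth[[L]] %in% res$loci[[L]]$consensus_snps
  }, logical(1))
  expect_true(all(hit))

  none <- make_annotation_scores(n_loci = 40, planted_fraction = 0, seed = 12)
  expect_length(none$truth, 0)
})

test_that("generated files round-trip through the readers without loss", {
  fx <- acceptance_fixture()
  inputs <- read_fixture_inputs(fx)
  expect_equal(inputs$genome, fx$sim$genome)
  expect_equal(nrow(inputs$snps), nrow(fx$sim$snps))
  expect_equal(inputs$snps$position, fx$sim$snps$position)
  expect_equal(nrow(inputs$peaks), nrow(fx$sim$peaks))
  # MEME serialization carries 6 decimals, so round-trip is close, not exact
  for (tf in names(inputs$pwms)) {
    expect_equal(inputs$pwms[[tf]]$probs, fx$sim$pwms[[tf]]$probs,
                 tolerance = 1e-4)
  }
  pool <- read_pool_table(file.path(fx$dir, "pool.tsv"))
  expect_equal(nrow(pool), nrow(fx$sim$pool))
  expr <- read_expression_matrix(file.path(fx$dir, "expression.tsv"),
                                 file.path(fx$dir, "stages.tsv"))
  expect_equal(dim(expr$values), dim(fx$sim$downstream$expression$values))
})

test_that("simulate_study is bit-reproducible for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(d1, seed = 303, length_bp = 5e4, n_sites_per_tf = 3,
                 n_disrupting = 6, n_benign_in_peak = 6, n_outside_peak = 6)
  simulate_study(d2, seed = 303, length_bp = 5e4, n_sites_per_tf = 3,
                 n_disrupting = 6, n_benign_in_peak = 6, n_outside_peak = 6)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
})
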