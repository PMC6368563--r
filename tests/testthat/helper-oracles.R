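# Independent oracles and shared fixtures for the test suite.

# Brute-force null distribution of the discretized motif score: enumerate all
# 4^w windows, score each against the integer matrix, weight by the
# zero-order background, and suffix-sum. Independent of the DP convolution
# it checks. With a dyadic background (e.g. uniform 0.25) every quantity is
# exactly representable, so agreement is exact, not approximate.
brute_survival <- function(lom, dist) {
  w <- lom$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- integer(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (i in seq_len(w)) {
    sc <- sc + lom$int_entries[i, grid[, i]]
    pr <- pr * lom$background[grid[, i]]
  }
  pmf <- numeric(length(dist$support))
  agg <- tapply(pr, sc - dist$support[1] + 1L, sum)
  pmf[as.integer(names(agg))] <- agg
  rev(cumsum(rev(pmf)))
}

# Exact-rational two-sided minimum-likelihood binomial p at ratio 0.5:
# binomial coefficients are exact integers for n <= 25 and 2^-n is dyadic,
# so comparisons and sums are exact.
binom_minlike_oracle <- function(a, b) {
  n <- a + b
  cf <- choose(n, 0:n)
  sum(cf[cf <= cf[a + 1]]) / 2^n
}

random_prob_pwm <- function(name, w, background = rep(0.25, 4)) {
  probs <- matrix(runif(4L * w), nrow = w)
  probs <- probs / rowSums(probs)
  pwm(name, probs, background)
}

# The packaged synthetic study: built once per test run and reused by every
# test that needs the full fixture.
.fixture_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.fixture_cache$sim)) {
    dir <- file.path(tempdir(), "regsnpscan-fixture")
    unlink(dir, recursive = TRUE)
    .fixture_cache$sim <- simulate_study(dir, seed = 20190208)
    .fixture_cache$dir <- dir
  }
  list(sim = .fixture_cache$sim, dir = .fixture_cache$dir)
}

read_fixture_inputs <- function(fx) {
  peaks <- do.call(rbind, lapply(names(fx$sim$paths$peaks), function(tf) {
    read_narrowpeak(fx$sim$paths$peaks[[tf]], tf_name = tf)
  }))
  list(genome = read_genome_fasta(file.path(fx$dir, "genome.fa")),
       pwms = read_meme_motifs(file.path(fx$dir, "motifs.meme")),
       peaks = peaks,
       snps = read_snvs(file.path(fx$dir, "snps.vcf"), dialect = "vcf"))
}
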