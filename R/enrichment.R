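# Resampling nulls: the MAF-matched eQTL-enrichment Z test and the per-TF
# disruption-count null. All draws are without replacement within a
# simulation and fully determined by the supplied seed.

maf_bin_index <- function(maf, bin_width = 0.05) {
  if (any(is.na(maf)) || any(maf <= 0 | maf > 0.5)) {
    stop("MAF values must lie in (0, 0.5]")
  }
  pmin(as.integer(ceiling(maf / bin_width)), as.integer(ceiling(0.5 / bin_width)))
}

# pool candidates indexed per MAF bin; shared by the sampler and the Z test
pool_bins <- function(pool, bin_width) {
  split(seq_len(nrow(pool)), maf_bin_index(pool$maf, bin_width))
}

#' Draw a MAF-matched SNP sample from a pool
#'
#' One pool SNP is drawn uniformly without replacement per template SNP from
#' the same MAF bin (bins of `bin_width` on (0, 0.5]).
#'
#' @param pool data.frame with at least snp_id, maf (layout of
#'   [read_pool_table()]).
#' @param template_mafs MAFs of the observed set to match.
#' @param bin_width MAF bin width, default 0.05.
#' @param seed RNG seed; identical seeds give identical draws.
#' @return character vector of sampled snp_ids (grouped by bin).
#' @export
maf_matched_sample <- function(pool, template_mafs, bin_width = 0.05,
                               seed = 1L) {
  bins <- pool_bins(pool, bin_width)
  need <- table(maf_bin_index(template_mafs, bin_width))
  with_seed(seed, {
    picks <- lapply(names(need), function(b) {
      cand <- bins[[b]]
      k <- need[[b]]
      if (is.null(cand) || length(cand) < k) {
        stop(sprintf(
          "infeasible MAF matching: bin %s (%.2f, %.2f] needs %d SNPs, pool has %d",
          b, (as.integer(b) - 1L) * bin_width, as.integer(b) * bin_width,
          k, length(cand %||% integer(0))))
      }
      cand[sample.int(length(cand), k)]
    })
    pool$snp_id[unlist(picks)]
  })
}

#' MAF-matched eQTL-enrichment Z test
#'
#' Counts eQTL-significant SNPs in the observed set, then builds a null by
#' repeatedly drawing MAF-matched samples of the same size from the pool and
#' counting significant SNPs in each. The standardized statistic is
#' `z = (observed - null_mean) / null_sd` with the one-tailed conversion
#' `p = pnorm(-|z|)` (a `two_tailed` flag doubles it).
#'
#' @param pool data.frame with snp_id, maf, eqtl_flag.
#' @param observed_set snp_ids of the observed set (must be in the pool).
#' @param n_sims number of null draws, default 10000.
#' @param bin_width MAF bin width, default 0.05.
#' @param seed RNG seed.
#' @param exclude_observed drop observed SNPs from the sampling pool
#'   (default FALSE).
#' @param two_tailed double the p-value (default FALSE).
#' @return object of class `enrichment_result`: observed, null_mean,
#'   null_sd, z, p, n_sims, seed, null_counts. A degenerate null
#'   (`null_sd == 0`) reports z and p as NA.
#' @export
eqtl_enrichment_z <- function(pool, observed_set, n_sims = 10000L,
                              bin_width = 0.05, seed = 1L,
                              exclude_observed = FALSE, two_tailed = FALSE) {
  if (n_sims < 100L) stop("n_sims must be >= 100")
  pool <- pool[order(pool$snp_id), , drop = FALSE]   # row-order invariance
  idx <- match(observed_set, pool$snp_id)
  if (anyNA(idx)) {
    stop("observed SNP absent from pool: ", observed_set[is.na(idx)][1])
  }
  observed <- sum(pool$eqtl_flag[idx])
  template_mafs <- pool$maf[idx]
  sampling_pool <- if (exclude_observed) pool[-idx, , drop = FALSE] else pool
  bins <- pool_bins(sampling_pool, bin_width)
  need <- table(maf_bin_index(template_mafs, bin_width))
  bin_flags <- lapply(names(need), function(b) {
    cand <- bins[[b]]
    if (is.null(cand) || length(cand) < need[[b]]) {
      stop(sprintf("infeasible MAF matching: bin %s needs %d SNPs, pool has %d",
                   b, need[[b]], length(cand %||% integer(0))))
    }
    sampling_pool$eqtl_flag[cand]
  })
  ks <- as.integer(need)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      tot <- 0L
      for (j in seq_along(bin_flags)) {
        fl <- bin_flags[[j]]
        tot <- tot + sum(fl[sample.int(length(fl), ks[j])])
      }
      tot
    }, integer(1))
  })
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  if (null_sd > 0) {
    z <- (observed - null_mean) / null_sd
    p <- stats::pnorm(-abs(z))
    if (two_tailed) p <- min(1, 2 * p)
  } else {
    z <- NA_real_
    p <- NA_real_
    message("degenerate null (sd = 0); z and p undefined")
  }
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p = p,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 null_counts = null_counts),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "MAF-matched enrichment: observed %d, null %.2f +/- %.2f, z = %.3f, p = %.3g (%d sims)\n",
    x$observed, x$null_mean, x$null_sd, x$z, x$p, x$n_sims))
  invisible(x)
}

#' Per-TF disruption-count null by resampling from a labelled pool
#'
#' Repeatedly samples `m` SNPs without replacement from the pool of
#' TF-labelled binding-disrupting SNPs, counts the draws per TF, and reports
#' the null mean/sd plus the add-one empirical p-value
#' `(r + 1) / (n_sims + 1)` where `r` counts simulations reaching the
#' observed count.
#'
#' @param pool_tf data.frame with snp_id and tf (one label per SNP).
#' @param m sample size per simulation (the observed number of disrupting
#'   SNPs), default 132.
#' @param observed_counts named integer vector, observed disrupting-SNP
#'   count per TF; TFs absent from the vector count as 0.
#' @param n_sims number of simulations, default 1000.
#' @param seed RNG seed.
#' @return data.frame tf, observed, null_mean, null_sd, empirical_p.
#' @export
tf_count_null <- function(pool_tf, m = 132L, observed_counts,
                          n_sims = 1000L, seed = 1L) {
  n <- nrow(pool_tf)
  if (m > n) stop(sprintf("cannot sample %d SNPs from a pool of %d", m, n))
  tfs <- sort(unique(pool_tf$tf))
  tf_idx <- match(pool_tf$tf, tfs)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      tabulate(tf_idx[sample.int(n, m)], nbins = length(tfs))
    }, integer(length(tfs)))
  })
  sims <- matrix(sims, nrow = length(tfs))
  obs <- vapply(tfs, function(tf) {
    as.integer(observed_counts[tf] %||% 0L)
  }, integer(1))
  obs[is.na(obs)] <- 0L
  r <- rowSums(sims >= obs)
  data.frame(tf = tfs, observed = obs,
             null_mean = rowMeans(sims),
             null_sd = apply(sims, 1, stats::sd),
             empirical_p = (r + 1) / (n_sims + 1),
             stringsAsFactors = FALSE)
}
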