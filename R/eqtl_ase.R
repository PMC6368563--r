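# eQTL target-gene tiering across datasets with per-dataset significance
# rules, exact binomial allele-specific-expression tests, and LD partner
# screening by genotype-dosage correlation.

#' Default per-dataset eQTL significance rules
#'
#' CMC FDR < 0.05, LIBD FDR < 0.01, GTEX nominal p < 0.001 — the defaults of
#' the three source studies.
#'
#' @return named list of `list(metric, cutoff)` rules.
#' @export
default_eqtl_thresholds <- function() {
  list(CMC = list(metric = "fdr", cutoff = 0.05),
       LIBD = list(metric = "fdr", cutoff = 0.01),
       GTEX = list(metric = "p", cutoff = 0.001))
}

#' Tier target genes of disrupting SNPs across eQTL datasets
#'
#' For each (SNP, gene) pair, counts the datasets in which the association
#' passes that dataset's own rule (a dataset counts once regardless of how
#' many tissues pass). Tiers: `any` (>= 1 dataset), `replicated` (>= 2),
#' `full` (all three named datasets).
#'
#' @param disrupting_ids snp_ids of binding-disrupting SNPs.
#' @param eqtl data.frame (layout of [read_eqtl_table()]).
#' @param thresholds named list of per-dataset rules; see
#'   [default_eqtl_thresholds()].
#' @return data.frame snp_id, gene, n_supporting_datasets, datasets
#'   (comma-separated), tier; only pairs with at least one supporting
#'   dataset appear.
#' @export
tier_targets <- function(disrupting_ids, eqtl,
                         thresholds = default_eqtl_thresholds()) {
  eqtl <- eqtl[eqtl$snp_id %in% disrupting_ids, , drop = FALSE]
  unknown <- setdiff(unique(eqtl$dataset), names(thresholds))
  if (length(unknown)) {
    stop("no significance rule configured for dataset: ",
         paste(unknown, collapse = ", "))
  }
  if (!nrow(eqtl)) {
    return(data.frame(snp_id = character(0), gene = character(0),
                      n_supporting_datasets = integer(0),
                      datasets = character(0), tier = character(0),
                      stringsAsFactors = FALSE))
  }
  passes <- vapply(seq_len(nrow(eqtl)), function(i) {
    rule <- thresholds[[eqtl$dataset[i]]]
    val <- eqtl[[rule$metric]][i]
    !is.na(val) && val < rule$cutoff
  }, logical(1))
  sig <- unique(eqtl[passes, c("snp_id", "gene", "dataset"), drop = FALSE])
  if (!nrow(sig)) {
    return(data.frame(snp_id = character(0), gene = character(0),
                      n_supporting_datasets = integer(0),
                      datasets = character(0), tier = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(sig$snp_id, sig$gene, sep = "\r")
  agg <- lapply(split(sig$dataset, key), function(d) sort(unique(d)))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  n_sup <- lengths(agg)
  out <- data.frame(
    snp_id = vapply(parts, `[[`, "", 1L),
    gene = vapply(parts, `[[`, "", 2L),
    n_supporting_datasets = as.integer(n_sup),
    datasets = vapply(agg, paste, "", collapse = ","),
    tier = ifelse(n_sup >= 3L, "full",
                  ifelse(n_sup >= 2L, "replicated", "any")),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_supporting_datasets, out$snp_id, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Minimum-likelihood ("minlike") two-sided p-value: the sum of `P(k)` over
#' all outcomes whose probability does not exceed that of the observation,
#' under `Binomial(ref + alt, null_ratio)`. At `null_ratio = 0.5` this
#' coincides with tail doubling by symmetry.
#'
#' @param ref_count,alt_count non-negative allele read counts (not both 0).
#' @param null_ratio expected reference-allele fraction, default 0.5.
#' @return p-value in (0, 1].
#' @export
binomial_ase <- function(ref_count, alt_count, null_ratio = 0.5) {
  if (ref_count < 0 || alt_count < 0) stop("negative allele count")
  n <- ref_count + alt_count
  if (n < 1) stop("undefined input: both allele counts are zero")
  d <- stats::dbinom(0:n, n, null_ratio)
  # relative tolerance guards against ulp-level asymmetry in dbinom
  min(1, sum(d[d <= d[ref_count + 1L] * (1 + 1e-7)]))
}

#' Apply the binomial ASE test to an allelic count table
#'
#' Rows with both counts zero are rejected with a message and dropped;
#' remaining rows are annotated with `binom_p` and a significance flag.
#'
#' @param ase data.frame (layout of [read_ase_table()]).
#' @param null_ratio expected reference fraction, default 0.5.
#' @param alpha imbalance significance threshold, default 0.001.
#' @return input with added columns binom_p and imbalanced.
#' @export
ase_test <- function(ase, null_ratio = 0.5, alpha = 0.001) {
  bad <- ase$ref_count + ase$alt_count < 1
  if (any(bad)) {
    message(sum(bad), " ASE row(s) with zero total reads dropped")
    ase <- ase[!bad, , drop = FALSE]
  }
  ase$binom_p <- mapply(binomial_ase, ase$ref_count, ase$alt_count,
                        MoreArgs = list(null_ratio = null_ratio))
  ase$imbalanced <- ase$binom_p < alpha
  rownames(ase) <- NULL
  ase
}

#' LD partners of an index SNP by squared dosage correlation
#'
#' Composite r-squared: the squared Pearson correlation of 0/1/2 genotype
#' dosage vectors (missing genotypes excluded pairwise). Partners within
#' `window_kb` of the index SNP with `r2 >= r2_min` are reported, sorted by
#' r2 descending. Monomorphic SNPs have undefined r2 and are skipped with a
#' message.
#'
#' @param geno list with `map` and `mat` (layout of [read_genotypes()]).
#' @param index_snp snp_id of the index SNP.
#' @param r2_min minimum r-squared, default 0.3.
#' @param window_kb window half-width in kb, default 1000.
#' @return data.frame snp_a (index), snp_b, r2, distance_bp.
#' @export
ld_partners <- function(geno, index_snp, r2_min = 0.3, window_kb = 1000L) {
  map <- geno$map
  i <- match(index_snp, map$snp_id)
  if (is.na(i)) stop("index SNP not in genotype table: ", index_snp)
  x <- geno$mat[i, ]
  if (stats::sd(x, na.rm = TRUE) %in% c(0, NA)) {
    stop("index SNP is monomorphic; r2 undefined")
  }
  in_win <- map$contig == map$contig[i] &
    abs(map$position - map$position[i]) <= window_kb * 1000 &
    seq_len(nrow(map)) != i
  cand <- which(in_win)
  rows <- lapply(cand, function(j) {
    y <- geno$mat[j, ]
    r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
    if (is.na(r)) {
      message("skipping monomorphic SNP ", map$snp_id[j])
      return(NULL)
    }
    r2 <- r^2
    if (r2 < r2_min) return(NULL)
    data.frame(snp_a = index_snp, snp_b = map$snp_id[j], r2 = r2,
               distance_bp = abs(map$position[j] - map$position[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0), distance_bp = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$r2, out$snp_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
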