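# Orchestration: a single config drives the full screen plus every
# downstream statistic, writing one TSV/JSON per stage and a manifest with
# the config hash, seed and per-stage row counts. Output is a pure function
# of (inputs, config, seed).

#' Default pipeline configuration
#'
#' Parameter defaults: match p-value threshold 1e-3, summit flank 50 bp,
#' allele-context flank 20 bp, peak FDR 0.05, per-dataset eQTL rules
#' (CMC FDR < 0.05, LIBD FDR < 0.01, GTEX p < 0.001), 10,000 enrichment and
#' 1000 TF-null simulations, MAF bin 0.05, LD r2 >= 0.3 in a 1 Mb window,
#' ASE significance 0.001.
#'
#' @param input_dir directory laid out by [simulate_study()].
#' @param out_dir output directory for [run_all()].
#' @param seed master seed.
#' @return named list config; paths may be edited before [run_all()].
#' @export
default_config <- function(input_dir, out_dir, seed = 1L) {
  pth <- function(f) file.path(input_dir, f)
  peak_files <- list.files(input_dir, pattern = "^peaks_.*\\.narrowPeak$",
                           full.names = TRUE)
  names(peak_files) <- sub("^peaks_(.*)\\.narrowPeak$", "\\1",
                           basename(peak_files))
  list(
    genome = pth("genome.fa"), motifs = pth("motifs.meme"),
    peaks = as.list(peak_files[sort(names(peak_files))]),
    snps = pth("snps.vcf"),
    annotation = pth("annotation_scores.tsv"), eqtl = pth("eqtl.tsv"),
    ase = pth("ase.tsv"), pool = pth("pool.tsv"),
    tf_pool = pth("tf_pool.tsv"), genotypes = pth("genotypes.tsv"),
    expression = pth("expression.tsv"), stages = pth("stages.tsv"),
    specificity = pth("specificity.tsv"),
    gene_model = pth("gene_model.tsv"),
    out_dir = out_dir,
    alpha = 1e-3, flank_summit = 50L, flank_context = 20L,
    peak_fdr = 0.05, thresholds = default_eqtl_thresholds(),
    n_sims_eqtl = 10000L, n_sims_tf = 1000L, tf_null_m = 132L,
    maf_bin = 0.05, r2_min = 0.3, ld_window_kb = 1000L,
    ase_alpha = 0.001, specificity_cutoff = 0.1, seed = as.integer(seed))
}

validate_config <- function(config) {
  path_keys <- c("genome", "motifs", "snps", "annotation", "eqtl", "ase",
                 "pool", "tf_pool", "genotypes", "expression", "stages",
                 "specificity", "gene_model")
  for (key in path_keys) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p)) {
      stop("config: missing or unreadable input for '", key, "': ",
           p %||% "<unset>")
    }
  }
  for (p in unlist(config$peaks)) {
    if (!file.exists(p)) stop("config: missing peak file ", p)
  }
  for (key in c("alpha", "peak_fdr", "ase_alpha")) {
    v <- config[[key]]
    if (v <= 0 || v > 1) stop("config: ", key, " must be in (0, 1]")
  }
  if (config$flank_summit < 0 || config$flank_context < 0) {
    stop("config: flanks must be >= 0")
  }
  invisible(config)
}

# out_dir is excluded so runs into different directories from identical
# inputs hash identically
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes, in order: format readers, the binding-disruption screen, the
#' per-TF summary, genomic-context classification, per-locus consensus
#' prioritization, the MAF-matched enrichment Z test and TF-count null, eQTL
#' target tiering, binomial ASE tests, LD partner screening, and expression
#' comparisons. Every stage writes a deterministic file under
#' `config$out_dir`; a manifest records the config hash, seed and per-stage
#' row counts.
#'
#' @param config list from [default_config()] (validated before any
#'   compute).
#' @return invisibly, a list of all in-memory stage results.
#' @export
run_all <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()

  genome <- read_genome_fasta(config$genome)
  pwms <- read_meme_motifs(config$motifs)
  peaks <- do.call(rbind, lapply(names(config$peaks), function(tf) {
    read_narrowpeak(config$peaks[[tf]], q_threshold = config$peak_fdr,
                    tf_name = tf)
  }))
  snps <- read_snvs(config$snps, dialect = "vcf")
  counts$snps <- nrow(snps)
  counts$peaks_retained <- nrow(peaks)

  calls <- run_disruption_screen(
    genome, snps, peaks, pwms, alpha = config$alpha,
    flank_summit = config$flank_summit,
    flank_context = config$flank_context)
  write_table(calls, out("disruption_calls.tsv"))
  counts$disruption_calls <- nrow(calls)
  disrupting_ids <- sort(unique(calls$snp_id[calls$disrupts]))
  counts$disrupting_snps <- length(disrupting_ids)

  tf_summary <- summarize_by_tf(calls)
  write_table(tf_summary$per_tf, out("tf_summary.tsv"))
  write_table(tf_summary$co_disruption, out("tf_co_disruption.tsv"))

  gene_model <- read_gene_model(config$gene_model)
  context <- genomic_context(snps, gene_model)
  write_table(context, out("genomic_context.tsv"))

  ann <- read_annotation_scores(config$annotation)
  cons <- consensus(ann)
  write_table(cons$table, out("consensus_snps.tsv"))
  write_table(cons$summary, out("consensus_summary.tsv"))
  counts$consensus_loci <- sum(cons$summary$has_consensus)

  pool <- read_pool_table(config$pool)
  observed <- intersect(disrupting_ids, pool$snp_id)
  enr <- eqtl_enrichment_z(pool, observed, n_sims = config$n_sims_eqtl,
                           bin_width = config$maf_bin,
                           seed = derive_seed(config$seed, "enrichment"))
  jsonlite::write_json(
    list(observed = enr$observed, null_mean = enr$null_mean,
         null_sd = enr$null_sd, z = enr$z, p = enr$p,
         n_sims = enr$n_sims, seed = enr$seed),
    out("enrichment.json"), auto_unbox = TRUE, digits = NA)

  tf_pool <- utils::read.delim(config$tf_pool, stringsAsFactors = FALSE)
  obs_counts <- table(unique(calls[calls$disrupts,
                                   c("snp_id", "tf_name")])$tf_name)
  tf_null <- tf_count_null(tf_pool, m = config$tf_null_m,
                           observed_counts = obs_counts,
                           n_sims = config$n_sims_tf,
                           seed = derive_seed(config$seed, "tf_null"))
  write_table(tf_null, out("tf_count_null.tsv"))

  eqtl <- read_eqtl_table(config$eqtl)
  tiers <- tier_targets(disrupting_ids, eqtl, thresholds = config$thresholds)
  write_table(tiers, out("target_tiers.tsv"))
  counts$targets_any <- length(unique(tiers$snp_id))
  counts$targets_replicated <-
    length(unique(tiers$snp_id[tiers$n_supporting_datasets >= 2]))
  counts$targets_full <-
    length(unique(tiers$snp_id[tiers$n_supporting_datasets >= 3]))

  ase <- ase_test(read_ase_table(config$ase), alpha = config$ase_alpha)
  write_table(ase, out("ase.tsv"))
  counts$ase_imbalanced <- sum(ase$imbalanced)

  geno <- read_genotypes(config$genotypes)
  ld <- if (length(disrupting_ids) &&
            disrupting_ids[1] %in% geno$map$snp_id) {
    ld_partners(geno, disrupting_ids[1], r2_min = config$r2_min,
                window_kb = config$ld_window_kb)
  } else if (nrow(geno$map)) {
    ld_partners(geno, geno$map$snp_id[1], r2_min = config$r2_min,
                window_kb = config$ld_window_kb)
  } else {
    data.frame()
  }
  write_table(ld, out("ld_partners.tsv"))

  expr <- read_expression_matrix(config$expression, config$stages)
  target_genes <- sort(unique(tiers$gene[tiers$n_supporting_datasets >= 2]))
  background_genes <- setdiff(rownames(expr$values),
                              sort(unique(eqtl$gene)))
  cmp <- compare_gene_sets(expr, target_genes, background_genes)
  write_table(data.frame(
    comparison = c("target_vs_background", "prenatal_vs_postnatal"),
    statistic = c(cmp$sets$statistic, cmp$prenatal$statistic),
    p = c(cmp$sets$p, cmp$prenatal$p), stringsAsFactors = FALSE),
    out("expression_tests.tsv"))

  spec <- read_specificity_table(config$specificity)
  ct <- celltype_counts(spec, target_genes,
                        cutoff = config$specificity_cutoff)
  write_table(ct, out("celltype_counts.tsv"))

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   row_counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(calls = calls, tf_summary = tf_summary, context = context,
                 consensus = cons, enrichment = enr, tf_null = tf_null,
                 tiers = tiers, ase = ase, ld = ld, expression_tests = cmp,
                 celltype_counts = ct, counts = counts))
}
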