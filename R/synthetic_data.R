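# Ground-truth generator: produces every input the pipeline consumes, with
# planted signal at stated effect sizes, so each stage is testable without
# external downloads. All generators are deterministic given (parameters,
# seed); seeds for sub-stages are derived from the master seed by stage name.

#' Generate an i.i.d. random genome
#'
#' @param n_contigs number of contigs, default 1.
#' @param length_bp contig length, default 1e6.
#' @param gc GC content in `[0, 1]`, default 0.41 (human-like).
#' @param seed RNG seed.
#' @param prefix contig name prefix, default "chr".
#' @return named character vector of contig sequences.
#' @export
make_genome <- function(n_contigs = 1L, length_bp = 1e6, gc = 0.41,
                        seed = 1L, prefix = "chr") {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(derive_seed(seed, "make_genome"), {
    genome <- vapply(seq_len(n_contigs), function(i) {
      decode_seq(sample.int(4L, length_bp, replace = TRUE, prob = probs))
    }, character(1))
    names(genome) <- paste0(prefix, seq_len(n_contigs))
    genome
  })
}

#' Generate random informative PWMs
#'
#' Each column concentrates `dominance` probability on one random base and
#' splits the remainder over the other three, giving motifs whose consensus
#' match is far beyond the 1e-3 significance threshold at widths >= 8.
#'
#' @param tf_names motif/TF names.
#' @param widths motif widths (recycled against `tf_names`).
#' @param dominance per-column probability of the consensus base,
#'   default 0.9.
#' @param seed RNG seed.
#' @return named list of `pwm` objects with uniform background.
#' @export
random_pwms <- function(tf_names, widths, dominance = 0.9, seed = 1L) {
  widths <- rep_len(widths, length(tf_names))
  with_seed(derive_seed(seed, "random_pwms"), {
    pwms <- lapply(seq_along(tf_names), function(k) {
      w <- widths[k]
      probs <- matrix((1 - dominance) / 3, nrow = w, ncol = 4)
      top <- sample.int(4L, w, replace = TRUE)
      probs[cbind(seq_len(w), top)] <- dominance
      pwm(tf_names[k], probs)
    })
    names(pwms) <- tf_names
    pwms
  })
}

#' Plant motif instances and matching peaks into a genome
#'
#' Writes each PWM's consensus at non-overlapping random positions on random
#' strands and emits one peak per site with the summit at the site centre
#' plus a bounded jitter, q-values above the retention threshold.
#'
#' @param genome named character vector of contigs.
#' @param pwms list of `pwm` objects (names = TF names).
#' @param n_sites_per_tf planted instances per TF, default 10.
#' @param summit_jitter_bp max |summit - site centre|, default 5 (<= 10).
#' @param peak_halfwidth peak extension beyond the site (bp), default 100.
#' @param min_gap minimum spacing between planted sites (bp), default 300.
#' @param seed RNG seed.
#' @return list: `genome` (edited), `peaks` (data.frame in
#'   [read_narrowpeak()] layout), `sites` (data.frame tf, contig, start,
#'   strand, width).
#' @export
plant_motifs_and_peaks <- function(genome, pwms, n_sites_per_tf = 10L,
                                   summit_jitter_bp = 5L,
                                   peak_halfwidth = 100L, min_gap = 300L,
                                   seed = 1L) {
  if (summit_jitter_bp > 10L) stop("summit_jitter_bp must be <= 10")
  margin <- 1000L
  with_seed(derive_seed(seed, "plant_motifs"), {
    taken <- list()  # per contig: matrix of occupied [start, end)
    sites <- list()
    peak_rows <- list()
    for (tf in names(pwms)) {
      p <- pwms[[tf]]
      w <- p$width
      cons <- consensus_seq(p)
      for (k in seq_len(n_sites_per_tf)) {
        placed <- FALSE
        for (try in seq_len(10000L)) {
          contig <- sample(names(genome), 1L)
          len <- nchar(genome[[contig]])
          if (len < 2L * margin + w) next
          start <- sample.int(len - w - 2L * margin, 1L) + margin
          occ <- taken[[contig]]
          clash <- !is.null(occ) &&
            any(start < occ[, 2] + min_gap & start + w + min_gap > occ[, 1])
          if (clash) next
          strand <- sample(c("+", "-"), 1L)
          written <- if (strand == "+") cons else revcomp(cons)
          substr(genome[[contig]], start + 1L, start + w) <- written
          taken[[contig]] <- rbind(occ, c(start, start + w))
          centre <- start + w %/% 2L
          jitter <- if (summit_jitter_bp > 0) {
            sample(seq.int(-summit_jitter_bp, summit_jitter_bp), 1L)
          } else 0L
          summit <- centre + jitter
          pstart <- max(start - peak_halfwidth, 0L)
          pend <- min(start + w + peak_halfwidth, len)
          sites[[length(sites) + 1L]] <- data.frame(
            tf = tf, contig = contig, start = start, strand = strand,
            width = w, stringsAsFactors = FALSE)
          peak_rows[[length(peak_rows) + 1L]] <- data.frame(
            contig = contig, start = pstart, end = pend,
            summit_offset = summit - pstart,
            neg_log10_q = round(runif(1, 2, 8), 3),
            tf_name = tf, peak_id = sprintf("%s_peak_%02d", tf, k),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("insufficient room to place all motif sites; ",
               "reduce n_sites_per_tf or enlarge the genome")
        }
      }
    }
    list(genome = genome, peaks = do.call(rbind, peak_rows),
         sites = do.call(rbind, sites))
  })
}

#' Plant disrupting and benign SNPs around the planted sites
#'
#' Disrupting SNPs sit at maximally informative motif columns with the
#' alternative allele set to the column's lowest-probability base (worst-case
#' swap); benign-in-peak SNPs sit inside summit windows but outside every
#' motif; outside-peak SNPs lie beyond every summit flank. MAFs are drawn
#' uniform(0.05, 0.5).
#'
#' @param genome edited genome from [plant_motifs_and_peaks()].
#' @param sites,peaks the planted sites and peaks.
#' @param pwms the PWM list used for planting.
#' @param n_disrupting,n_benign_in_peak,n_outside_peak class sizes,
#'   defaults 50/75/75.
#' @param flank_summit summit window half-width used downstream, default 50.
#' @param seed RNG seed.
#' @return list: `snps` (SNV data.frame), `truth` (lists of snp_ids per
#'   class and the disrupting SNP -> TF map).
#' @export
plant_snps <- function(genome, sites, peaks, pwms, n_disrupting = 50L,
                       n_benign_in_peak = 75L, n_outside_peak = 75L,
                       flank_summit = 50L, seed = 1L) {
  summits <- data.frame(contig = peaks$contig,
                        pos = peaks$start + peaks$summit_offset)
  in_any_site <- function(contig, pos) {
    s <- sites[sites$contig == contig, , drop = FALSE]
    any(pos >= s$start & pos < s$start + s$width)
  }
  near_any_summit <- function(contig, pos, dist) {
    s <- summits[summits$contig == contig, , drop = FALSE]
    any(abs(pos - s$pos) <= dist)
  }
  with_seed(derive_seed(seed, "plant_snps"), {
    used <- character(0)
    rows <- list()
    # disrupting: cycle sites, next-most-informative unused column each pass
    site_order <- sample.int(nrow(sites))
    col_cursor <- integer(nrow(sites))
    si <- 0L
    for (i in seq_len(n_disrupting)) {
      found <- FALSE
      for (pass in seq_len(nrow(sites))) {
        si <- si %% nrow(sites) + 1L
        s <- sites[site_order[si], ]
        p <- pwms[[s$tf]]
        info_order <- order(apply(p$probs, 1, max), decreasing = TRUE)
        cur <- col_cursor[site_order[si]] + 1L
        if (cur > s$width) next
        col_cursor[site_order[si]] <- cur
        col <- info_order[cur]
        gpos <- if (s$strand == "+") s$start + col - 1L else s$start + s$width - col
        key <- paste(s$contig, gpos)
        if (key %in% used) next
        used <- c(used, key)
        ref <- genome_fetch(genome, s$contig, gpos, gpos + 1L)
        worst <- BASES[which.min(p$probs[col, ])]
        alt <- if (s$strand == "+") worst else comp_base(worst)
        stopifnot(ref != alt)
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = sprintf("rsd%04d", i), contig = s$contig,
          position = gpos, ref = ref, alt = alt, tf = s$tf,
          class = "disrupting", stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
      if (!found) stop("infeasible placement: not enough motif columns for ",
                       n_disrupting, " disrupting SNPs")
    }
    place <- function(n, id_fmt, class, pick_pos) {
      for (i in seq_len(n)) {
        for (try in seq_len(10000L)) {
          cand <- pick_pos()
          key <- paste(cand$contig, cand$pos)
          if (key %in% used) next
          if (cand$ok) {
            used <<- c(used, key)
            ref <- genome_fetch(genome, cand$contig, cand$pos, cand$pos + 1L)
            alt <- sample(setdiff(BASES, ref), 1L)
            rows[[length(rows) + 1L]] <<- data.frame(
              snp_id = sprintf(id_fmt, i), contig = cand$contig,
              position = cand$pos, ref = ref, alt = alt, tf = NA_character_,
              class = class, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    place(n_benign_in_peak, "rsb%04d", "benign_in_peak", function() {
      k <- sample.int(nrow(summits), 1L)
      contig <- summits$contig[k]
      pos <- summits$pos[k] + sample(seq.int(-flank_summit, flank_summit), 1L)
      len <- nchar(genome[[contig]])
      list(contig = contig, pos = pos,
           ok = pos >= 30L && pos < len - 30L && !in_any_site(contig, pos))
    })
    place(n_outside_peak, "rso%04d", "outside_peak", function() {
      contig <- sample(names(genome), 1L)
      len <- nchar(genome[[contig]])
      pos <- sample.int(len - 60L, 1L) + 30L
      list(contig = contig, pos = pos,
           ok = !near_any_summit(contig, pos, flank_summit + 30L) &&
             !in_any_site(contig, pos))
    })
    df <- do.call(rbind, rows)
    df$maf <- round(runif(nrow(df), 0.05, 0.5), 4)
    df$locus_id <- NA_character_
    snps <- df[, c("snp_id", "contig", "position", "ref", "alt", "maf",
                   "locus_id")]
    truth <- list(
      disrupting = df$snp_id[df$class == "disrupting"],
      benign_in_peak = df$snp_id[df$class == "benign_in_peak"],
      outside_peak = df$snp_id[df$class == "outside_peak"],
      disrupting_tf = stats::setNames(df$tf[df$class == "disrupting"],
                                      df$snp_id[df$class == "disrupting"]))
    list(snps = snps, truth = truth)
  })
}

#' Generate five-annotator score tables with a planted consensus SNP
#'
#' In a `planted_fraction` of loci one SNP receives the locus maximum in two
#' randomly chosen scoring methods (plus the best RegulomeDB rating);
#' remaining scores are i.i.d. continuous draws, so ties have probability
#' zero.
#'
#' @param n_loci number of loci, default 100.
#' @param snps_per_locus SNPs per locus (>= 2), default 5.
#' @param planted_fraction fraction of loci with a planted consensus SNP,
#'   default 1.
#' @param seed RNG seed.
#' @return list: `rows` (annotation data.frame), `truth` (named character
#'   vector locus_id -> planted snp_id).
#' @export
make_annotation_scores <- function(n_loci = 100L, snps_per_locus = 5L,
                                   planted_fraction = 1, seed = 1L) {
  if (snps_per_locus < 2L) stop("each locus needs at least 2 SNPs")
  ratings <- c(t(outer(1:3, letters[1:6], paste0)), "4", "5", "6")
  with_seed(derive_seed(seed, "annotation_scores"), {
    n <- n_loci * snps_per_locus
    rows <- data.frame(
      snp_id = sprintf("rsa%05d", seq_len(n)),
      locus_id = rep(sprintf("L%03d", seq_len(n_loci)),
                     each = snps_per_locus),
      cadd = runif(n, 0, 30), eigen = runif(n, -4, 20),
      gwava = runif(n, 0, 1), linsight = runif(n, 0, 1),
      regulomedb = sample(setdiff(ratings, "1a"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    n_planted <- round(planted_fraction * n_loci)
    planted <- character(0)
    for (L in seq_len(n_planted)) {
      i0 <- (L - 1L) * snps_per_locus + 1L
      idx <- i0:(i0 + snps_per_locus - 1L)
      star <- sample(idx, 1L)
      for (m in sample(SCORING_METHODS, 2L)) {
        rows[[m]][star] <- max(rows[[m]][idx]) + runif(1, 0.5, 1)
      }
      rows$regulomedb[star] <- "1a"
      planted[sprintf("L%03d", L)] <- rows$snp_id[star]
    }
    list(rows = rows, truth = planted)
  })
}

#' Generate a SNP pool for enrichment resampling
#'
#' @param n pool size, default 20000.
#' @param eqtl_rate background eQTL-significance rate, default 0.3.
#' @param seed RNG seed.
#' @param extra optional data.frame (snp_id, maf, eqtl_flag) appended to the
#'   pool, e.g. the fixture's own SNPs.
#' @return pool data.frame snp_id, maf, eqtl_flag, tf.
#' @export
make_enrichment_pool <- function(n = 20000L, eqtl_rate = 0.3, seed = 1L,
                                 extra = NULL) {
  with_seed(derive_seed(seed, "enrichment_pool"), {
    pool <- data.frame(
      snp_id = sprintf("pool%06d", seq_len(n)),
      maf = round(runif(n, 0.01, 0.5), 4),
      eqtl_flag = runif(n) < eqtl_rate,
      tf = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(extra)) {
      extra$tf <- extra$tf %||% NA_character_
      pool <- rbind(pool, extra[, c("snp_id", "maf", "eqtl_flag", "tf")])
    }
    pool
  })
}

#' Generate a TF-labelled disruption pool for the per-TF count null
#'
#' @param n pool size, default 8447.
#' @param tf_names TF labels.
#' @param shares sampling weight per TF (normalized), default equal.
#' @param seed RNG seed.
#' @return data.frame snp_id, tf (exactly one label per SNP).
#' @export
make_tf_pool <- function(n = 8447L, tf_names, shares = NULL, seed = 1L) {
  shares <- shares %||% rep(1, length(tf_names))
  with_seed(derive_seed(seed, "tf_pool"), {
    data.frame(snp_id = sprintf("tfp%05d", seq_len(n)),
               tf = sample(tf_names, n, replace = TRUE,
                           prob = shares / sum(shares)),
               stringsAsFactors = FALSE)
  })
}

#' Generate eQTL, ASE, expression and specificity tables with planted signal
#'
#' Disrupting SNPs are eQTL-significant at `enriched_rate` per dataset
#' (independently), all other SNPs at `background_rate`; each SNP keeps one
#' target gene across datasets so multi-dataset tiering is recoverable. ASE
#' counts are Binomial(n_reads, 0.5) except for disrupting SNPs, which use
#' the stated imbalance ratio. Target-gene expression is elevated overall
#' and additionally in prenatal stages.
#'
#' @param disrupting_ids,benign_ids SNP id vectors from [plant_snps()].
#' @param datasets eQTL dataset names, default CMC/LIBD/GTEX.
#' @param enriched_rate,background_rate per-dataset significance rates,
#'   defaults 0.6 and 0.3.
#' @param ase_n_reads total reads per ASE site, default 50.
#' @param ase_imbalance_ratio reference-allele fraction at imbalanced SNPs,
#'   default 0.9.
#' @param overall_shift log2 elevation of target genes across all stages,
#'   default 1.
#' @param prenatal_shift additional log2 elevation in prenatal stages,
#'   default 0.8.
#' @param n_background_genes background gene count, default 400.
#' @param n_stages total stages (half prenatal), default 12.
#' @param seed RNG seed.
#' @return list: eqtl, ase, expression (`stage_expr`), stage_meta,
#'   specificity, target_genes, truth (imbalanced ids, shifts, rates).
#' @export
make_eqtl_ase_expression <- function(disrupting_ids, benign_ids,
                                     datasets = c("CMC", "LIBD", "GTEX"),
                                     enriched_rate = 0.6,
                                     background_rate = 0.3,
                                     ase_n_reads = 50L,
                                     ase_imbalance_ratio = 0.9,
                                     overall_shift = 1,
                                     prenatal_shift = 0.8,
                                     n_background_genes = 400L,
                                     n_stages = 12L, seed = 1L) {
  thresholds <- default_eqtl_thresholds()
  with_seed(derive_seed(seed, "eqtl_ase_expression"), {
    all_ids <- c(disrupting_ids, benign_ids)
    is_dis <- all_ids %in% disrupting_ids
    gene_of <- stats::setNames(
      ifelse(is_dis,
             sprintf("TG%03d", (cumsum(is_dis) + 1L) %/% 2L)[seq_along(all_ids)],
             sprintf("NG%03d", seq_along(all_ids))),
      all_ids)
    gtex_tissues <- c("Cortex", "Cerebellum", "Caudate", "Hypothalamus")
    eqtl_rows <- list()
    for (ds in datasets) {
      rule <- thresholds[[ds]]
      rate <- ifelse(is_dis, enriched_rate, background_rate)
      sig <- runif(length(all_ids)) < rate
      val_sig <- runif(length(all_ids), 1e-10, rule$cutoff * 0.9)
      val_ns <- runif(length(all_ids), rule$cutoff * 1.5, 1)
      val <- ifelse(sig, val_sig, val_ns)
      p <- if (rule$metric == "p") val else val / 10
      fdr <- if (rule$metric == "fdr") val else NA_real_
      tissue <- if (ds == "GTEX") {
        sample(gtex_tissues, length(all_ids), replace = TRUE)
      } else "DLPFC"
      eqtl_rows[[ds]] <- data.frame(
        snp_id = all_ids, gene = unname(gene_of[all_ids]), dataset = ds,
        tissue = tissue, p = p, fdr = fdr, stringsAsFactors = FALSE)
    }
    eqtl <- do.call(rbind, eqtl_rows)
    rownames(eqtl) <- NULL
    ase <- data.frame(
      snp_id = all_ids, tissue = "Cortex",
      ref_count = rbinom(length(all_ids), ase_n_reads,
                         ifelse(is_dis, ase_imbalance_ratio, 0.5)),
      stringsAsFactors = FALSE)
    ase$alt_count <- ase_n_reads - ase$ref_count
    target_genes <- sort(unique(gene_of[disrupting_ids]))
    bg_genes <- sprintf("BG%04d", seq_len(n_background_genes))
    genes <- c(target_genes, bg_genes)
    n_pre <- n_stages %/% 2L
    stages <- sprintf("stage_%02d", seq_len(n_stages))
    is_pre <- seq_len(n_stages) <= n_pre
    base <- rnorm(length(genes), 3, 0.5) +
      ifelse(genes %in% target_genes, overall_shift, 0)
    log2v <- outer(base, rep(0, n_stages), `+`) +
      matrix(rnorm(length(genes) * n_stages, 0, 0.5),
             nrow = length(genes)) +
      outer(as.numeric(genes %in% target_genes),
            ifelse(is_pre, prenatal_shift, 0))
    values <- 2^log2v
    rownames(values) <- genes
    expr <- stage_expr(values, stages, is_pre)
    cell_types <- c("pyramidal_SS", "pyramidal_CA1",
                    sprintf("celltype_%02d", seq_len(22L)))
    spec <- expand.grid(gene = genes, cell_type = cell_types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    spec$specificity <- round(rbeta(nrow(spec), 1, 12), 4)
    boost <- spec$cell_type == "pyramidal_SS" &
      spec$gene %in% target_genes & runif(nrow(spec)) < 0.6
    spec$specificity[boost] <- round(runif(sum(boost), 0.15, 0.5), 4)
    list(eqtl = eqtl, ase = ase, expression = expr,
         stage_meta = data.frame(stage = stages, prenatal = is_pre,
                                 stringsAsFactors = FALSE),
         specificity = spec, target_genes = target_genes,
         truth = list(imbalanced_ase_snp_ids = disrupting_ids,
                      enriched_eqtl_rate = enriched_rate,
                      background_eqtl_rate = background_rate,
                      overall_shift = overall_shift,
                      prenatal_shift = prenatal_shift,
                      gene_of = as.list(gene_of)))
  })
}

#' Generate a genotype matrix with planted LD partners
#'
#' The index SNP gets `n_ld_partners` exact copies (r2 = 1) and
#' `n_independent` independently drawn SNPs in the surrounding window.
#'
#' @param index_id snp_id for the index SNP.
#' @param contig,position index SNP location.
#' @param n_ld_partners,n_independent partner counts, defaults 5 and 200.
#' @param n_samples samples, default 300.
#' @param seed RNG seed.
#' @return list(map, mat) in the [read_genotypes()] layout.
#' @export
make_genotypes <- function(index_id, contig = "chr1", position = 500000L,
                           n_ld_partners = 5L, n_independent = 200L,
                           n_samples = 300L, seed = 1L) {
  with_seed(derive_seed(seed, "genotypes"), {
    x <- rbinom(n_samples, 2, 0.3)
    n_tot <- 1L + n_ld_partners + n_independent
    mat <- matrix(NA_real_, nrow = n_tot, ncol = n_samples)
    mat[1, ] <- x
    for (j in seq_len(n_ld_partners)) mat[1L + j, ] <- x
    for (j in seq_len(n_independent)) {
      mat[1L + n_ld_partners + j, ] <- rbinom(n_samples, 2, runif(1, 0.05, 0.5))
    }
    ids <- c(index_id, sprintf("ldpar%03d", seq_len(n_ld_partners)),
             sprintf("ldind%04d", seq_len(n_independent)))
    offs <- c(0L, seq_len(n_ld_partners) * 1000L,
              seq_len(n_independent) * 997L + 50000L)
    rownames(mat) <- ids
    colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
    list(map = data.frame(snp_id = ids, contig = contig,
                          position = position + offs,
                          stringsAsFactors = FALSE),
         mat = mat)
  })
}

#' Generate a simple gene model for genomic-context annotation
#'
#' @param genome named character vector of contigs.
#' @param n_genes genes per contig, default 15.
#' @param seed RNG seed (placement only).
#' @return interval data.frame in the [read_gene_model()] layout.
#' @export
make_gene_model <- function(genome, n_genes = 15L, seed = 1L) {
  with_seed(derive_seed(seed, "gene_model"), {
    rows <- list()
    for (contig in names(genome)) {
      len <- nchar(genome[[contig]])
      span <- len %/% (n_genes + 1L)
      for (i in seq_len(n_genes)) {
        gstart <- (i - 1L) * span + span %/% 4L
        gend <- gstart + min(10000L, span %/% 2L)
        strand <- sample(c("+", "-"), 1L)
        g <- sprintf("%s_gene%02d", contig, i)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig,
          start = c(gstart, gstart, gstart + 500L,
                    gstart + (gend - gstart) %/% 2L),
          end = c(gend, gstart + 500L, gstart + 800L,
                  gstart + (gend - gstart) %/% 2L + 300L),
          type = c("gene", "UTR", "exon", "exon"),
          gene = g, strand = strand, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a complete study fixture on disk
#'
#' Generates the genome, motifs, peaks, SNVs, annotation tables, eQTL/ASE
#' tables, pools, genotypes, expression matrices and gene model; writes every
#' file in its external format plus a `truth.json` recording the planted
#' signal. Bit-reproducible given (parameters, seed).
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; every sub-generator derives its own stream.
#' @param length_bp genome length, default 1e6.
#' @param tf_names,widths TFs and motif widths, defaults TFA/TFB/TFC at
#'   8/10/12.
#' @param n_sites_per_tf planted sites per TF, default 10.
#' @param n_disrupting,n_benign_in_peak,n_outside_peak SNP class sizes,
#'   defaults 50/75/75.
#' @param ... further parameters forwarded to
#'   [make_eqtl_ase_expression()].
#' @return invisibly, a list with `truth`, `paths` and the in-memory pieces.
#' @export
simulate_study <- function(dir, seed = 1L, length_bp = 1e6,
                           tf_names = c("TFA", "TFB", "TFC"),
                           widths = c(8L, 10L, 12L),
                           n_sites_per_tf = 10L, n_disrupting = 50L,
                           n_benign_in_peak = 75L, n_outside_peak = 75L,
                           ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  pwms <- random_pwms(tf_names, widths, seed = seed)
  genome <- make_genome(length_bp = length_bp, seed = seed)
  planted <- plant_motifs_and_peaks(genome, pwms,
                                    n_sites_per_tf = n_sites_per_tf,
                                    seed = seed)
  snp_out <- plant_snps(planted$genome, planted$sites, planted$peaks, pwms,
                        n_disrupting = n_disrupting,
                        n_benign_in_peak = n_benign_in_peak,
                        n_outside_peak = n_outside_peak, seed = seed)
  ann <- make_annotation_scores(seed = seed)
  downstream <- make_eqtl_ase_expression(
    disrupting_ids = snp_out$truth$disrupting,
    benign_ids = c(snp_out$truth$benign_in_peak,
                   snp_out$truth$outside_peak),
    seed = seed, ...)
  fixture_pool_rows <- data.frame(
    snp_id = snp_out$snps$snp_id, maf = snp_out$snps$maf,
    eqtl_flag = vapply(snp_out$snps$snp_id, function(s) {
      any(downstream$eqtl$snp_id == s & downstream$eqtl$dataset == "CMC" &
            downstream$eqtl$fdr < 0.05)
    }, logical(1)),
    tf = NA_character_, stringsAsFactors = FALSE)
  pool <- make_enrichment_pool(seed = seed, extra = fixture_pool_rows)
  tf_pool <- make_tf_pool(tf_names = tf_names, seed = seed)
  geno <- make_genotypes(index_id = snp_out$truth$disrupting[1],
                         contig = names(genome)[1],
                         position = snp_out$snps$position[1], seed = seed)
  gene_model <- make_gene_model(planted$genome, seed = seed)

  write_genome_fasta(planted$genome, pth("genome.fa"))
  write_meme_motifs(pwms, pth("motifs.meme"))
  peak_paths <- character(0)
  for (tf in tf_names) {
    f <- pth(sprintf("peaks_%s.narrowPeak", tf))
    write_narrowpeak(planted$peaks[planted$peaks$tf_name == tf, ], f)
    peak_paths[tf] <- f
  }
  write_snvs_vcf(snp_out$snps, pth("snps.vcf"))
  write_table(ann$rows, pth("annotation_scores.tsv"))
  write_table(downstream$eqtl, pth("eqtl.tsv"))
  write_table(downstream$ase, pth("ase.tsv"))
  write_table(pool, pth("pool.tsv"))
  write_table(tf_pool, pth("tf_pool.tsv"))
  geno_df <- cbind(geno$map, as.data.frame(geno$mat))
  write_table(geno_df, pth("genotypes.tsv"))
  expr_df <- data.frame(gene = rownames(downstream$expression$values),
                        downstream$expression$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_table(expr_df, pth("expression.tsv"))
  write_table(downstream$stage_meta, pth("stages.tsv"))
  write_table(downstream$specificity, pth("specificity.tsv"))
  write_table(gene_model, pth("gene_model.tsv"))

  truth <- c(snp_out$truth,
             list(sites = planted$sites,
                  consensus_snp_by_locus = as.list(ann$truth),
                  target_genes = downstream$target_genes),
             downstream$truth)
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- list(
    genome = pth("genome.fa"), motifs = pth("motifs.meme"),
    peaks = as.list(peak_paths), snps = pth("snps.vcf"),
    annotation = pth("annotation_scores.tsv"), eqtl = pth("eqtl.tsv"),
    ase = pth("ase.tsv"), pool = pth("pool.tsv"),
    tf_pool = pth("tf_pool.tsv"), genotypes = pth("genotypes.tsv"),
    expression = pth("expression.tsv"), stages = pth("stages.tsv"),
    specificity = pth("specificity.tsv"),
    gene_model = pth("gene_model.tsv"), truth = pth("truth.json"))
  invisible(list(truth = truth, paths = paths, pwms = pwms,
                 genome = planted$genome, peaks = planted$peaks,
                 sites = planted$sites, snps = snp_out$snps,
                 annotation = ann$rows, downstream = downstream,
                 pool = pool, tf_pool = tf_pool, genotypes = geno,
                 gene_model = gene_model))
}
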