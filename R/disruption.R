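# Allele-aware scanning of SNP-centred windows inside ChIP-Seq peak-summit
# neighbourhoods, and the TF binding-disruption verdict: a SNP disrupts a
# motif when at least one allele's best overlapping window attains a match
# p-value below alpha (default 1e-3).

snv_condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Pair SNPs with peaks whose summit lies within a flank
#'
#' A SNP pairs with every retained peak (any TF) whose summit is within
#' `flank` bp on the same contig; `|position - summit| <= flank`.
#'
#' @param snps SNV data.frame (layout of [read_snvs()]).
#' @param peaks peak data.frame (layout of [read_narrowpeak()]), already
#'   FDR-filtered.
#' @param flank window half-width in bp, default 50.
#' @return data.frame with columns snp_id, peak_id, tf_name, snp_row,
#'   peak_row.
#' @export
snps_in_summit_windows <- function(snps, peaks, flank = 50L) {
  empty <- data.frame(snp_id = character(0), peak_id = character(0),
                      tf_name = character(0), snp_row = integer(0),
                      peak_row = integer(0), stringsAsFactors = FALSE)
  if (!nrow(snps) || !nrow(peaks)) return(empty)
  if (flank < 0) stop("flank must be >= 0")
  summit <- peaks$start + peaks$summit_offset
  win <- GenomicRanges::GRanges(
    peaks$contig,
    IRanges::IRanges(start = pmax(summit - flank, 0L) + 1L,
                     end = summit + flank + 1L))
  pts <- GenomicRanges::GRanges(
    snps$contig, IRanges::IRanges(start = snps$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, win)
  si <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  out <- data.frame(snp_id = snps$snp_id[si], peak_id = peaks$peak_id[pi],
                    tf_name = peaks$tf_name[pi], snp_row = si, peak_row = pi,
                    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$tf_name, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the two allele contexts around a SNP
#'
#' Returns two sequences of length `2 * flank + 1` differing only at the
#' centre base. The genome base at the SNP position must equal the declared
#' reference allele; mismatches raise a catchable condition rather than being
#' silently flipped.
#'
#' @param genome named character vector of contigs.
#' @param snp one-row SNV data.frame (or list) with contig, position, ref,
#'   alt.
#' @param flank context half-width in bp, default 20.
#' @return list with ref_seq, alt_seq, snp_index (0-based centre offset).
#' @export
allele_context <- function(genome, snp, flank = 20L) {
  contig <- snp$contig
  pos <- snp$position
  if (!contig %in% names(genome)) {
    stop(snv_condition("regsnpscan_boundary", paste("unknown contig", contig)))
  }
  len <- nchar(genome[[contig]])
  if (pos < flank || pos + flank >= len) {
    stop(snv_condition("regsnpscan_boundary",
                       sprintf("SNP %s at %s:%d is within %d bp of a contig end",
                               snp$snp_id %||% "?", contig, pos, flank)))
  }
  ref_seq <- genome_fetch(genome, contig, pos - flank, pos + flank + 1L)
  centre <- substr(ref_seq, flank + 1L, flank + 1L)
  if (centre != snp$ref) {
    stop(snv_condition("regsnpscan_ref_mismatch",
                       sprintf("reference mismatch at %s:%d: genome has %s, ref_allele %s",
                               contig, pos, centre, snp$ref)))
  }
  alt_seq <- ref_seq
  substr(alt_seq, flank + 1L, flank + 1L) <- snp$alt
  list(ref_seq = ref_seq, alt_seq = alt_seq, snp_index = as.integer(flank))
}

# Best match over all windows overlapping the SNP position by >= 1 bp, both
# strands. Returns best score/p-value/window/strand and the number of scored
# (N-free) window x strand combinations.
allele_scan <- function(lom, dist, seq, snp_index) {
  codes <- encode_seq(seq)
  w <- lom$width
  L <- length(codes)
  s0 <- max(0L, snp_index - w + 1L)
  s1 <- min(L - w, snp_index)
  if (s1 < s0) {
    stop(snv_condition("regsnpscan_no_window",
                       "context too short for any motif window"))
  }
  starts <- s0:s1
  res <- data.frame(start = integer(0), strand = character(0),
                    int = numeric(0), dbl = numeric(0))
  for (strand in c("+", "-")) {
    Eint <- if (strand == "+") lom$int_entries else rc_entries(lom$int_entries)
    Edbl <- if (strand == "+") lom$entries else rc_entries(lom$entries)
    sub <- codes[(s0 + 1L):(s1 + w)]
    sc <- strand_scores(sub, Eint, Edbl)
    res <- rbind(res, data.frame(start = starts, strand = strand,
                                 int = sc$int, dbl = sc$dbl,
                                 stringsAsFactors = FALSE))
  }
  ok <- !is.na(res$int)
  if (!any(ok)) {
    stop(snv_condition("regsnpscan_no_window",
                       "all windows overlapping the SNP contain N"))
  }
  res <- res[ok, , drop = FALSE]
  res$pvalue <- score_pvalue(dist, res$int)
  best <- res[order(res$pvalue, -res$dbl, res$start, res$strand), ][1, ]
  list(best_score = best$dbl, best_pvalue = best$pvalue,
       best_window_start = best$start, best_strand = best$strand,
       n_windows_scored = nrow(res))
}

#' Allele-aware disruption call for one SNP x motif pair
#'
#' Scores every motif window overlapping the SNP (both strands) for each
#' allele context and applies the verdict rule: the SNP disrupts the motif
#' when one or more alleles attain a best match p-value below `alpha`.
#'
#' @param lom `log_odds_matrix`.
#' @param dist matching `score_dist`.
#' @param ref_seq,alt_seq allele contexts differing only at `snp_index`.
#' @param snp_index 0-based offset of the SNP within the contexts.
#' @param alpha match p-value threshold, default 1e-3.
#' @return list with `ref` and `alt` per-allele scan results (best_score,
#'   best_pvalue, best_window_start, best_strand, n_windows_scored),
#'   `disrupts`, and `delta_llr` (ref best score minus alt best score).
#' @export
call_disruption <- function(lom, dist, ref_seq, alt_seq, snp_index,
                            alpha = 1e-3) {
  ref <- allele_scan(lom, dist, ref_seq, snp_index)
  alt <- allele_scan(lom, dist, alt_seq, snp_index)
  list(ref = ref, alt = alt,
       disrupts = (ref$best_pvalue < alpha) || (alt$best_pvalue < alpha),
       delta_llr = ref$best_score - alt$best_score)
}

#' Run the full binding-disruption screen
#'
#' Pairs SNPs with FDR-retained peak summits, extracts both allele contexts,
#' scans every motif whose name matches the peak's TF, and emits one
#' disruption call per (SNP, TF) after deduplication (the call with the
#' smallest min-allele p-value wins). Per-record failures (reference
#' mismatches, contig-end SNPs, all-N contexts) are collected in the
#' `skipped` attribute, never fatal.
#'
#' @param genome named character vector of contigs.
#' @param snps SNV data.frame.
#' @param peaks FDR-filtered peak data.frame.
#' @param pwms list of `pwm` objects; motif names are matched to
#'   `peaks$tf_name`.
#' @param alpha match p-value threshold, default 1e-3.
#' @param flank_summit summit pairing half-width (bp), default 50.
#' @param flank_context allele context half-width (bp), default 20.
#' @param pseudocount_frac,scale passed to [build_log_odds()].
#' @param differential if TRUE, additionally require that exactly one allele
#'   passes and `delta_llr != 0` (off by default: the verdict rule is
#'   one-or-more alleles passing).
#' @return data.frame, one row per retained (SNP, TF) call, ordered by
#'   snp_id then tf_name, with attribute `skipped` (data.frame snp_id,
#'   tf_name, reason).
#' @export
run_disruption_screen <- function(genome, snps, peaks, pwms, alpha = 1e-3,
                                  flank_summit = 50L, flank_context = 20L,
                                  pseudocount_frac = 0.1, scale = 1000L,
                                  differential = FALSE) {
  loms <- lapply(pwms, build_log_odds, pseudocount_frac = pseudocount_frac,
                 scale = scale)
  dists <- lapply(loms, exact_pvalue_table)
  motif_names <- vapply(pwms, function(p) p$name, character(1))
  pairs <- snps_in_summit_windows(snps, peaks, flank = flank_summit)
  rows <- vector("list", nrow(pairs))
  skipped <- list()
  for (k in seq_len(nrow(pairs))) {
    tf <- pairs$tf_name[k]
    mi <- which(motif_names == tf)
    if (!length(mi)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp_id = pairs$snp_id[k], tf_name = tf,
        reason = "no motif for TF", stringsAsFactors = FALSE)
      next
    }
    snp <- snps[pairs$snp_row[k], ]
    result <- tryCatch({
      ctx <- allele_context(genome, snp, flank = flank_context)
      call <- call_disruption(loms[[mi]], dists[[mi]], ctx$ref_seq,
                              ctx$alt_seq, ctx$snp_index, alpha = alpha)
      better <- if (call$ref$best_pvalue <= call$alt$best_pvalue) {
        call$ref
      } else {
        call$alt
      }
      disrupts <- call$disrupts
      if (differential) {
        one_passes <- xor(call$ref$best_pvalue < alpha,
                          call$alt$best_pvalue < alpha)
        disrupts <- disrupts && one_passes && call$delta_llr != 0
      }
      data.frame(
        snp_id = snp$snp_id, tf_name = tf, motif = motif_names[mi],
        peak_id = pairs$peak_id[k],
        ref_best_score = call$ref$best_score,
        ref_best_p = call$ref$best_pvalue,
        alt_best_score = call$alt$best_score,
        alt_best_p = call$alt$best_pvalue,
        delta_llr = call$delta_llr, disrupts = disrupts,
        window_start = snp$position - flank_context + better$best_window_start,
        strand = better$best_strand, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(snp_id = snp$snp_id, tf_name = tf,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if ("reason" %in% names(result)) {
      skipped[[length(skipped) + 1L]] <- result
    } else {
      rows[[k]] <- result
    }
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(snp_id = character(0), tf_name = character(0),
                        motif = character(0), peak_id = character(0),
                        ref_best_score = numeric(0), ref_best_p = numeric(0),
                        alt_best_score = numeric(0), alt_best_p = numeric(0),
                        delta_llr = numeric(0), disrupts = logical(0),
                        window_start = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  } else {
    # dedup per (snp, tf): keep the strongest call (smallest min-allele p)
    minp <- pmin(calls$ref_best_p, calls$alt_best_p)
    ord <- order(calls$snp_id, calls$tf_name, minp, calls$peak_id)
    calls <- calls[ord, , drop = FALSE]
    calls <- calls[!duplicated(calls[, c("snp_id", "tf_name")]), , drop = FALSE]
    calls <- calls[order(calls$snp_id, calls$tf_name), , drop = FALSE]
  }
  rownames(calls) <- NULL
  attr(calls, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(snp_id = character(0), tf_name = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  calls
}

#' Per-TF disruption counts and pairwise co-disruption
#'
#' @param calls output of [run_disruption_screen()].
#' @return list with `per_tf` (tf_name, n_disrupting_snps; distinct SNPs)
#'   and `co_disruption` (tf_a, tf_b, n_snps disrupting both).
#' @export
summarize_by_tf <- function(calls) {
  d <- unique(calls[calls$disrupts, c("snp_id", "tf_name")])
  if (!nrow(d)) {
    return(list(
      per_tf = data.frame(tf_name = character(0),
                          n_disrupting_snps = integer(0),
                          stringsAsFactors = FALSE),
      co_disruption = data.frame(tf_a = character(0), tf_b = character(0),
                                 n_snps = integer(0),
                                 stringsAsFactors = FALSE)))
  }
  counts <- table(d$tf_name)
  per_tf <- data.frame(tf_name = names(counts),
                       n_disrupting_snps = as.integer(counts),
                       stringsAsFactors = FALSE)
  per_tf <- per_tf[order(-per_tf$n_disrupting_snps, per_tf$tf_name), ]
  rownames(per_tf) <- NULL
  pair_rows <- list()
  by_snp <- split(d$tf_name, d$snp_id)
  for (tfs in by_snp) {
    tfs <- sort(unique(tfs))
    if (length(tfs) >= 2L) {
      cmb <- utils::combn(tfs, 2L)
      for (j in seq_len(ncol(cmb))) {
        key <- paste(cmb[1, j], cmb[2, j], sep = "\t")
        pair_rows[[key]] <- (pair_rows[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(pair_rows)) {
    parts <- strsplit(names(pair_rows), "\t", fixed = TRUE)
    co <- data.frame(tf_a = vapply(parts, `[[`, "", 1L),
                     tf_b = vapply(parts, `[[`, "", 2L),
                     n_snps = as.integer(unlist(pair_rows)),
                     stringsAsFactors = FALSE)
    co <- co[order(-co$n_snps, co$tf_a, co$tf_b), ]
    rownames(co) <- NULL
  } else {
    co <- data.frame(tf_a = character(0), tf_b = character(0),
                     n_snps = integer(0), stringsAsFactors = FALSE)
  }
  list(per_tf = per_tf, co_disruption = co)
}

#' Classify SNPs by genomic context
#'
#' Assigns exactly one category per SNP by the precedence
#' exonic > UTR > intronic > upstream > downstream > intergenic, with a
#' 1 kb default upstream/downstream margin. This is a deliberately
#' simplified interval-precedence annotation (see the attached `note`), not
#' a transcript-aware annotator.
#'
#' @param snps SNV data.frame.
#' @param gene_model interval data.frame (layout of [read_gene_model()]).
#' @param margin upstream/downstream margin in bp, default 1000.
#' @return data.frame snp_id, category, with attributes `fractions` (named
#'   proportions) and `note`.
#' @export
genomic_context <- function(snps, gene_model, margin = 1000L) {
  pts <- GenomicRanges::GRanges(
    snps$contig, IRanges::IRanges(start = snps$position + 1L, width = 1L))
  category <- rep(NA_character_, nrow(snps))
  mark <- function(gr, label) {
    if (!length(gr)) return(invisible(NULL))
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(pts, gr))
    category[is.na(category) & seq_along(category) %in% hit] <<- label
    invisible(NULL)
  }
  iv <- function(rows) {
    GenomicRanges::GRanges(rows$contig,
                           IRanges::IRanges(start = rows$start + 1L,
                                            end = rows$end))
  }
  mark(iv(gene_model[gene_model$type == "exon", ]), "exonic")
  mark(iv(gene_model[gene_model$type == "UTR", ]), "UTR")
  genes <- gene_model[gene_model$type == "gene", ]
  mark(iv(genes), "intronic")
  if (nrow(genes)) {
    plus <- genes$strand != "-"
    up <- data.frame(
      contig = genes$contig,
      start = ifelse(plus, pmax(genes$start - margin, 0L), genes$end),
      end = ifelse(plus, genes$start, genes$end + margin))
    dn <- data.frame(
      contig = genes$contig,
      start = ifelse(plus, genes$end, pmax(genes$start - margin, 0L)),
      end = ifelse(plus, genes$end + margin, genes$start))
    mark(iv(up[up$start < up$end, ]), "upstream")
    mark(iv(dn[dn$start < dn$end, ]), "downstream")
  }
  category[is.na(category)] <- "intergenic"
  out <- data.frame(snp_id = snps$snp_id, category = category,
                    stringsAsFactors = FALSE)
  lvls <- c("exonic", "UTR", "intronic", "upstream", "downstream",
            "intergenic")
  attr(out, "fractions") <- prop.table(table(factor(category, levels = lvls)))
  attr(out, "note") <- "simplified interval-precedence annotation"
  out
}
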