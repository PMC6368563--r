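# Readers/writers for the external formats the pipeline touches. Validation
# is strict: malformed input stops with a message naming the offending line
# or column rather than silently propagating bad records.

#' Read a genome FASTA file
#'
#' @param path FASTA file. Sequences are upper-cased and must be over
#'   A/C/G/T/N.
#' @return named character vector, one upper-case sequence per contig
#'   (names are the first whitespace-delimited token of each header).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (any(nchar(genome) == 0L)) stop("empty sequence in ", path)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop(sprintf("contig %s contains characters outside {A,C,G,T,N}",
                 names(genome)[bad][1]))
  }
  if (anyDuplicated(names(genome))) stop("duplicated contig names in ", path)
  genome
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Fetch a genome subsequence by 0-based half-open coordinates
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return character scalar of length `end - start`.
#' @export
genome_fetch <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("coordinates [%d, %d) out of range for %s (length %d)",
                 start, end, contig, len))
  }
  substr(genome[[contig]], start + 1L, end)
}

## ---- MEME minimal motif format ------------------------------------------

#' Read motifs in MEME minimal motif format
#'
#' Parses the version line, optional alphabet/background sections and every
#' MOTIF block with its letter-probability matrix. Matrix rows are
#' renormalized to sum to 1; the file's background frequencies are attached
#' to each motif (uniform if absent). Duplicate motif names are suffixed
#' with an ordinal so they stay usable as join keys.
#'
#' @param path MEME-format file.
#' @return list of `pwm` objects (see [pwm()]).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    stop("line 1: not a MEME minimal motif file (missing 'MEME version' line)")
  }
  background <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- character(0)
    j <- bg_i[1] + 1L
    while (length(toks) < 8L && j <= length(lines) &&
           !grepl("^MOTIF", lines[j])) {
      toks <- c(toks, strsplit(trimws(lines[j]), "\\s+")[[1]])
      toks <- toks[nzchar(toks)]
      j <- j + 1L
    }
    if (length(toks) < 8L) {
      stop(sprintf("line %d: malformed background frequencies", bg_i[1]))
    }
    letters_in <- toks[seq(1, 7, by = 2)]
    freqs <- suppressWarnings(as.numeric(toks[seq(2, 8, by = 2)]))
    idx <- match(BASES, letters_in)
    if (anyNA(idx) || anyNA(freqs)) {
      stop(sprintf("line %d: malformed background frequencies", bg_i[1]))
    }
    background <- freqs[idx]
    if (abs(sum(background) - 1) > 1e-3 || any(background < 0)) {
      stop(sprintf("line %d: background frequencies do not form a distribution",
                   bg_i[1]))
    }
    background <- background / sum(background)
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (!length(motif_i)) stop("no MOTIF blocks found in ", path)
  pwms <- vector("list", length(motif_i))
  for (k in seq_along(motif_i)) {
    mi <- motif_i[k]
    fields <- strsplit(trimws(lines[mi]), "\\s+")[[1]]
    if (length(fields) < 2L) stop(sprintf("line %d: MOTIF line has no name", mi))
    name <- fields[2]
    look <- (mi + 1L):min(mi + 10L, length(lines))
    lp_rel <- which(grepl("^letter-probability matrix", lines[look]))
    if (!length(lp_rel)) {
      stop(sprintf("line %d: MOTIF block lacks a letter-probability matrix", mi))
    }
    lp <- look[lp_rel[1]]
    header <- lines[lp]
    if (grepl("alength=", header)) {
      alen <- as.integer(sub(".*alength=\\s*(\\d+).*", "\\1", header))
      if (!is.na(alen) && alen != 4L) {
        stop(sprintf("line %d: alphabet length %d not supported (need 4)",
                     lp, alen))
      }
    }
    if (!grepl("w=\\s*\\d+", header)) {
      stop(sprintf("line %d: letter-probability matrix lacks 'w='", lp))
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header))
    if (is.na(w) || w < 1L) stop(sprintf("line %d: invalid motif width", lp))
    if (lp + w > length(lines)) {
      stop(sprintf("line %d: matrix truncated (expected %d rows)", lp, w))
    }
    probs <- matrix(NA_real_, nrow = w, ncol = 4,
                    dimnames = list(NULL, BASES))
    for (r in seq_len(w)) {
      lineno <- lp + r
      nums <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[lineno]), "\\s+")[[1]]))
      if (length(nums) != 4L || anyNA(nums)) {
        stop(sprintf("line %d: expected 4 probabilities, got '%s'",
                     lineno, trimws(lines[lineno])))
      }
      if (any(nums < 0 | nums > 1)) {
        stop(sprintf("line %d: probability outside [0, 1]", lineno))
      }
      s <- sum(nums)
      if (s <= 0) stop(sprintf("line %d: probability row sums to zero", lineno))
      probs[r, ] <- nums / s
    }
    pwms[[k]] <- pwm(name, probs, background)
  }
  nms <- vapply(pwms, function(p) p$name, character(1))
  dup <- duplicated(nms)
  if (any(dup)) {
    for (k in which(dup)) {
      ordinal <- sum(nms[seq_len(k)] == nms[k])
      pwms[[k]]$name <- paste0(nms[k], "_", ordinal)
    }
  }
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  pwms
}

#' Write motifs in MEME minimal motif format
#'
#' @param pwms list of `pwm` objects sharing one background.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path) {
  bg <- pwms[[1]]$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
    ""
  )
  for (p in pwms) {
    lines <- c(lines,
               paste("MOTIF", p$name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width),
               apply(p$probs, 1, function(r) {
                 sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])
               }),
               "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- narrowPeak ----------------------------------------------------------

#' Read ENCODE narrowPeak (BED6+4) peaks with an FDR filter
#'
#' Column 9 is interpreted as -log10(q-value) per the ENCODE convention, so
#' an FDR <= `q_threshold` filter keeps peaks with
#' `neg_log10_q >= -log10(q_threshold)`. A summit offset of -1 in column 10
#' falls back to the interval midpoint (floor).
#'
#' @param path narrowPeak file (10 tab-separated columns).
#' @param q_threshold peak-level FDR cutoff, default 0.05.
#' @param tf_name TF label to attach; default `NA` takes the text before the
#'   first underscore of the name column.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   summit_offset, neg_log10_q, tf_name, peak_id. Attributes `n_input` and
#'   `dropped` (the filtered-out rows) make the retained/dropped partition
#'   auditable.
#' @export
read_narrowpeak <- function(path, q_threshold = 0.05, tf_name = NA_character_) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  if (ncol(raw) != 10L) {
    stop(sprintf("%s: narrowPeak requires 10 columns, found %d", path, ncol(raw)))
  }
  names(raw) <- c("chrom", "start", "end", "name", "score", "strand",
                  "signal", "p", "q", "peak")
  if (any(raw$start < 0 | raw$end < 0)) {
    stop(path, ": negative coordinates in narrowPeak")
  }
  if (any(raw$start >= raw$end)) stop(path, ": peak with start >= end")
  summit <- ifelse(raw$peak < 0, (raw$end - raw$start) %/% 2L, raw$peak)
  if (any(summit < 0 | summit >= raw$end - raw$start)) {
    stop(path, ": summit offset outside the peak interval")
  }
  tf <- if (is.na(tf_name)) sub("_.*$", "", raw$name) else tf_name
  df <- data.frame(contig = raw$chrom, start = raw$start, end = raw$end,
                   summit_offset = summit, neg_log10_q = raw$q,
                   tf_name = tf, peak_id = raw$name,
                   stringsAsFactors = FALSE)
  keep <- df$neg_log10_q >= -log10(q_threshold)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(df)
  attr(out, "dropped") <- df[!keep, , drop = FALSE]
  out
}

#' Write peaks as narrowPeak
#'
#' @param peaks data.frame in the layout returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.4f\t%.4f\t%.4f\t%d",
                   peaks$contig, peaks$start, peaks$end, peaks$peak_id,
                   0L, peaks$neg_log10_q, peaks$neg_log10_q,
                   peaks$neg_log10_q, peaks$summit_offset)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- SNVs (VCF-lite / TSV) ----------------------------------------------

validate_snv_frame <- function(df, n_skipped) {
  bad <- !(df$ref %in% BASES) | !(df$alt %in% BASES)
  if (any(bad)) {
    stop("SNV with allele outside {A,C,G,T}: ", df$snp_id[bad][1])
  }
  if (any(df$ref == df$alt)) {
    stop("SNV with identical ref and alt allele: ",
         df$snp_id[df$ref == df$alt][1])
  }
  key <- paste(df$snp_id, df$alt)
  df <- df[!duplicated(key), , drop = FALSE]
  coords <- tapply(paste(df$contig, df$position),
                   df$snp_id, function(x) length(unique(x)))
  if (any(coords > 1L)) {
    stop("snp_id with conflicting coordinates: ",
         names(coords)[coords > 1L][1])
  }
  rownames(df) <- NULL
  attr(df, "n_skipped_indels") <- n_skipped
  df
}

#' Read SNVs from a VCF subset or a TSV table
#'
#' The VCF dialect parses CHROM/POS/ID/REF/ALT only; positions are converted
#' from 1-based to the package's 0-based convention, multi-allelic records
#' are expanded to one row per alternative allele, and any record with an
#' allele longer than one base (an indel) is skipped and counted. The TSV
#' dialect expects columns snp_id, contig, position (0-based), ref, alt and
#' optional maf, locus_id.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return data.frame with columns snp_id, contig, position, ref, alt, maf,
#'   locus_id; attribute `n_skipped_indels` counts excluded indel records.
#' @export
read_snvs <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    require_columns(df, c("snp_id", "contig", "position", "ref", "alt"),
                    paste0("SNV table ", path))
    if (is.null(df$maf)) df$maf <- NA_real_
    if (is.null(df$locus_id)) df$locus_id <- NA_character_
    is_indel <- nchar(df$ref) > 1L | nchar(df$alt) > 1L
    out <- df[!is_indel, c("snp_id", "contig", "position", "ref", "alt",
                           "maf", "locus_id"), drop = FALSE]
    return(validate_snv_frame(out, sum(is_indel)))
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(validate_snv_frame(
      data.frame(snp_id = character(0), contig = character(0),
                 position = integer(0), ref = character(0),
                 alt = character(0), maf = numeric(0),
                 locus_id = character(0), stringsAsFactors = FALSE), 0L))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L)) {
    stop(path, ": VCF data line with fewer than 5 columns")
  }
  n_skipped <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ref <- toupper(f[4])
    alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    info <- if (length(f) >= 8L) f[8] else "."
    maf <- NA_real_
    locus <- NA_character_
    if (grepl("MAF=", info)) {
      maf <- as.numeric(sub(".*MAF=([^;]+).*", "\\1", info))
    }
    if (grepl("LOCUS=", info)) {
      locus <- sub(".*LOCUS=([^;]+).*", "\\1", info)
    }
    # one expanded (ref, alt) pair per alt; any pair with an allele longer
    # than one base is an indel and is skipped + counted
    keep <- nchar(ref) == 1L & nchar(alts) == 1L & alts %in% BASES
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) {
      rows[[i]] <- NULL
      next
    }
    rows[[i]] <- data.frame(
      snp_id = f[3], contig = f[1],
      position = as.integer(f[2]) - 1L,
      ref = ref, alt = alts[keep], maf = maf, locus_id = locus,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  validate_snv_frame(out, n_skipped)
}

#' Write SNVs as a minimal VCF v4.2
#'
#' Positions are converted back to 1-based; maf and locus_id travel in the
#' INFO column as `MAF=`/`LOCUS=` keys.
#'
#' @param snps SNV data.frame (layout of [read_snvs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snvs_vcf <- function(snps, path) {
  info <- mapply(function(maf, locus) {
    parts <- character(0)
    if (!is.na(maf)) parts <- c(parts, sprintf("MAF=%.6g", maf))
    if (!is.na(locus)) parts <- c(parts, paste0("LOCUS=", locus))
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }, snps$maf, snps$locus_id)
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                     snps$contig, snps$position + 1L, snps$snp_id,
                     snps$ref, snps$alt, info))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- analysis tables -----------------------------------------------------

#' Read a gene-model interval table
#'
#' @param path TSV with columns contig, start, end, type (one of gene, exon,
#'   UTR) and optional gene, strand.
#' @return validated data.frame.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("contig", "start", "end", "type"),
                  paste0("gene model ", path))
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$gene)) df$gene <- paste0("g", seq_len(nrow(df)))
  ok <- df$type %in% c("gene", "exon", "UTR")
  if (!all(ok)) stop("gene model: unknown interval type ", df$type[!ok][1])
  df
}

#' Read a five-annotator score table
#'
#' @param path TSV with columns snp_id, locus_id, cadd, eigen, gwava,
#'   linsight, regulomedb.
#' @return data.frame.
#' @export
read_annotation_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("snp_id", "locus_id", "cadd", "eigen", "gwava",
                        "linsight", "regulomedb"),
                  paste0("annotation table ", path))
  df$regulomedb <- as.character(df$regulomedb)
  df
}

#' Read an eQTL association table
#'
#' @param path TSV with columns snp_id, gene, dataset, tissue, p, fdr.
#' @return data.frame.
#' @export
read_eqtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("snp_id", "gene", "dataset", "tissue", "p", "fdr"),
                  paste0("eQTL table ", path))
  df
}

#' Read an allelic read-count table
#'
#' @param path TSV with columns snp_id, tissue, ref_count, alt_count.
#' @return data.frame.
#' @export
read_ase_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("snp_id", "tissue", "ref_count", "alt_count"),
                  paste0("ASE table ", path))
  df
}

#' Read a SNP pool table for enrichment resampling
#'
#' @param path TSV with columns snp_id, maf, eqtl_flag and optional tf.
#' @return data.frame with logical eqtl_flag.
#' @export
read_pool_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("snp_id", "maf", "eqtl_flag"),
                  paste0("SNP pool ", path))
  df$eqtl_flag <- as.logical(df$eqtl_flag)
  if (is.null(df$tf)) df$tf <- NA_character_
  df
}

#' Read a genotype dosage matrix
#'
#' @param path TSV whose first three columns are snp_id, contig, position,
#'   followed by one 0/1/2 dosage column per sample.
#' @return list with `map` (data.frame snp_id, contig, position) and `mat`
#'   (numeric matrix, SNPs in rows, rownames = snp_id).
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("snp_id", "contig", "position"),
                  paste0("genotype table ", path))
  if (ncol(df) < 4L) stop(path, ": genotype table has no sample columns")
  mat <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.na(mat) & !(mat %in% c(0, 1, 2)))) {
    stop(path, ": genotype dosages must be 0/1/2 or NA")
  }
  rownames(mat) <- df$snp_id
  list(map = df[, 1:3], mat = mat)
}

#' Read a stage-labelled expression matrix with its stage metadata sidecar
#'
#' @param path expression TSV: column `gene` then one RPKM column per stage.
#' @param stages_path sidecar TSV with columns stage, prenatal (TRUE/FALSE),
#'   rows in developmental order.
#' @return `stage_expr` list: `values` (gene x stage matrix), `stages`,
#'   `is_prenatal`.
#' @export
read_expression_matrix <- function(path, stages_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, "gene", paste0("expression matrix ", path))
  meta <- utils::read.delim(stages_path, stringsAsFactors = FALSE)
  require_columns(meta, c("stage", "prenatal"),
                  paste0("stage metadata ", stages_path))
  if (!setequal(meta$stage, setdiff(names(df), "gene"))) {
    stop("stage metadata does not match expression matrix columns")
  }
  values <- as.matrix(df[, meta$stage, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$gene
  if (any(values < 0, na.rm = TRUE)) stop("negative RPKM values in ", path)
  stage_expr(values, meta$stage, as.logical(meta$prenatal))
}

#' Read a cell-type specificity table
#'
#' @param path TSV with columns gene, cell_type, specificity (in `[0, 1]`).
#' @return data.frame.
#' @export
read_specificity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("gene", "cell_type", "specificity"),
                  paste0("specificity table ", path))
  if (any(df$specificity < 0 | df$specificity > 1, na.rm = TRUE)) {
    stop(path, ": specificity outside [0, 1]")
  }
  df
}
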