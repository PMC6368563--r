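# Shared internals: DNA encoding, seeded RNG scoping, deterministic TSV I/O.
# Coordinates are 0-based half-open everywhere inside the package; conversion
# to 1-based formats (VCF, FASTA substrings, GRanges) happens at the boundary.

BASES <- c("A", "C", "G", "T")
.base_codes <- utf8ToInt("ACGT")
.n_code <- utf8ToInt("N")

# A/C/G/T -> 1..4, anything else (N) -> NA
encode_seq <- function(s) {
  match(utf8ToInt(toupper(s)), .base_codes)
}

decode_seq <- function(codes) {
  out <- .base_codes[codes]
  out[is.na(out)] <- .n_code
  intToUtf8(out)
}

# complement of code i is 5 - i (A<->T, C<->G); NA propagates
revcomp_codes <- function(codes) {
  rev(5L - codes)
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]
}

#' Reverse complement of a DNA string
#'
#' @param s character scalar over A/C/G/T/N (case-insensitive).
#' @return upper-case reverse complement.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(s) {
  decode_seq(revcomp_codes(encode_seq(s)))
}

# Deterministic per-stage seed derived from a master seed; keeps every source
# of randomness behind one integer while giving stages independent streams.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 2147480000 * 7919 + h) %% 2147483629)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_table_column <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.6g", x)
    out[is.na(x)] <- "NA"
  } else if (is.logical(x)) {
    out <- ifelse(x, "TRUE", "FALSE")
    out[is.na(x)] <- "NA"
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
  }
  out
}

#' Write a table of records as deterministic TSV
#'
#' Tab-separated with a header row; doubles rendered with 6 significant
#' digits; byte-identical output for identical input, so pipeline runs can be
#' compared file-by-file.
#'
#' @param rows data.frame (or coercible) of homogeneous records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) {
    body <- character(0)
  } else {
    cols <- lapply(df, format_table_column)
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @return data.frame with character/numeric/logical columns as parsed.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
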