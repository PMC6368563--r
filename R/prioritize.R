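# Per-locus consensus prioritization of functional SNPs from five
# heterogeneous annotators: four "bigger is better" scores (CADD, Eigen,
# GWAVA, LINSIGHT) and one ordinal rating (RegulomeDB, smaller is better).
# Ties are kept as sets; cross-locus comparison is never performed.

SCORING_METHODS <- c("cadd", "eigen", "gwava", "linsight")

#' Order key for RegulomeDB ordinal ratings
#'
#' Grammar: category 1-6 with an optional letter a-f allowed only for
#' categories 1-3 (where a letter is mandatory; a bare "1" is ambiguous and
#' rejected). Ordering: category ascending, then letter ascending, e.g.
#' "1a" < "1f" < "2a" < "4" < "6".
#'
#' @param x character vector of ratings; NA passes through.
#' @return integer key vector (smaller = more likely functional).
#' @export
regdb_rating_key <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  m <- regexec("^([1-6])([a-f]?)$", x[ok])
  parts <- regmatches(x[ok], m)
  bad <- lengths(parts) == 0L
  if (any(bad)) {
    stop("unparseable RegulomeDB rating: '", x[ok][bad][1], "'")
  }
  cat <- as.integer(vapply(parts, `[[`, "", 2L))
  let <- vapply(parts, `[[`, "", 3L)
  if (any(cat <= 3L & let == "")) {
    stop("ambiguous RegulomeDB rating '", x[ok][cat <= 3L & let == ""][1],
         "': categories 1-3 require a letter")
  }
  if (any(cat >= 4L & let != "")) {
    stop("invalid RegulomeDB rating '", x[ok][cat >= 4L & let != ""][1],
         "': categories 4-6 take no letter")
  }
  out[ok] <- cat * 10L + ifelse(let == "", 0L, match(let, letters[1:6]))
  out
}

#' Per-locus argmax SNP set for one scoring method
#'
#' @param rows annotation data.frame (layout of
#'   [read_annotation_scores()]).
#' @param method one of "cadd", "eigen", "gwava", "linsight".
#' @return named list: locus_id -> character vector of top snp_ids (ties
#'   kept). Loci where every SNP is missing the score are absent.
#' @export
top_by_score <- function(rows, method) {
  method <- match.arg(method, SCORING_METHODS)
  scores <- rows[[method]]
  keep <- !is.na(scores)
  if (!any(keep)) return(list())
  sub <- rows[keep, ]
  sc <- scores[keep]
  lapply(split(seq_len(nrow(sub)), sub$locus_id), function(i) {
    top <- sc[i] == max(sc[i])
    sort(unique(sub$snp_id[i][top]))
  })
}

#' Per-locus argmin SNP set under the RegulomeDB ordering
#'
#' @param rows annotation data.frame.
#' @return named list: locus_id -> character vector of best-rated snp_ids
#'   (ties kept); all-missing loci absent.
#' @export
top_by_rating <- function(rows) {
  key <- regdb_rating_key(rows$regulomedb)
  keep <- !is.na(key)
  if (!any(keep)) return(list())
  sub <- rows[keep, ]
  k <- key[keep]
  lapply(split(seq_len(nrow(sub)), sub$locus_id), function(i) {
    top <- k[i] == min(k[i])
    sort(unique(sub$snp_id[i][top]))
  })
}

#' Per-locus consensus functional SNPs across the five annotators
#'
#' A SNP is a consensus SNP for its locus when (a) it is in the argmax set of
#' at least two of the four scoring methods, or (b) it is in the argmax set
#' of at least one scoring method and also in the RegulomeDB argmin set.
#'
#' @param rows annotation data.frame.
#' @return list with `loci` (per-locus list: top_by_method, consensus_snps,
#'   has_consensus), `table` (data.frame locus_id, snp_id, one row per
#'   consensus SNP) and `summary` (data.frame locus_id, has_consensus,
#'   n_consensus).
#' @export
consensus <- function(rows) {
  tops <- lapply(SCORING_METHODS, function(m) top_by_score(rows, m))
  names(tops) <- SCORING_METHODS
  rtop <- top_by_rating(rows)
  loci <- sort(unique(rows$locus_id))
  per_locus <- lapply(loci, function(L) {
    tbm <- lapply(tops, function(t) t[[L]] %||% character(0))
    tbm$regulomedb <- rtop[[L]] %||% character(0)
    snps <- sort(unique(rows$snp_id[rows$locus_id == L]))
    n_top <- vapply(snps, function(s) {
      sum(vapply(SCORING_METHODS,
                 function(m) s %in% tbm[[m]], logical(1)))
    }, integer(1))
    cons <- snps[n_top >= 2L | (n_top >= 1L & snps %in% tbm$regulomedb)]
    list(top_by_method = tbm, consensus_snps = cons,
         has_consensus = length(cons) > 0L)
  })
  names(per_locus) <- loci
  tab <- do.call(rbind, lapply(loci, function(L) {
    cs <- per_locus[[L]]$consensus_snps
    if (!length(cs)) return(NULL)
    data.frame(locus_id = L, snp_id = cs, stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(locus_id = character(0), snp_id = character(0),
                      stringsAsFactors = FALSE)
  }
  summary <- data.frame(
    locus_id = loci,
    has_consensus = vapply(per_locus, `[[`, logical(1), "has_consensus"),
    n_consensus = vapply(per_locus,
                         function(x) length(x$consensus_snps), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(loci = per_locus, table = tab, summary = summary)
}
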