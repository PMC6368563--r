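# Spatio-temporal expression comparison of target-gene sets against
# background, and cell-type specificity counting. The unit of comparison is
# the per-stage median over the gene set (the gene-set expression profile).

#' Construct a stage-labelled expression matrix
#'
#' @param values non-negative gene x stage matrix (RPKM), rownames = genes.
#' @param stages stage labels in developmental order (= colnames).
#' @param is_prenatal logical vector marking prenatal stages.
#' @return object of class `stage_expr`.
#' @export
stage_expr <- function(values, stages, is_prenatal) {
  values <- as.matrix(values)
  if (length(stages) != ncol(values) ||
      length(is_prenatal) != length(stages)) {
    stop("stages/is_prenatal must match the matrix columns")
  }
  if (!length(stages)) stop("at least one stage is required")
  colnames(values) <- stages
  structure(list(values = values, stages = stages,
                 is_prenatal = as.logical(is_prenatal)),
            class = "stage_expr")
}

#' Per-stage median expression of a gene set
#'
#' Duplicate gene names are collapsed (set semantics); genes absent from the
#' matrix are reported via message and dropped.
#'
#' @param mat `stage_expr` object.
#' @param gene_set character vector of gene names.
#' @return named numeric vector, one median per stage.
#' @export
stage_medians <- function(mat, gene_set) {
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(mat$values))
  missing <- setdiff(gene_set, present)
  if (length(missing)) {
    message(length(missing), " gene(s) absent from the expression matrix")
  }
  if (!length(present)) stop("no gene of the set is in the expression matrix")
  apply(mat$values[present, , drop = FALSE], 2, stats::median)
}

# rank-sum wrapper with an explicit degenerate branch: when every value in
# both samples is identical the statistic sits at its expectation and the
# comparison is uninformative (p = 1)
ranksum <- function(a, b, alternative = "two.sided") {
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = NULL))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Compare a target gene set against background across stages
#'
#' Two rank-sum comparisons of per-stage medians: (1) target vs background
#' across all stages, and (2) prenatal vs postnatal stages within the target
#' set. Exact test when sample sizes permit and there are no ties, normal
#' approximation with tie correction otherwise.
#'
#' @param mat `stage_expr` object.
#' @param target_set,background_set gene name vectors (non-empty after
#'   intersection with the matrix).
#' @param alternative passed to [stats::wilcox.test()]; default two-sided.
#' @return list with `sets` (statistic, p for target vs background),
#'   `prenatal` (statistic, p for prenatal vs postnatal target medians),
#'   `target_medians`, `background_medians`.
#' @export
compare_gene_sets <- function(mat, target_set, background_set,
                              alternative = "two.sided") {
  tm <- stage_medians(mat, target_set)
  bm <- stage_medians(mat, background_set)
  sets <- ranksum(tm, bm, alternative)
  pre <- mat$is_prenatal
  prenatal <- if (any(pre) && any(!pre)) {
    ranksum(tm[pre], tm[!pre], alternative)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  list(sets = sets, prenatal = prenatal,
       target_medians = tm, background_medians = bm)
}

#' Count gene-set genes above a specificity cutoff per cell type
#'
#' Strict inequality: a gene at exactly the cutoff is not counted.
#'
#' @param spec specificity data.frame (layout of
#'   [read_specificity_table()]).
#' @param gene_set gene name vector.
#' @param cutoff specificity cutoff, default 0.1.
#' @return data.frame cell_type, n_genes (every cell type present in
#'   `spec`, zeros included), sorted by n_genes descending.
#' @export
celltype_counts <- function(spec, gene_set, cutoff = 0.1) {
  gene_set <- unique(gene_set)
  cell_types <- sort(unique(spec$cell_type))
  hit <- spec$gene %in% gene_set & spec$specificity > cutoff
  counts <- vapply(cell_types, function(ct) {
    length(unique(spec$gene[hit & spec$cell_type == ct]))
  }, integer(1))
  out <- data.frame(cell_type = cell_types, n_genes = counts,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_genes, out$cell_type), ]
  rownames(out) <- NULL
  out
}
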