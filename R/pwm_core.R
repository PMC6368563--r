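# Log-odds PWM scoring against a zero-order background with exact p-values.
#
# Scores are pseudocount-regularized log2 likelihood ratios summed over motif
# positions. For p-values the per-position entries are discretized onto an
# integer grid (`scale` grid units per log2 unit) and the null distribution
# of the total score under the background model is built by position-wise
# convolution; the survival function of that distribution gives the exact
# tail probability of any discretized score. On the integer grid this equals
# brute-force enumeration over all 4^w windows.

#' Construct a position weight matrix
#'
#' @param name motif name (used as the join key to ChIP-Seq peak TF labels).
#' @param probs numeric w x 4 matrix of per-position base probabilities,
#'   columns in A, C, G, T order; each row must sum to 1 within 1e-6.
#' @param background length-4 base frequencies of the zero-order background
#'   model (default uniform); must sum to 1 within 1e-6.
#' @return object of class `pwm` with fields name, width, probs, background.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) stop("motif width must be >= 1")
  if (any(probs < 0)) stop("negative probability in PWM ", name)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stop(sprintf("PWM %s: row %d sums to %.8f, not 1",
                 name, which(abs(sums - 1) > 1e-6)[1],
                 sums[which(abs(sums - 1) > 1e-6)[1]]))
  }
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 non-negative frequencies summing to 1")
  }
  colnames(probs) <- BASES
  structure(list(name = name, width = nrow(probs), probs = probs,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d), consensus %s\n",
              x$name, x$width, consensus_seq(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' Per-column argmax base; ties resolve to the first base in A,C,G,T order.
#'
#' @param pwm a `pwm` object.
#' @return character scalar of length `pwm$width`.
#' @export
consensus_seq <- function(pwm) {
  paste(BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Build the pseudocount-regularized log-odds matrix of a PWM
#'
#' Entry (i, a) is `log2((p[i,a] + c*b[a]) / ((1 + c) * b[a]))` where `c` is
#' the pseudocount fraction and `b` the background; the additive `c*b[a]`
#' term guarantees finite entries at zero-probability cells. Entries are also
#' discretized to an integer grid for the exact p-value machinery.
#'
#' @param pwm a `pwm` object.
#' @param pseudocount_frac pseudocount fraction `c > 0`, default 0.1.
#' @param scale integer grid units per log2 unit, default 1000.
#' @return object of class `log_odds_matrix` with fields source, width,
#'   entries (double), int_entries (integer), scale, background.
#' @export
build_log_odds <- function(pwm, pseudocount_frac = 0.1, scale = 1000L) {
  if (pseudocount_frac <= 0) stop("pseudocount_frac must be > 0")
  b <- pwm$background
  if (any(b <= 0)) stop("invalid background: zero frequency for some base")
  num <- sweep(pwm$probs, 2, pseudocount_frac * b, "+")
  den <- (1 + pseudocount_frac) * b
  entries <- log2(sweep(num, 2, den, "/"))
  int_entries <- matrix(as.integer(round(entries * scale)),
                        nrow = pwm$width, ncol = 4L,
                        dimnames = dimnames(entries))
  structure(list(source = pwm$name, width = pwm$width, entries = entries,
                 int_entries = int_entries, scale = as.integer(scale),
                 background = b),
            class = "log_odds_matrix")
}

# entries of the reverse-complement matrix: scoring the reverse complement of
# a window against the forward matrix equals scoring the window itself
# against this flipped matrix
rc_entries <- function(m) {
  m[rev(seq_len(nrow(m))), 4:1, drop = FALSE]
}

#' Score one window against a log-odds matrix
#'
#' For the minus strand the reverse complement of the window is scored
#' against the forward matrix.
#'
#' @param lom `log_odds_matrix`.
#' @param window character scalar of length `lom$width`.
#' @param strand `"+"` or `"-"`.
#' @return continuous log2 log-odds score; `NA` if the window contains an
#'   ambiguous base (callers skip such windows).
#' @export
score_window <- function(lom, window, strand = "+") {
  codes <- encode_seq(window)
  if (length(codes) != lom$width) {
    stop(sprintf("window length %d != motif width %d",
                 length(codes), lom$width))
  }
  if (anyNA(codes)) return(NA_real_)
  if (strand == "-") codes <- revcomp_codes(codes)
  sum(lom$entries[cbind(seq_len(lom$width), codes)])
}

#' Exact null distribution of the discretized motif score
#'
#' Position-wise convolution under the zero-order background:
#' `D_0 = {0: 1}`, `D_i(s) = sum_a b[a] * D_{i-1}(s - e_int(i, a))`. The
#' survival function `P(score >= s)` follows by suffix summation and matches
#' enumeration over all 4^w windows exactly on the integer grid.
#'
#' @param lom `log_odds_matrix`.
#' @return object of class `score_dist` with integer `support` (a contiguous
#'   grid), `pmf`, `survival` and `scale`.
#' @export
exact_pvalue_table <- function(lom) {
  E <- lom$int_entries
  b <- lom$background
  rmin <- apply(E, 1, min)
  rmax <- apply(E, 1, max)
  lo <- sum(rmin)
  hi <- sum(rmax)
  if (hi - lo + 1 > 2e7) {
    stop("score grid too large for exact p-values; use a smaller scale")
  }
  cur <- 1
  curlo <- 0L
  for (i in seq_len(lom$width)) {
    newlen <- length(cur) + (rmax[i] - rmin[i])
    new <- numeric(newlen)
    for (a in 1:4) {
      off <- E[i, a] - rmin[i]
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + b[a] * cur
    }
    cur <- new
    curlo <- curlo + rmin[i]
  }
  support <- seq.int(lo, hi)
  survival <- rev(cumsum(rev(cur)))
  structure(list(support = support, pmf = cur, survival = survival,
                 scale = lom$scale),
            class = "score_dist")
}

#' Look up exact p-values for discretized scores
#'
#' @param dist `score_dist` from [exact_pvalue_table()].
#' @param int_score integer score(s) on the same grid.
#' @return `P(score >= int_score)` under the background model; 1 below the
#'   support, 0 above it (unreachable for real windows); NA stays NA.
#' @export
score_pvalue <- function(dist, int_score) {
  n <- length(dist$support)
  i <- int_score - dist$support[1] + 1L
  out <- rep(NA_real_, length(i))
  ok <- !is.na(i)
  ii <- pmin(pmax(i[ok], 0L), n + 1L)
  out[ok] <- c(1, dist$survival, 0)[ii + 1L]
  out
}

#' Smallest achievable score whose survival is below a significance level
#'
#' Only achievable scores (grid points with positive probability, i.e.
#' scores some window can actually attain) are considered.
#'
#' @param dist `score_dist`.
#' @param alpha significance level in (0, 1].
#' @return smallest achievable integer score s with
#'   `P(score >= s) <= alpha`, or `NA_integer_` as a sentinel when no window
#'   can pass.
#' @export
pvalue_threshold_score <- function(dist, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  k <- which(dist$survival <= alpha & dist$pmf > 0)
  if (!length(k)) return(NA_integer_)
  dist$support[k[1]]
}

# Vectorized window scores along an encoded sequence for one scoring matrix.
# Returns int (grid) and dbl (continuous) scores per 0-based window start;
# windows containing N give NA.
strand_scores <- function(codes, Eint, Edbl) {
  w <- nrow(Eint)
  n_pos <- length(codes) - w + 1L
  si <- numeric(n_pos)
  sdb <- numeric(n_pos)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n_pos - 1L)]
    si <- si + Eint[i, ][ci]
    sdb <- sdb + Edbl[i, ][ci]
  }
  list(int = si, dbl = sdb)
}

#' Scan a sequence for motif matches at a p-value threshold
#'
#' Every window start on both strands is scored; matches with
#' `p-value <= alpha` are emitted. Windows containing N are skipped.
#'
#' @param lom `log_odds_matrix`.
#' @param dist matching `score_dist`.
#' @param seq character scalar, length >= motif width.
#' @param alpha match p-value threshold, default 1e-3.
#' @return data.frame with columns motif, window_start (0-based), strand,
#'   score (continuous log2 LLR), pvalue; ordered by window_start then
#'   strand.
#' @export
scan_sequence <- function(lom, dist, seq, alpha = 1e-3) {
  codes <- encode_seq(seq)
  w <- lom$width
  if (length(codes) < w) stop("sequence shorter than motif width")
  plus <- strand_scores(codes, lom$int_entries, lom$entries)
  minus <- strand_scores(codes, rc_entries(lom$int_entries),
                         rc_entries(lom$entries))
  starts <- seq_len(length(codes) - w + 1L) - 1L
  build <- function(sc, strand) {
    pv <- score_pvalue(dist, sc$int)
    keep <- which(!is.na(pv) & pv <= alpha)
    data.frame(motif = rep(lom$source, length(keep)),
               window_start = starts[keep],
               strand = rep(strand, length(keep)),
               score = sc$dbl[keep], pvalue = pv[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(plus, "+"), build(minus, "-"))
  out <- out[order(out$window_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
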