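test_that("log-odds entries follow the pseudocount-regularized closed form", {
  uni <- pwm("uni", matrix(0.25, nrow = 3, ncol = 4))
  lom <- build_log_odds(uni)
  expect_equal(unname(lom$entries), matrix(0, 3, 4))   # log2(1) everywhere

  # deterministic column: probs[1, A] = 1, c = 0.1, uniform background
  det <- pwm("det", matrix(c(1, 0, 0, 0), nrow = 1))
  lom <- build_log_odds(det, pseudocount_frac = 0.1, scale = 1000L)
  expect_equal(unname(lom$entries[1, "A"]), log2(1.025 / 0.275),
               tolerance = 1e-12)
  expect_equal(unname(lom$entries[1, "C"]), log2(0.025 / 0.275),
               tolerance = 1e-12)
  expect_identical(unname(lom$int_entries[1, "A"]),
                   as.integer(round(log2(1.025 / 0.275) * 1000)))  # 1898
  expect_identical(unname(lom$int_entries[1, "C"]), -3459L)

  bad <- pwm("bad", matrix(0.25, 2, 4))
  bad$background <- c(0.5, 0.5, 0, 0)
  expect_error(build_log_odds(bad), "background")
})

test_that("single-position distribution enumerates exactly", {
  lom <- build_log_odds(pwm("w1", matrix(c(1, 0, 0, 0), 1)), scale = 1000L)
  # force the illustrative grid (2000, -1000, -1000, -1000)
  lom$int_entries <- matrix(c(2000L, -1000L, -1000L, -1000L), 1,
                            dimnames = list(NULL, c("A", "C", "G", "T")))
  d <- exact_pvalue_table(lom)
  expect_equal(score_pvalue(d, 2000L), 0.25)
  expect_equal(score_pvalue(d, -1000L), 1)
  expect_equal(sum(d$pmf), 1)
  expect_equal(d$survival[1], 1)
  expect_equal(pvalue_threshold_score(d, 1), min(d$support))
  expect_equal(pvalue_threshold_score(d, 0.25), 2000L)
  # alpha below the survival at max support -> sentinel
  expect_identical(pvalue_threshold_score(d, 0.1), NA_integer_)
})

test_that("DP survival equals brute-force enumeration on the integer grid", {
  withr::with_seed(42, {
    for (w in 4:6) {
      lom <- build_log_odds(random_prob_pwm(paste0("r", w), w))
      d <- exact_pvalue_table(lom)
      expect_identical(unname(brute_survival(lom, d)), d$survival)
      expect_true(all(diff(d$survival) <= 0))        # monotone p-values
    }
    # non-dyadic background: agreement within numerical tolerance
    bg <- c(0.3, 0.2, 0.2, 0.3)
    lom <- build_log_odds(random_prob_pwm("nb", 5, background = bg))
    d <- exact_pvalue_table(lom)
    expect_equal(unname(brute_survival(lom, d)), d$survival,
                 tolerance = 1e-12)
  })
})

test_that("window scoring respects strand semantics and ambiguity", {
  # palindromic matrix: row i = complement-reversed row w-1-i
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.7))
  lom <- build_log_odds(pwm("pal", probs))
  withr::with_seed(1, {
    for (k in 1:10) {
      win <- paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
      expect_equal(score_window(lom, win, "+"), score_window(lom, win, "-"))
    }
  })
  one <- build_log_odds(pwm("one", matrix(c(1, 0, 0, 0), 1)))
  one$entries <- matrix(c(2, -1, -1, -1), 1,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(score_window(one, "A", "+"), 2)
  expect_true(is.na(score_window(one, "N", "+")))
  expect_error(score_window(one, "AA", "+"), "width")
})

test_that("scan_sequence finds planted consensus matches and counts windows", {
  withr::with_seed(99, {
    p <- random_pwms("M", 8, dominance = 0.95, seed = 3)[[1]]
    lom <- build_log_odds(p)
    d <- exact_pvalue_table(lom)
    flank <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    seq <- paste0(flank, consensus_seq(p), flank)
    hits <- scan_sequence(lom, d, seq, alpha = 1e-3)
    best <- hits[which.max(hits$score), ]
    expect_equal(best$window_start, 30)
    expect_equal(best$strand, "+")
    # alpha = 1: every window on both strands matches, minus N windows
    all_hits <- scan_sequence(lom, d, seq, alpha = 1)
    expect_equal(nrow(all_hits), 2 * (nchar(seq) - 8 + 1))
    # one N at position 0 voids only the single window that covers it
    seqN <- sub("^.", "N", seq)
    expect_equal(nrow(scan_sequence(lom, d, seqN, alpha = 1)),
                 2 * (nchar(seq) - 8 + 1) - 2)
    # degenerate uniform matrix: all p-values are 1, nothing passes
    ulom <- build_log_odds(pwm("u", matrix(0.25, 4, 4)))
    ud <- exact_pvalue_table(ulom)
    expect_equal(nrow(scan_sequence(ulom, ud, seq, alpha = 0.999)), 0)
  })
})

test_that("strand consistency: scanning the reverse complement mirrors matches", {
  withr::with_seed(7, {
    p <- random_prob_pwm("S", 5)
    lom <- build_log_odds(p)
    d <- exact_pvalue_table(lom)
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    fwd <- scan_sequence(lom, d, seq, alpha = 0.2)
    rev <- scan_sequence(lom, d, revcomp(seq), alpha = 0.2)
    # mirror the reverse-complement matches back onto forward coordinates
    rev$window_start <- nchar(seq) - 5 - rev$window_start
    rev$strand <- ifelse(rev$strand == "+", "-", "+")
    ord <- function(x) {
      x <- x[order(x$window_start, x$strand), ]
      rownames(x) <- NULL
      x
    }
    expect_equal(ord(rev), ord(fwd), tolerance = 1e-12)
  })
})

test_that("discretization error is bounded by w / (2 * scale)", {
  withr::with_seed(11, {
    lom <- build_log_odds(random_prob_pwm("D", 6), scale = 1000L)
    for (k in 1:20) {
      win <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
      codes <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
      int_score <- sum(lom$int_entries[cbind(1:6, codes)])
      expect_lt(abs(score_window(lom, win) - int_score / 1000),
                6 / (2 * 1000) + 1e-12)
    }
  })
})
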