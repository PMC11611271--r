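# brute-force adjusted F1: materialize the 2x2 confusion matrix from
# the adjustment rules written out case by case
adjusted_f1_oracle <- function(truth, pred) {
  ta <- pa <- integer(length(truth))
  for (i in seq_along(truth)) {
    if (truth[i] == "Low") {
      ta[i] <- 0L
      pa[i] <- if (pred[i] == "High") 1L else 0L
    } else if (truth[i] == "High") {
      ta[i] <- 1L
      pa[i] <- if (pred[i] == "Low") 0L else 1L
    } else {
      ta[i] <- 1L
      pa[i] <- 1L
    }
  }
  tp <- sum(ta == 1 & pa == 1)
  fp <- sum(ta == 0 & pa == 1)
  fn <- sum(ta == 1 & pa == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

test_that("label adjustment follows the Mid-lenient remapping", {
  expect_equal(unlist(adjust_labels("Low", "Mid")), c(true_adj = 0L, pred_adj = 0L))
  expect_equal(unlist(adjust_labels("Low", "High")), c(true_adj = 0L, pred_adj = 1L))
  expect_equal(unlist(adjust_labels("High", "Mid")), c(true_adj = 1L, pred_adj = 1L))
  expect_equal(unlist(adjust_labels("High", "Low")), c(true_adj = 1L, pred_adj = 0L))
  expect_equal(unlist(adjust_labels("Mid", "Low")), c(true_adj = 1L, pred_adj = 1L))
  expect_error(adjust_labels("Lowish", "High"), class = "foldscan_label_error")
  expect_error(adjust_labels(c("Low", "High"), "High"),
               class = "foldscan_shape_error")
})

test_that("adjusted F1 matches its confusion-matrix definition", {
  truth <- c("Low", "Mid", "High")
  expect_equal(adjusted_f1(truth, truth), 1.0)
  bal <- rep(c("Low", "Mid", "High"), each = 7)
  expect_equal(adjusted_f1(bal, rep("High", 21)), 0.8)
  expect_equal(adjusted_f1(truth, c("High", "Mid", "Low")), 0.5)
  expect_warning(z <- adjusted_f1(rep("Low", 4), rep("Low", 4)), "undefined")
  expect_equal(z, 0)

  withr::with_seed(9, {
    classes <- c("Low", "Mid", "High")
    for (i in 1:50) {
      n <- sample(1:40, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      expect_equal(suppressWarnings(adjusted_f1(truth, pred)),
                   adjusted_f1_oracle(truth, pred))
    }
  })
})

test_that("the always-High baseline follows the closed form 2m/(2m+l)", {
  bal <- rep(c("Low", "Mid", "High"), each = 5)
  expect_equal(always_high_baseline(bal), 0.8)
  expect_equal(always_high_baseline(rep("Mid", 9)), 1.0)
  # all-Low truth: zero precision, F1 = 0
  expect_equal(always_high_baseline(rep("Low", 9)), 0)

  withr::with_seed(10, {
    for (i in 1:30) {
      truth <- sample(c("Low", "Mid", "High"), sample(2:50, 1), replace = TRUE)
      l <- sum(truth == "Low")
      m <- sum(truth != "Low")
      want <- if (m == 0) 0 else 2 * m / (2 * m + l)
      expect_equal(suppressWarnings(always_high_baseline(truth)), want)
    }
  })
})

test_that("macro F1 averages per-class scores", {
  truth <- c("Low", "Low", "Mid", "High")
  expect_equal(macro_f1(truth, truth), 1)
  expect_lt(macro_f1(truth, c("Low", "Mid", "Mid", "Low")), 1)
})

test_that("non-touchable accuracy counts agreeing scored positions", {
  mk <- function(flags, excluded = rep(FALSE, length(flags))) {
    tibble::new_tibble(
      tibble::tibble(position = seq_along(flags), score = NA_real_,
                     flag = as.integer(flags), excluded = excluded),
      nrow = length(flags), class = "fs_nontouchable",
      threshold_used = "mean", threshold_value = NA_real_
    )
  }
  measured <- mk(c(1, 0, 1, 0))
  expect_equal(nontouchable_accuracy(measured, mk(c(1, 1, 1, 0))), 0.75)
  expect_equal(nontouchable_accuracy(measured, measured), 1.0)
  # all-ones baseline accuracy equals the measured prevalence, exactly
  expect_equal(nontouchable_accuracy(measured, mk(c(1, 1, 1, 1))), 0.5)
  expect_equal(nontouchable_baseline(measured), 0.5)
  # excluded positions drop out of both numerator and denominator
  meas2 <- mk(c(1, 0, 1, 0), excluded = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nontouchable_accuracy(meas2, mk(c(0, 0, 1, 0))), 1.0)
  expect_error(nontouchable_accuracy(measured, mk(c(1, 0))),
               class = "foldscan_incompatible_maps")
})

test_that("unmatched score counts above-average residues in randomized regions", {
  imp <- rep(0, 36)
  imp[c(2, 5, 8, 11)] <- 1  # mean ~ 0.111
  expect_equal(unmatched_score(imp, list(c(1, 10))), 3 / 36)
  expect_equal(unmatched_score(imp, list(c(1, 10), c(11, 11))), 4 / 36)
  expect_equal(unmatched_score(rep(0.5, 36), list(c(1, 36))), 1.0)
  expect_equal(unmatched_score(imp, list(c(20, 30))), 0)
  expect_equal(unmatched_score(imp, list(c(5, 4))), 0)  # empty region
  expect_error(unmatched_score(imp, list(c(30, 40))),
               class = "foldscan_range_error")
  # monotone non-decreasing as regions grow
  u <- vapply(1:36, function(k) unmatched_score(imp, list(c(1, k))),
              numeric(1))
  expect_true(all(diff(u) >= 0))
})

test_that("spearman correlation equals Pearson on mid-ranks", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_rank_correlation(x, 2 * x + 1), 1.0)
  expect_equal(spearman_rank_correlation(x, -x), -1.0)
  # ties: brute-force mid-rank oracle
  a <- c(1, 2, 2, 4)
  b <- c(1, 3, 2, 4)
  expect_equal(spearman_rank_correlation(a, b),
               stats::cor(rank(a, ties.method = "average"),
                          rank(b, ties.method = "average"),
                          method = "pearson"))
  expect_error(spearman_rank_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "foldscan_undefined_correlation")
  expect_error(spearman_rank_correlation(1:2, 1:2),
               class = "foldscan_shape_error")
})

test_that("BLOSUM62 similarity follows the positive-pair convention", {
  expect_equal(pairwise_similarity("ACDEFGHIKLMNPQRSTVWY",
                                   "ACDEFGHIKLMNPQRSTVWY"), 100)
  expect_equal(pairwise_similarity("AAAA", "AAAT"), 75)
  expect_error(pairwise_similarity("ACDX", "ACDE"),
               class = "foldscan_alphabet_error")

  withr::with_seed(12, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:25) {
      a <- paste(sample(aas, sample(10:30, 1), replace = TRUE), collapse = "")
      b <- paste(sample(aas, sample(10:30, 1), replace = TRUE), collapse = "")
      expect_equal(pairwise_similarity(a, b), pairwise_similarity(b, a))
    }
  })

  m <- similarity_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(diag(m), c(a = 100, b = 100))
  expect_equal(m["a", "b"], 75)
})

test_that("hit rate is the fraction of successful campaigns", {
  camp <- tibble::tibble(target = letters[1:10],
                         success = c(rep(TRUE, 9), FALSE))
  expect_equal(hit_rate(camp), 0.9)
  expect_error(hit_rate(camp[0, ]))
})
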