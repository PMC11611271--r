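fs_check_classes <- function(x, arg) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("Low", "Mid", "High"))
  if (length(bad)) {
    abort(sprintf("unknown class token(s) in %s: %s", arg,
                  paste(bad, collapse = ", ")),
          class = "foldscan_label_error")
  }
  x
}

#' Collapse three foldability classes to adjusted binary labels
#'
#' The adjusted labels reduce (Low, Mid, High) to two classes, 0 = Low
#' and 1 = Mid-High, treating the inherently ambiguous Mid class
#' leniently: a Low truth scores the prediction 1 only when the model
#' said High (a serious error), a High truth scores 0 only when the
#' model said Low, and a Mid truth sets both labels to 1 regardless of
#' the prediction.
#'
#' @param truth,pred Vectors over {Low, Mid, High} (vectorized).
#' @return Tibble with columns `true_adj`, `pred_adj` (0/1).
#' @export
adjust_labels <- function(truth, pred) {
  truth <- fs_check_classes(truth, "truth")
  pred <- fs_check_classes(pred, "pred")
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length",
          class = "foldscan_shape_error")
  }
  true_adj <- ifelse(truth == "Low", 0L, 1L)
  pred_adj <- integer(length(pred))
  pred_adj[truth == "Low"] <- as.integer(pred[truth == "Low"] == "High")
  pred_adj[truth == "High"] <- as.integer(pred[truth == "High"] != "Low")
  pred_adj[truth == "Mid"] <- 1L
  tibble(true_adj = true_adj, pred_adj = pred_adj)
}

#' Adjusted F1 score
#'
#' Binary F1 on the adjusted labels of [adjust_labels()], with Mid-High
#' (1) as the positive class. When precision and recall are both
#' undefined or zero the score is 0 (with a warning).
#'
#' @inheritParams adjust_labels
#' @return Scalar in \[0, 1\].
#' @export
adjusted_f1 <- function(truth, pred) {
  adj <- adjust_labels(truth, pred)
  tp <- sum(adj$true_adj == 1 & adj$pred_adj == 1)
  fp <- sum(adj$true_adj == 0 & adj$pred_adj == 1)
  fn <- sum(adj$true_adj == 1 & adj$pred_adj == 0)
  if (2 * tp + fp + fn == 0) {
    warn("adjusted F1 undefined (no positive labels or predictions); returning 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Always-High baseline for the adjusted F1
#'
#' Adjusted F1 of a degenerate model that predicts High-foldability for
#' every sequence; with `l` Low and `m` Mid-or-High truths this equals
#' `2m / (2m + l)` (0.8 for balanced classes). A useful model must beat
#' it.
#'
#' @param truth Vector over {Low, Mid, High}.
#' @return Scalar in \[0, 1\].
#' @export
always_high_baseline <- function(truth) {
  truth <- fs_check_classes(truth, "truth")
  if (length(truth) == 0) abort("empty truth vector")
  adjusted_f1(truth, rep("High", length(truth)))
}

#' Standard macro-averaged F1 over the three classes
#'
#' Unadjusted macro F1 for reporting alongside the adjusted score;
#' classes absent from both truth and prediction are skipped.
#'
#' @inheritParams adjust_labels
#' @return Scalar in \[0, 1\].
#' @export
macro_f1 <- function(truth, pred) {
  truth <- fs_check_classes(truth, "truth")
  pred <- fs_check_classes(pred, "pred")
  if (length(truth) != length(pred)) {
    abort("truth and pred must have equal length",
          class = "foldscan_shape_error")
  }
  f1s <- vapply(c("Low", "Mid", "High"), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Accuracy of a predicted non-touchable map
#'
#' Fraction of scored positions where the predicted flag agrees with
#' the measured flag. Positions excluded in either map (cysteines,
#' never-randomized positions) are left out. The all-ones baseline
#' (`nontouchable_baseline()`) — a model that calls every residue
#' non-touchable — scores exactly the prevalence of measured
#' non-touchable flags.
#'
#' @param measured,predicted `fs_nontouchable` maps over the same
#'   scaffold (see [call_nontouchable()]).
#' @return Scalar in \[0, 1\].
#' @export
nontouchable_accuracy <- function(measured, predicted) {
  if (nrow(measured) != nrow(predicted)) {
    abort("maps cover different numbers of positions",
          class = "foldscan_incompatible_maps")
  }
  keep <- !measured$excluded & !predicted$excluded
  if (!any(keep)) abort("no scored positions shared between the maps",
                        class = "foldscan_incompatible_maps")
  mean(measured$flag[keep] == predicted$flag[keep])
}

#' @rdname nontouchable_accuracy
#' @export
nontouchable_baseline <- function(measured) {
  keep <- !measured$excluded
  mean(measured$flag[keep] == 1L)
}

#' Unmatched score of a legacy library design
#'
#' Audits a previously randomized library against a per-position
#' importance profile: mismatched residues are those inside the
#' randomized regions whose importance is at or above the scaffold-wide
#' average, and the unmatched score is their count divided by the
#' scaffold length. High unmatched scores flag designs that randomized
#' folding-critical positions and empirically correspond to low panning
#' hit rates.
#'
#' @param importance Per-position numeric importance (measured or
#'   predicted ES); its mean over non-`NA` entries is the threshold.
#' @param regions List of `c(start, end)` ranges (1-based inclusive)
#'   that were randomized.
#' @param scaffold_length Denominator; defaults to
#'   `length(importance)`.
#' @return Scalar in \[0, 1\].
#' @export
unmatched_score <- function(importance, regions,
                            scaffold_length = length(importance)) {
  pos <- unique(unlist(lapply(regions, function(r) {
    if (r[2] < r[1]) return(integer())
    seq(r[1], r[2])
  })))
  if (any(pos < 1 | pos > length(importance))) {
    abort("randomized regions fall outside the scaffold",
          class = "foldscan_range_error")
  }
  avg <- mean(importance, na.rm = TRUE)
  mismatched <- sum(!is.na(importance[pos]) & importance[pos] >= avg)
  mismatched / scaffold_length
}

#' Hit rate of a panning campaign table
#'
#' Successful campaigns divided by total campaigns.
#'
#' @param campaigns Data frame with a logical (or 0/1) `success`
#'   column, one row per panning campaign.
#' @return Scalar in \[0, 1\].
#' @export
hit_rate <- function(campaigns) {
  if (nrow(campaigns) == 0) abort("no campaigns supplied")
  mean(as.logical(campaigns$success))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors of length >= 3",
          class = "foldscan_shape_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "foldscan_undefined_correlation")
  }
  cor(x, y, method = "spearman")
}

fs_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Pairwise sequence similarity under BLOSUM62
#'
#' Global (Needleman-Wunsch) alignment of two peptide sequences under
#' the BLOSUM62 substitution matrix (gap opening -10, extension -1);
#' similarity is the percentage of alignment columns whose residue pair
#' has a strictly positive BLOSUM62 score (gap columns count in the
#' denominator). Identical sequences score 100.
#'
#' @param a,b Amino-acid sequences.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return Percent similarity in \[0, 100\].
#' @export
pairwise_similarity <- function(a, b, gap_opening = 10, gap_extension = 1) {
  for (s in c(a, b)) {
    if (!nzchar(s) || grepl(sprintf("[^%s]", paste(AMINO_ACIDS, collapse = "")), s)) {
      abort("sequences must be non-empty over the 20-letter alphabet",
            class = "foldscan_alphabet_error")
    }
  }
  B62 <- fs_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = B62,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  is_res <- al_a != "-" & al_b != "-"
  pos_score <- logical(length(al_a))
  pos_score[is_res] <- B62[cbind(al_a[is_res], al_b[is_res])] > 0
  100 * sum(pos_score) / length(al_a)
}

#' Pairwise similarity matrix for a set of scaffolds
#'
#' @param sequences Named character vector of scaffold sequences.
#' @return Symmetric numeric matrix of percent similarities
#'   (diagonal 100).
#' @export
similarity_matrix <- function(sequences) {
  n <- length(sequences)
  m <- matrix(100, n, n, dimnames = list(names(sequences), names(sequences)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      m[i, j] <- m[j, i] <- pairwise_similarity(sequences[[i]], sequences[[j]])
    }
  }
  m
}
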