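#' Per-sequence post/pre abundance ratios
#'
#' For every sequence present in the pre-sort library, the ratio of its
#' normalized frequency in the displayed (post-sort) population to its
#' normalized frequency in the original library. Sequences absent from
#' the post-sort table get ratio 0 (they failed to display). Sequences
#' absent from the pre-sort table have an undefined ratio and are
#' excluded by default; `pseudocount` adds 0.5 UMIs to both samples and
#' keeps them instead.
#'
#' @param pre,post Normalized count tables with the same denominator
#'   convention.
#' @param pseudocount If `TRUE`, add 0.5 UMIs to every sequence in both
#'   samples so post-only sequences are retained.
#' @return Tibble with columns `sequence`, `ratio`.
#' @export
sequence_ratios <- function(pre, post, pseudocount = FALSE) {
  d_pre <- attr(pre, "denominator")
  d_post <- attr(post, "denominator")
  if (!identical(d_pre, d_post)) {
    abort("pre and post tables use different normalization denominators",
          class = "foldscan_configuration_error")
  }
  if (is.null(d_pre) || is.na(d_pre)) {
    abort("tables must be normalized (see normalize_counts())",
          class = "foldscan_configuration_error")
  }
  if (pseudocount) {
    seqs <- union(pre$sequence, post$sequence)
    c_pre <- setNames(rep(0, length(seqs)), seqs)
    c_pre[pre$sequence] <- pre$count
    c_post <- setNames(rep(0, length(seqs)), seqs)
    c_post[post$sequence] <- post$count
    f_pre <- (c_pre + 0.5) / sum(c_pre + 0.5)
    f_post <- (c_post + 0.5) / sum(c_post + 0.5)
    return(tibble(sequence = seqs, ratio = unname(f_post / f_pre)))
  }
  f_post <- setNames(post$frequency, post$sequence)
  tibble(sequence = pre$sequence,
         ratio = unname(dplyr::coalesce(f_post[pre$sequence], 0)) /
           pre$frequency)
}

#' Label sequences by foldability percentiles
#'
#' Sequences whose post/pre ratio strictly exceeds the upper percentile
#' (default 95th) are labeled `High` foldability; those strictly below
#' the lower percentile (default 5th) are `Low`; the remainder are
#' `Mid`. Percentiles use linear interpolation between order statistics,
#' and the strict inequalities send boundary ties to `Mid`.
#'
#' @param ratios Tibble from [sequence_ratios()] (columns `sequence`,
#'   `ratio`), optionally with a `scaffold` column.
#' @param hi_pct,lo_pct Upper and lower percentile cutoffs (0-100).
#' @param scaffold_id Scaffold identifier stored with the records.
#' @return Tibble with columns `sequence`, `scaffold`, `ratio`, `label`
#'   (factor Low < Mid < High).
#' @export
assign_labels <- function(ratios, hi_pct = 95, lo_pct = 5,
                          scaffold_id = NULL) {
  if (nrow(ratios) < 20) {
    abort(sprintf("need at least 20 ratios to set percentiles, got %d",
                  nrow(ratios)),
          class = "foldscan_insufficient_data")
  }
  if (lo_pct >= hi_pct) abort("lo_pct must be below hi_pct")
  q <- quantile(ratios$ratio, c(lo_pct, hi_pct) / 100,
                type = 7, names = FALSE)
  label <- rep("Mid", nrow(ratios))
  label[ratios$ratio > q[2]] <- "High"
  label[ratios$ratio < q[1]] <- "Low"
  scaffold_col <- if ("scaffold" %in% names(ratios)) ratios$scaffold
  tibble(sequence = ratios$sequence,
         scaffold = scaffold_id %||% scaffold_col %||% NA_character_,
         ratio = ratios$ratio,
         label = factor(label, levels = c("Low", "Mid", "High")))
}

#' Downsample the Mid class to balance the dataset
#'
#' Uniformly subsamples the `Mid` records, without replacement, to
#' `min(|High|, |Low|)`, leaving `High` and `Low` untouched, so all
#' three classes are equally represented during training. Deterministic
#' under `seed`. If `Mid` is already at or below the target it is kept
#' whole with a warning.
#'
#' @param dataset Labeled tibble from [assign_labels()].
#' @param seed Integer seed for the subsample.
#' @return The balanced labeled tibble.
#' @export
balance_mid <- function(dataset, seed) {
  n_hi <- sum(dataset$label == "High")
  n_lo <- sum(dataset$label == "Low")
  target <- min(n_hi, n_lo)
  mid_idx <- which(dataset$label == "Mid")
  if (length(mid_idx) < target) {
    warn(sprintf("only %d Mid records available for a target of %d; keeping all",
                 length(mid_idx), target))
    return(dataset)
  }
  keep <- withr_seed(seed, sample(mid_idx, target))
  out <- dataset[sort(c(which(dataset$label != "Mid"), keep)), ]
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Leave-one-scaffold-out splits
#'
#' One split per scaffold: the scaffold's own records form the
#' validation set and the union of all other scaffolds' records the
#' training set, so every evaluation measures generalization to a
#' scaffold the model has never seen.
#'
#' @param datasets Named list of labeled tibbles (one per scaffold), or
#'   a single tibble with a `scaffold` column.
#' @return List of splits, each `list(scaffold=, train=, validation=)`.
#' @export
loso_splits <- function(datasets) {
  if (is.data.frame(datasets)) {
    datasets <- split(datasets, datasets$scaffold)
  }
  if (length(datasets) < 2) {
    abort("leave-one-scaffold-out needs at least 2 scaffolds",
          class = "foldscan_split_error")
  }
  ids <- names(datasets)
  lapply(ids, function(id) {
    list(scaffold = id,
         train = bind_rows(datasets[setdiff(ids, id)]),
         validation = datasets[[id]])
  })
}
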