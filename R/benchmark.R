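#' Label a sort experiment's sequences for training
#'
#' Convenience wrapper running [sequence_ratios()], [assign_labels()]
#' and [balance_mid()] on one experiment.
#'
#' @param experiment An `fs_sort_experiment`.
#' @param hi_pct,lo_pct Percentile cutoffs.
#' @param seed Seed for the Mid subsample.
#' @param balance Downsample Mid to `min(|High|, |Low|)`.
#' @return Labeled tibble (see [assign_labels()]).
#' @export
label_experiment <- function(experiment, hi_pct = 95, lo_pct = 5,
                             seed = 1, balance = TRUE) {
  ratios <- sequence_ratios(experiment$pre, experiment$post)
  labeled <- assign_labels(ratios, hi_pct = hi_pct, lo_pct = lo_pct,
                           scaffold_id = experiment$truth$scaffold$name)
  if (balance) labeled <- balance_mid(labeled, seed = seed)
  labeled
}

#' Measured ES profile of a sort experiment
#'
#' @param experiment An `fs_sort_experiment`.
#' @return An `fs_es_profile` from the experiment's pre/post frequency
#'   matrices.
#' @export
measure_es <- function(experiment) {
  es_profile(position_frequencies(experiment$pre, experiment$design),
             position_frequencies(experiment$post, experiment$design))
}

#' Leave-one-scaffold-out benchmark evaluation
#'
#' The package's end-to-end recovery experiment: for every scaffold in
#' a benchmark suite, train the classifier on the labeled, balanced
#' data of all other scaffolds, then (i) score foldability
#' classification on the held-out scaffold with the adjusted F1 against
#' the always-High baseline, and (ii) score Integrated-Gradients
#' non-touchable prediction against the measured non-touchable map and
#' the all-non-touchable baseline.
#'
#' @param suite An [make_benchmark_suite()] result.
#' @param config A [training_config()]; each fold trains with seed
#'   `config$seed + fold`.
#' @param hi_pct,lo_pct Labeling percentiles.
#' @param eval_on Evaluate on the held-out scaffold's `"balanced"`
#'   dataset (the same construction as training; default) or its
#'   `"full"` labeled dataset.
#' @param threshold Non-touchable threshold rule.
#' @param steps,target Integrated Gradients settings.
#' @param mode Attribution mode of [predicted_es_profile()].
#' @param keep_models Retain the per-fold models and attribution
#'   profiles in the result.
#' @return Object of class `fs_benchmark_eval`: list with `metrics`
#'   (one row per scaffold: `adjusted_f1`, `baseline_f1`, `macro_f1`,
#'   `nt_accuracy`, `nt_baseline`, sizes), `attributions`, and
#'   optionally `models`.
#' @export
evaluate_benchmark <- function(suite, config = training_config(),
                               hi_pct = 95, lo_pct = 5,
                               eval_on = c("balanced", "full"),
                               threshold = c("mean", "median"),
                               steps = 64,
                               target = c("probability", "logit"),
                               mode = c("parent", "top_high"),
                               keep_models = FALSE) {
  eval_on <- match.arg(eval_on)
  threshold <- match.arg(threshold)
  target <- match.arg(target)
  mode <- match.arg(mode)
  exps <- suite$experiments
  ids <- names(exps)

  balanced <- imap(exps, function(e, id) {
    label_experiment(e, hi_pct = hi_pct, lo_pct = lo_pct,
                     seed = config$seed + match(id, ids))
  })
  full <- imap(exps, function(e, id) {
    label_experiment(e, hi_pct = hi_pct, lo_pct = lo_pct, balance = FALSE)
  })
  splits <- loso_splits(balanced)

  rows <- list()
  models <- list()
  attributions <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cfg <- config
    cfg$seed <- config$seed + i
    model <- train_classifier(sp$train, cfg)
    eval_data <- if (eval_on == "balanced") sp$validation else full[[sp$scaffold]]
    preds <- predict_proba(model, eval_data$sequence)
    truth <- as.character(eval_data$label)
    pred <- as.character(preds$.pred_class)

    e <- exps[[sp$scaffold]]
    measured <- call_nontouchable(measure_es(e), threshold = threshold)
    prof <- predicted_es_profile(
      model, e$truth$scaffold, mode = mode,
      sequences = if (mode == "top_high") full[[sp$scaffold]]$sequence,
      steps = steps, target = target, threshold = threshold
    )
    rows[[i]] <- tibble(
      scaffold = sp$scaffold,
      n_train = nrow(sp$train), n_eval = nrow(eval_data),
      adjusted_f1 = adjusted_f1(truth, pred),
      baseline_f1 = always_high_baseline(truth),
      macro_f1 = macro_f1(truth, pred),
      nt_accuracy = nontouchable_accuracy(measured, prof$nontouchable),
      nt_baseline = nontouchable_baseline(measured),
      final_loss = tail(model$loss_history, 1)
    )
    attributions[[sp$scaffold]] <- prof
    if (keep_models) models[[sp$scaffold]] <- model
  }
  structure(
    list(metrics = bind_rows(rows), attributions = attributions,
         models = if (keep_models) models,
         labeled = balanced, eval_on = eval_on, config = config),
    class = "fs_benchmark_eval"
  )
}

#' @export
print.fs_benchmark_eval <- function(x, ...) {
  cat(sprintf("<fs_benchmark_eval> %d scaffolds (leave-one-scaffold-out, %s eval)\n",
              nrow(x$metrics), x$eval_on))
  print(x$metrics)
  invisible(x)
}

#' @method tidy fs_benchmark_eval
#' @export
tidy.fs_benchmark_eval <- function(x, ...) x$metrics

#' @method glance fs_benchmark_eval
#' @export
glance.fs_benchmark_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    n_scaffolds = nrow(m),
    mean_adjusted_f1 = mean(m$adjusted_f1),
    min_adjusted_f1 = min(m$adjusted_f1),
    n_above_baseline_f1 = sum(m$adjusted_f1 > m$baseline_f1),
    mean_nt_accuracy = mean(m$nt_accuracy),
    n_above_baseline_nt = sum(m$nt_accuracy > m$nt_baseline)
  )
}
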