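#' Integrated Gradients along a straight path
#'
#' Core path-integral attribution: for an objective `F` over a numeric
#' input `x` and a baseline `b`, the attribution of coordinate `i` is
#' `(x_i - b_i)` times the average of `dF/dx_i` along the straight line
#' from `b` to `x`. The integral is approximated with a Riemann sum
#' (midpoint rule by default, trapezoid as an option); by the
#' completeness axiom the attributions sum to `F(x) - F(b)` as the
#' number of steps grows.
#'
#' @param value_grad Function taking an input like `x` and returning
#'   `list(value = scalar, grad = gradient of value w.r.t. the input)`.
#' @param x Numeric vector or matrix input.
#' @param baseline Baseline input of the same shape.
#' @param steps Number of integration steps (>= 8).
#' @param rule `"midpoint"` or `"trapezoid"`.
#' @return Attributions with the shape of `x`; attributes `value_x`,
#'   `value_baseline` and `completeness_gap` record the endpoint values
#'   and `|sum(attributions) - (F(x) - F(b))|`.
#' @export
ig_path_attribution <- function(value_grad, x, baseline, steps = 64,
                                rule = c("midpoint", "trapezoid")) {
  rule <- match.arg(rule)
  if (steps < 8) abort("steps must be >= 8")
  diff <- x - baseline
  if (rule == "midpoint") {
    alphas <- (seq_len(steps) - 0.5) / steps
    weights <- rep(1 / steps, steps)
  } else {
    alphas <- seq(0, 1, length.out = steps + 1)
    weights <- c(0.5, rep(1, steps - 1), 0.5) / steps
  }
  avg_grad <- x * 0
  for (t in seq_along(alphas)) {
    g <- value_grad(baseline + alphas[t] * diff)$grad
    avg_grad <- avg_grad + weights[t] * g
  }
  attrib <- diff * avg_grad
  fx <- value_grad(x)$value
  fb <- value_grad(baseline)$value
  structure(attrib, value_x = fx, value_baseline = fb,
            completeness_gap = abs(sum(attrib) - (fx - fb)))
}

# value/gradient of the High-class objective w.r.t. token embeddings
fs_target_grad <- function(model, target) {
  cfg <- model$config
  function(Temb) {
    fw <- fs_forward(model$params, Temb, cfg, keep_cache = TRUE)
    p <- exp(fw$logits - max(fw$logits))
    p <- p / sum(p)
    if (target == "probability") {
      value <- p[3L]
      dlogits <- -p[3L] * p
      dlogits[3L] <- dlogits[3L] + p[3L]
    } else {
      value <- fw$logits[3L]
      dlogits <- c(0, 0, 1)
    }
    acc <- fs_zero_grads(model$params)
    grad <- fs_backward(model$params, fw$cache, dlogits, cfg, acc)
    list(value = value, grad = grad)
  }
}

#' Attribute the High-foldability prediction to residues
#'
#' Integrated Gradients attribution of the classifier's High-foldability
#' output to each residue of a sequence. The baseline is the null-token
#' embedding at every position (a sequence in a neutral state); the path
#' integral runs in embedding space from that baseline to the actual
#' residue embeddings, and each residue's attribution is the signed sum
#' over its embedding dimensions. The default target is the softmax
#' probability of the High class; the `"logit"` target avoids saturation
#' when probabilities are pinned near 0 or 1.
#'
#' @param model A trained `foldability_classifier`.
#' @param sequence One amino-acid sequence (within the model's
#'   `max_length`).
#' @param steps Integration steps (default 64).
#' @param target `"probability"` or `"logit"` of the High class.
#' @param rule Riemann rule, `"midpoint"` (default) or `"trapezoid"`.
#' @return Tibble with columns `position`, `residue`, `attribution`;
#'   attributes `value_x`, `value_baseline`, `completeness_gap`.
#' @export
integrated_gradients <- function(model, sequence, steps = 64,
                                 target = c("probability", "logit"),
                                 rule = c("midpoint", "trapezoid")) {
  target <- match.arg(target)
  rule <- match.arg(rule)
  if (!inherits(model, "foldability_classifier") ||
      is.null(model$params)) {
    abort("model must be a trained foldability_classifier",
          class = "foldscan_model_state")
  }
  batch <- encode_sequences(sequence, model$config$max_length)
  ids <- batch$ids[1L, seq_len(batch$lengths[1L])]
  L <- length(ids)
  x <- model$params$emb[ids, , drop = FALSE]
  baseline <- matrix(model$params$emb[NULL_ID, ], L,
                     model$config$emb_dim, byrow = TRUE)
  attrib <- ig_path_attribution(fs_target_grad(model, target), x, baseline,
                                steps = steps, rule = rule)
  out <- tibble(position = seq_len(L),
                residue = strsplit(sequence, "")[[1]],
                attribution = rowSums(attrib))
  attr(out, "value_x") <- attr(attrib, "value_x")
  attr(out, "value_baseline") <- attr(attrib, "value_baseline")
  attr(out, "completeness_gap") <- attr(attrib, "completeness_gap")
  out
}

#' Predicted per-residue ES from model attribution
#'
#' Uses Integrated Gradients to assign each scaffold position a
#' predicted enrichment score, then derives the non-touchable map by
#' thresholding at the scaffold-wide average. For honest evaluation the
#' model must have been trained without the target scaffold's data
#' (leave-one-scaffold-out discipline). The default attributes the
#' parent scaffold sequence; `mode = "top_high"` instead averages
#' attributions over the `k` library sequences with the highest
#' predicted High probability. Predicted ES shares the ranking of the
#' measured ES but not its scale, so only thresholding and ranking are
#' meaningful.
#'
#' @param model A trained `foldability_classifier`.
#' @param scaffold A [scaffold_spec()].
#' @param mode `"parent"` or `"top_high"`.
#' @param sequences Candidate library sequences (required for
#'   `"top_high"`).
#' @param k Number of top sequences averaged in `"top_high"` mode.
#' @param steps,target,rule Passed to [integrated_gradients()].
#' @param threshold Non-touchable threshold rule, `"mean"` or
#'   `"median"`.
#' @return Object of class `fs_attribution_profile`: list with
#'   `predicted_es` (tibble `position`, `residue`, `predicted_es`),
#'   `nontouchable` (see [call_nontouchable()]; cysteines excluded from
#'   metrics), `completeness_gap`, `mode`, and the scaffold.
#' @export
predicted_es_profile <- function(model, scaffold,
                                 mode = c("parent", "top_high"),
                                 sequences = NULL, k = 10, steps = 64,
                                 target = c("probability", "logit"),
                                 rule = c("midpoint", "trapezoid"),
                                 threshold = c("mean", "median")) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  rule <- match.arg(rule)
  threshold <- match.arg(threshold)
  if (scaffold$length > model$config$max_length) {
    abort("scaffold longer than the model's max_length",
          class = "foldscan_encoding_error")
  }
  seqs <- if (mode == "parent") {
    scaffold$sequence
  } else {
    if (is.null(sequences)) abort("mode 'top_high' needs candidate sequences")
    pp <- predict_proba(model, unique(sequences))
    pp$sequence[order(-pp$p_High)][seq_len(min(k, nrow(pp)))]
  }
  scores <- matrix(0, length(seqs), scaffold$length)
  gaps <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    a <- integrated_gradients(model, seqs[i], steps = steps,
                              target = target, rule = rule)
    scores[i, ] <- a$attribution
    gaps[i] <- attr(a, "completeness_gap")
  }
  predicted_es <- colMeans(scores)
  nontouchable <- call_nontouchable(predicted_es, threshold = threshold,
                                    exclude = scaffold$cys_positions)
  structure(
    list(scaffold = scaffold,
         predicted_es = tibble(position = seq_len(scaffold$length),
                               residue = scaffold$residues,
                               predicted_es = predicted_es),
         nontouchable = nontouchable,
         completeness_gap = max(gaps),
         mode = mode, n_sequences = length(seqs)),
    class = "fs_attribution_profile"
  )
}

#' @export
print.fs_attribution_profile <- function(x, ...) {
  cat(sprintf(
    "<fs_attribution_profile> %s (%s mode, %d seq): %d non-touchable of %d scored positions\n",
    x$scaffold$name, x$mode, x$n_sequences,
    sum(x$nontouchable$flag[!x$nontouchable$excluded]),
    sum(!x$nontouchable$excluded)))
  invisible(x)
}

#' @method tidy fs_attribution_profile
#' @export
tidy.fs_attribution_profile <- function(x, ...) {
  left_join(x$predicted_es,
            select(as_tibble(x$nontouchable), "position", "flag", "excluded"),
            by = "position")
}
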