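#' Plot an enrichment-score profile
#'
#' Heat map of the position-by-residue ES matrix with the per-position
#' wild-type ES as a bar chart underneath; the conventional view of a
#' shotgun alanine-scan experiment.
#'
#' @param object An `fs_es_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_es_profile
#' @export
autoplot.fs_es_profile <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s[!is.na(s$es), ],
                  ggplot2::aes(x = .data$position, y = .data$es)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0.4, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = s$position,
                                labels = paste0(s$residue, s$position)) +
    ggplot2::labs(x = NULL, y = "wild-type residue ES",
                  title = object$scaffold$name,
                  subtitle = "dashed line: criticality cutoff 0.4") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}

#' Plot a predicted-ES attribution profile
#'
#' @param object An `fs_attribution_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_attribution_profile
#' @export
autoplot.fs_attribution_profile <- function(object, ...) {
  d <- tidy(object)
  d$call <- ifelse(d$excluded, "excluded",
                   ifelse(d$flag == 1, "non-touchable", "amenable"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$predicted_es,
                                  fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`non-touchable` = "#d7301f",
                                          amenable = "#74a9cf",
                                          excluded = "grey70")) +
    ggplot2::scale_x_continuous(breaks = d$position,
                                labels = paste0(d$residue, d$position)) +
    ggplot2::labs(x = NULL, y = "predicted ES (IG attribution)",
                  title = object$scaffold$name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}

#' Plot the training loss of a classifier
#'
#' @param object A `foldability_classifier`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot foldability_classifier
#' @export
autoplot.foldability_classifier <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot benchmark metrics against their baselines
#'
#' Per-scaffold adjusted F1 (vs the always-High baseline) and
#' non-touchable accuracy (vs the all-non-touchable baseline).
#'
#' @param object An `fs_benchmark_eval`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_benchmark_eval
#' @export
autoplot.fs_benchmark_eval <- function(object, ...) {
  m <- object$metrics
  d <- bind_rows(
    tibble(scaffold = m$scaffold, metric = "adjusted F1",
           model = m$adjusted_f1, baseline = m$baseline_f1),
    tibble(scaffold = m$scaffold, metric = "non-touchable accuracy",
           model = m$nt_accuracy, baseline = m$nt_baseline)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scaffold)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$model), fill = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(y = .data$baseline), shape = 95,
                        size = 8, colour = "#d7301f") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "bars: model; red dash: baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
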