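#' Default end-to-end pipeline configuration
#'
#' All knobs of the simulate - count - enrich - label - train -
#' attribute - evaluate - design pipeline with their defaults: the
#' nine-scaffold benchmark conditions, 95/5 labeling percentiles, the
#' desk training preset, 64-step Integrated Gradients toward the High
#' probability, the 0.4 criticality cutoff and mean non-touchable
#' threshold, and matched-UMI normalization. Every stochastic step
#' derives its seed from the single `seed` field.
#'
#' @param ... Named overrides of any field (nested fields as lists).
#' @return A named list (class `fs_pipeline_config`).
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_scaffolds = 9L, library_size = 500L, depth = 50000L,
                    n_critical = 5L, beta = 3),
    labeling = list(hi_pct = 95, lo_pct = 5),
    training = list(preset = "desk"),
    attribution = list(steps = 64L, target = "probability", mode = "parent"),
    thresholds = list(critical_cutoff = 0.4, nontouchable = "mean"),
    denominator = "matched_umis",
    eval_on = "balanced",
    design_codon = "NNK",
    out_dir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[nm] <- over[nm]
    }
  }
  structure(cfg, class = "fs_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; problems are returned, not thrown.
#'
#' @param config A pipeline configuration list.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(!is.null(config$labeling$hi_pct) && !is.null(config$labeling$lo_pct) &&
        config$labeling$lo_pct < config$labeling$hi_pct,
      "percentile order: lo_pct must be below hi_pct")
  chk(config$thresholds$nontouchable %in% c("mean", "median"),
      "nontouchable threshold must be one of: mean, median")
  chk(is.numeric(config$thresholds$critical_cutoff),
      "critical_cutoff must be numeric")
  chk(config$denominator %in% c("matched_umis", "total_reads"),
      "denominator must be one of: matched_umis, total_reads")
  chk(config$eval_on %in% c("balanced", "full"),
      "eval_on must be one of: balanced, full")
  chk(config$training$preset %in% c("desk", "published"),
      "training preset must be one of: desk, published")
  chk(is.numeric(config$attribution$steps) && config$attribution$steps >= 8,
      "attribution steps must be >= 8")
  chk(config$attribution$target %in% c("probability", "logit"),
      "attribution target must be one of: probability, logit")
  chk(config$simulate$n_scaffolds >= 2, "need at least 2 scaffolds")
  errs
}

#' Read / write a pipeline configuration file
#'
#' YAML or JSON by file extension; configurations round-trip
#' losslessly.
#'
#' @param config A pipeline configuration.
#' @param path File ending in `.yaml`, `.yml` or `.json`.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$out_dir <- cfg$out_dir %||% NULL
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_pipeline_config, raw)
}

fs_log <- function(...) message("[foldscan] ", sprintf(...))

#' Run the full pipeline
#'
#' Executes the stages end to end from a single configuration:
#' simulate the benchmark suite, compute measured ES profiles and
#' critical/non-touchable calls, label and balance the datasets, train
#' under leave-one-scaffold-out cross-validation, attribute with
#' Integrated Gradients, evaluate against the baselines, and emit
#' positive/negative randomization designs from the predicted
#' non-touchable maps. Progress is logged to standard error; the
#' machine-readable report (and design JSONs) are written under
#' `config$out_dir` when set.
#'
#' @param config A [default_pipeline_config()] (or overrides list /
#'   path handled by [read_pipeline_config()]).
#' @return The report: a named list (class `fs_pipeline_report`) with
#'   the resolved config, the suite manifest, per-scaffold metrics,
#'   critical-position calls and design summaries.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errs <- validate_config(config)
  if (length(errs)) {
    abort(paste0("invalid pipeline config:\n  ",
                 paste(errs, collapse = "\n  ")))
  }
  fs_log("stage simulate: %d scaffolds (seed %d)",
         config$simulate$n_scaffolds, config$seed)
  suite <- make_benchmark_suite(
    n_scaffolds = config$simulate$n_scaffolds, seed = config$seed,
    library_size = config$simulate$library_size,
    depth = config$simulate$depth,
    n_critical = config$simulate$n_critical, beta = config$simulate$beta
  )
  tr_over <- config$training[setdiff(names(config$training), "preset")]
  tcfg <- do.call(training_config,
                  c(list(preset = config$training$preset), tr_over,
                    list(seed = config$seed)))
  fs_log("stage train/attribute/evaluate: preset %s, %d epochs",
         tcfg$preset, tcfg$epochs)
  ev <- evaluate_benchmark(
    suite, tcfg,
    hi_pct = config$labeling$hi_pct, lo_pct = config$labeling$lo_pct,
    eval_on = config$eval_on,
    threshold = config$thresholds$nontouchable,
    steps = config$attribution$steps, target = config$attribution$target,
    mode = config$attribution$mode
  )
  fs_log("stage design: codon %s", config$design_codon)
  designs <- imap(ev$attributions, function(prof, id) {
    sc <- prof$scaffold
    pos_design <- build_randomization_design(sc, prof$nontouchable,
                                             codon = config$design_codon)
    neg_design <- build_randomization_design(sc, prof$nontouchable,
                                             codon = config$design_codon,
                                             negative = TRUE)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_design_json(pos_design,
                        file.path(config$out_dir, paste0(id, "_positive.json")))
      write_design_json(neg_design,
                        file.path(config$out_dir, paste0(id, "_negative.json")))
    }
    list(scaffold = id,
         n_amenable = sum(prof$nontouchable$flag == 0L),
         positive_diversity = theoretical_diversity(pos_design),
         negative_diversity = theoretical_diversity(neg_design))
  })
  critical <- imap(suite$experiments, function(e, id) {
    as.integer(call_critical(measure_es(e),
                             cutoff = config$thresholds$critical_cutoff))
  })
  report <- structure(
    list(config = unclass(config),
         manifest = as.data.frame(suite$manifest),
         metrics = as.data.frame(ev$metrics),
         summary = as.data.frame(glance(ev)),
         critical_positions = critical,
         designs = unname(designs)),
    class = "fs_pipeline_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    fs_log("report written to %s", file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.fs_pipeline_report <- function(x, ...) {
  cat("<fs_pipeline_report>\n")
  print(as_tibble(x$metrics))
  print(as_tibble(x$summary))
  invisible(x)
}
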