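#' Position-by-residue frequency matrix
#'
#' Aggregates normalized per-sequence frequencies into per-position
#' residue frequencies: `freq[p, a]` is the summed frequency of all
#' sequences carrying residue `a` at position `p`. Computed for the
#' pre-sort library this is the "original" frequency F_orig; for the
#' post-sort (displayed) population it is the "expressed" frequency
#' F_exp.
#'
#' @param table A normalized count table (see [normalize_counts()]).
#' @param design The `library_design` the table was matched against.
#' @return Tibble with columns `position`, `residue`, `frequency`; the
#'   design is carried in the `"design"` attribute.
#' @export
position_frequencies <- function(table, design) {
  if (nrow(table) == 0) {
    abort("empty count table", class = "foldscan_empty_sample")
  }
  if (!"frequency" %in% names(table)) {
    abort("table has no frequency column; call normalize_counts() first")
  }
  len <- design$scaffold$length
  mat <- do.call(rbind, strsplit(table$sequence, ""))
  out <- purrr::map_dfr(seq_len(len), function(p) {
    f <- tapply(table$frequency, mat[, p], sum)
    tibble(position = p, residue = names(f), frequency = as.numeric(f))
  })
  attr(out, "design") <- design
  out
}

#' The Enrichment Score
#'
#' The conditional statistic comparing a residue's frequency in the
#' expressed (post-sort) population with its frequency in the original
#' library:
#' \deqn{ES = (F_{exp} - F_{orig}) / (1 - F_{orig})} when
#' \eqn{F_{exp} > F_{orig}}, and
#' \deqn{ES = (F_{exp} - F_{orig}) / F_{orig}} otherwise.
#' ES lies in \[-1, 1\]: positive values mark enrichment after sorting
#' (residues needed for display, hence folding), negative values
#' de-enrichment. A residue absent from both samples (the indeterminate
#' 0/0 case of the second branch) scores 0, encoding "no information".
#'
#' @param f_exp,f_orig Frequencies in \[0, 1\] (vectorized).
#' @return Numeric vector of enrichment scores in \[-1, 1\].
#' @export
enrichment_score <- function(f_exp, f_orig) {
  if (any(f_exp < 0 | f_exp > 1 | f_orig < 0 | f_orig > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]", class = "foldscan_domain_error")
  }
  up <- f_exp > f_orig
  es <- numeric(length(f_exp))
  es[up] <- (f_exp[up] - f_orig[up]) / (1 - f_orig[up])
  dn <- !up & f_orig > 0
  es[dn] <- (f_exp[dn] - f_orig[dn]) / f_orig[dn]
  # remaining: f_exp <= f_orig with f_orig == 0, i.e. 0/0 -> 0
  es
}

#' Enrichment-score profile of a sorting experiment
#'
#' Applies [enrichment_score()] element-wise to the pre- and post-sort
#' position-frequency matrices of one scaffold, and summarises each
#' position by the ES of its wild-type residue: in a shotgun alanine
#' scan, enrichment of the retained wild-type residue is the natural
#' per-position measure of how much folding depends on that residue.
#' Positions never randomized in the design (cysteines and other fixed
#' positions) carry no measurable ES and are reported as `NA` in the
#' summary.
#'
#' @param pre,post Position-frequency tibbles from
#'   [position_frequencies()] for the pre-sort and displayed samples of
#'   the same design.
#' @return An object of class `fs_es_profile`: list with `scores` (long
#'   tibble `position`, `residue`, `f_orig`, `f_exp`, `es`), `summary`
#'   (tibble `position`, `residue`, `es`), and the scaffold.
#' @export
es_profile <- function(pre, post) {
  design <- attr(pre, "design")
  design_post <- attr(post, "design")
  if (!is.null(design) && !is.null(design_post) &&
      !identical(design$scaffold$sequence, design_post$scaffold$sequence)) {
    abort("pre and post matrices come from different scaffolds",
          class = "foldscan_incompatible_matrices")
  }
  if (is.null(design)) abort("pre matrix lacks its design attribute")
  scores <- dplyr::full_join(
    rename(pre, f_orig = "frequency"),
    rename(post, f_exp = "frequency"),
    by = c("position", "residue")
  ) |>
    mutate(f_orig = dplyr::coalesce(.data$f_orig, 0),
           f_exp = dplyr::coalesce(.data$f_exp, 0)) |>
    arrange(.data$position, .data$residue)
  scores$es <- enrichment_score(scores$f_exp, scores$f_orig)

  sc <- design$scaffold
  randomized <- lengths(design$allowed) > 1
  summary <- tibble(position = seq_len(sc$length),
                    residue = sc$residues) |>
    left_join(select(scores, "position", "residue", "es"),
              by = c("position", "residue"))
  summary$es[!randomized] <- NA_real_

  structure(list(scores = scores, summary = summary,
                 scaffold = sc, design = design),
            class = "fs_es_profile")
}

#' @export
print.fs_es_profile <- function(x, ...) {
  cat(sprintf("<fs_es_profile> %s: %d positions, %d randomized\n",
              x$scaffold$name, x$scaffold$length,
              sum(!is.na(x$summary$es))))
  print(x$summary, n = 6)
  invisible(x)
}

#' @method tidy fs_es_profile
#' @export
tidy.fs_es_profile <- function(x, ...) x$scores

#' @method glance fs_es_profile
#' @export
glance.fs_es_profile <- function(x, ...) {
  tibble(scaffold = x$scaffold$name,
         n_positions = x$scaffold$length,
         n_randomized = sum(!is.na(x$summary$es)),
         mean_wt_es = mean(x$summary$es, na.rm = TRUE),
         max_wt_es = max(x$summary$es, na.rm = TRUE))
}

#' Max-normalize a per-position ES summary
#'
#' Divides the per-position wild-type ES by its maximum so the highest
#' score within the scaffold is exactly 1, the convention used to
#' compare profiles across scaffolds. When no entry is positive the
#' profile is returned unchanged with a warning (a scaffold with no
#' enriched residue has no meaningful normalization).
#'
#' @param profile An `fs_es_profile`.
#' @return The profile with an `es_normalized` column in its summary.
#' @export
max_normalize_profile <- function(profile) {
  es <- profile$summary$es
  m <- suppressWarnings(max(es, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) {
    warn("no positive ES entry; profile left unnormalized")
    profile$summary$es_normalized <- es
    return(profile)
  }
  profile$summary$es_normalized <- es / m
  profile
}

#' Call folding-critical positions
#'
#' Positions whose wild-type-residue ES meets the criticality cutoff.
#' The default 0.4 reflects that well-designed hyperstable scaffolds
#' show mostly positive ES with a median near 0.4, so residues at or
#' above it are considered indispensable for folding.
#'
#' @param profile An `fs_es_profile`.
#' @param cutoff ES threshold (default 0.4).
#' @return Integer vector of 1-based critical positions.
#' @export
call_critical <- function(profile, cutoff = 0.4) {
  s <- profile$summary
  s$position[!is.na(s$es) & s$es >= cutoff]
}

#' Call non-touchable residues
#'
#' A position is non-touchable when its per-position score is at or
#' above the scaffold-wide average (arithmetic mean by default; the
#' median variant is also used in practice). Non-touchable positions are
#' excluded from library randomization; the remaining, "amenable"
#' positions are eligible. Excluded positions (cysteines, positions the
#' design never varied, or any `NA` score) are flagged non-touchable by
#' convention but marked `excluded` so accuracy metrics can skip them.
#'
#' @param scores Per-position numeric scores (measured or predicted ES;
#'   `NA` allowed), or an `fs_es_profile` whose summary supplies them.
#' @param threshold `"mean"` or `"median"`.
#' @param exclude Additional 1-based positions to exclude (e.g. cysteine
#'   positions).
#' @return Tibble of class `fs_nontouchable` with columns `position`,
#'   `score`, `flag` (0/1), `excluded`; the threshold used and its value
#'   are stored as attributes.
#' @export
call_nontouchable <- function(scores, threshold = c("mean", "median"),
                              exclude = integer()) {
  threshold <- match.arg(threshold)
  if (inherits(scores, "fs_es_profile")) {
    exclude <- union(exclude, scores$scaffold$cys_positions)
    scores <- scores$summary$es
  }
  n <- length(scores)
  excluded <- is.na(scores) | seq_len(n) %in% exclude
  thr_fun <- if (threshold == "mean") mean else stats::median
  thr <- thr_fun(scores[!excluded])
  flag <- as.integer(!excluded & !is.na(scores) & scores >= thr)
  flag[excluded] <- 1L
  tibble::new_tibble(
    tibble(position = seq_len(n), score = as.numeric(scores),
           flag = flag, excluded = excluded),
    nrow = n, class = "fs_nontouchable",
    threshold_used = threshold, threshold_value = thr
  )
}
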