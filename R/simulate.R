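# Residue pools for synthetic scaffolds. Folding-critical positions
# carry strongly hydrophobic core residues; the remaining background is
# polar/small. This emulates the hydrophobic-core folding determinant of
# small disulfide-constrained folds: burying the core residues (and
# pairing the cysteines) is what selection rewards, so criticality is a
# property a sequence model can read off the residues themselves.
CORE_RESIDUES <- c("F", "I", "L", "M", "V", "W")
BACKGROUND_RESIDUES <- setdiff(AMINO_ACIDS, c("C", CORE_RESIDUES))

#' Generate a random synthetic scaffold with planted critical positions
#'
#' Draws a scaffold in the supported size range (28-47 residues, 4 or 6
#' non-adjacent cysteines, i.e. 2-3 disulfides), plants `n_critical`
#' folding-critical positions among the non-cysteine residues, and
#' assigns strongly hydrophobic core residues there against a
#' polar/small background. Uses the current RNG state; seed upstream.
#'
#' @param name Scaffold identifier.
#' @param length Scaffold length (default: uniform over 28-47).
#' @param n_cys Number of cysteines, 4 or 6 (default: random).
#' @param n_critical Number of planted critical positions (default 5).
#' @return List with elements `scaffold` (a [scaffold_spec()]) and
#'   `critical_positions`.
#' @export
random_scaffold <- function(name, length = NULL, n_cys = NULL,
                            n_critical = 5) {
  len <- length %||% sample(28:47, 1)
  nc <- n_cys %||% sample(c(4L, 6L), 1)
  repeat {
    cys <- sort(sample(len, nc))
    if (all(diff(cys) >= 2)) break
  }
  non_cys <- setdiff(seq_len(len), cys)
  critical <- sort(sample(non_cys, n_critical))
  res <- character(len)
  res[cys] <- "C"
  bg <- setdiff(non_cys, critical)
  res[bg] <- sample(BACKGROUND_RESIDUES, length(bg), replace = TRUE)
  res[critical] <- sample(CORE_RESIDUES, n_critical, replace = TRUE)
  list(scaffold = scaffold_spec(name, paste(res, collapse = "")),
       critical_positions = critical)
}

#' Planted ground truth for a simulated selection
#'
#' The simulator's foldability model is additive-logistic: retaining
#' the wild-type residue at each planted critical position contributes
#' `beta` to the log-odds of successful display, on top of the baseline
#' `beta0`. The default `beta0 = -(sum(beta) - mean(beta))/2` puts the
#' display midpoint just below half the critical residues, so a fully
#' retained variant displays almost surely while a fully mutated one
#' still displays at a small but sequenceable rate — one round of FACS
#' enrichment, not an absolute kill, keeping the de-enriched tail
#' quantifiable in the post-sort sample.
#'
#' @param scaffold A [scaffold_spec()].
#' @param critical_positions 1-based positions (must exclude
#'   cysteines).
#' @param beta Per-critical-position log-odds effect (scalar recycled,
#'   or one value per position); positive values encode a folding
#'   benefit of the wild-type residue.
#' @param beta0 Baseline log-odds.
#' @return Object of class `fs_ground_truth`.
#' @export
ground_truth <- function(scaffold, critical_positions, beta = 3,
                         beta0 = NULL) {
  critical_positions <- sort(as.integer(critical_positions))
  if (any(critical_positions %in% scaffold$cys_positions)) {
    abort("critical positions must exclude cysteines")
  }
  beta <- rep_len(beta, length(critical_positions))
  beta0 <- beta0 %||% (-(sum(beta) - mean(beta)) / 2)
  structure(
    list(scaffold = scaffold, critical_positions = critical_positions,
         beta = setNames(beta, critical_positions), beta0 = beta0),
    class = "fs_ground_truth"
  )
}

#' Display (foldability) probability under the planted truth
#'
#' `logistic(beta0 + sum over critical positions of beta * [residue ==
#' wild type])`, vectorized over sequences.
#'
#' @param sequences Character vector, each of scaffold length.
#' @param truth An [ground_truth()] object.
#' @return Numeric vector of probabilities.
#' @export
foldability_prob <- function(sequences, truth) {
  len <- truth$scaffold$length
  if (any(nchar(sequences) != len)) {
    abort("sequences must have the scaffold's length",
          class = "foldscan_shape_error")
  }
  if (length(truth$critical_positions) == 0) {
    return(rep(stats::plogis(truth$beta0), length(sequences)))
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  wt <- truth$scaffold$residues
  eta <- truth$beta0
  for (j in seq_along(truth$critical_positions)) {
    p <- truth$critical_positions[j]
    eta <- eta + truth$beta[[j]] * (mat[, p] == wt[p])
  }
  as.numeric(stats::plogis(eta))
}

#' Simulate one sort-seq experiment
#'
#' Samples a library of unique variants uniformly from the design's
#' combinatorial space, then draws the pre-sort sample as a multinomial
#' over variants with uniform weights and the post-sort (displayed)
#' sample with weights proportional to each variant's foldability
#' probability — one round of FACS enrichment. Count tables are
#' UMI-count tables normalized over matched UMIs; variants unobserved
#' in a sample are absent from its table, as in real sequencing.
#'
#' @param design A `library_design`.
#' @param truth A matching [ground_truth()].
#' @param library_size Number of unique variants (clamped to the
#'   design's theoretical diversity with a warning).
#' @param depth Reads (UMI-tagged molecules) per sample.
#' @param seed Integer seed; equal seeds give identical experiments.
#' @return Object of class `fs_sort_experiment` with fields `pre`,
#'   `post` (normalized count tables), `truth`, `design`, `library`.
#' @export
simulate_sort_experiment <- function(design, truth, library_size = 500,
                                     depth = 50000, seed = 1) {
  if (!identical(design$scaffold$sequence, truth$scaffold$sequence)) {
    abort("truth and design refer to different scaffolds")
  }
  div <- theoretical_diversity(design)
  if (library_size > div) {
    warn(sprintf("library_size %d exceeds theoretical diversity %.0f; clamping",
                 library_size, div))
    library_size <- div
  }
  withr_seed(seed, {
    variants <- character(0)
    for (round in 1:1000) {
      variants <- unique(c(variants, sample_design(design, library_size)))
      if (length(variants) >= library_size) break
    }
    variants <- head(variants, library_size)
    n <- length(variants)
    pre_counts <- drop(rmultinom(1, depth, rep(1 / n, n)))
    w <- foldability_prob(variants, truth)
    post_counts <- drop(rmultinom(1, depth, w / sum(w)))

    mk <- function(counts, tag) {
      keep <- counts > 0
      tab <- as_count_table(
        tibble(sequence = variants[keep], count = counts[keep]),
        sample_id = paste0(truth$scaffold$name, "_", tag),
        total = depth, scaffold_name = truth$scaffold$name
      )
      normalize_counts(tab, "matched_umis")
    }
    structure(
      list(pre = mk(pre_counts, "pre"), post = mk(post_counts, "post"),
           truth = truth, design = design, library = variants, seed = seed),
      class = "fs_sort_experiment"
    )
  })
}

#' @export
print.fs_sort_experiment <- function(x, ...) {
  cat(sprintf(
    "<fs_sort_experiment> %s: %d unique variants, %d reads/sample, %d critical positions\n",
    x$truth$scaffold$name, length(x$library), total_reads(x$pre),
    length(x$truth$critical_positions)))
  invisible(x)
}

#' Analytic expected wild-type ES under the planted truth
#'
#' For a shotgun alanine-scan library sampled uniformly (each scanned
#' position wild-type or Ala with probability 1/2), the expected
#' post-sort frequency of the wild-type residue at a position follows
#' in closed form from averaging the logistic display weight over the
#' binomial count of other retained critical residues; scanned
#' non-critical positions have expected ES 0, and never-scanned
#' positions are `NA`. Used as the law-of-large-numbers reference for
#' the simulator.
#'
#' @param truth A [ground_truth()].
#' @param design The shotgun alanine-scan `library_design`.
#' @return Tibble with columns `position`, `es_expected`.
#' @export
expected_wt_es <- function(truth, design) {
  len <- truth$scaffold$length
  scanned <- which(lengths(design$allowed) > 1)
  k <- length(truth$critical_positions)
  es <- rep(NA_real_, len)
  es[setdiff(scanned, truth$critical_positions)] <- 0
  for (j in seq_along(truth$critical_positions)) {
    p <- truth$critical_positions[j]
    if (!p %in% scanned) next
    others <- truth$beta[-j]
    ko <- length(others)
    # distribution of the summed retained effects at the other criticals
    eff <- 0
    if (ko > 0) {
      combos <- expand.grid(rep(list(c(0, 1)), ko))
      eff <- as.matrix(combos) %*% others
    }
    w_ret <- mean(stats::plogis(truth$beta0 + truth$beta[j] + eff))
    w_mut <- mean(stats::plogis(truth$beta0 + eff))
    f_exp <- w_ret / (w_ret + w_mut)
    es[p] <- enrichment_score(f_exp, 0.5)
  }
  tibble(position = seq_len(len), es_expected = es)
}

# first codon (alphabetically) for each amino acid under the standard code
fs_codon_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- sort(names(gc))
      map <<- vapply(split(codons, gc[codons]), min, "")
    }
    map
  }
})

int_to_umi <- function(i, width) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("A", length(i), width)
  i <- i - 1L
  for (pos in width:1) {
    out[, pos] <- bases[(i %% 4L) + 1L]
    i <- i %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

#' Emit simulated FASTQ reads for a sort experiment
#'
#' Turns the experiment's count tables back into UMI-tagged merged
#' reads: every counted UMI becomes `reads_per_umi` reads carrying a
#' distinct UMI, the anchors of the layout, and the variant's coding
#' sequence (reverse-translated with the design's codons where given,
#' otherwise the alphabetically first codon per amino acid, so emission
#' is deterministic given the seed). In error-free mode the pipeline
#' inversion is exact: [count_sequences()] on the emitted files
#' recovers the experiment's count tables. An optional uniform per-base
#' substitution rate exercises the rejection paths.
#'
#' @param experiment An `fs_sort_experiment`.
#' @param layout A [read_layout()].
#' @param dir Output directory for `pre.fastq` / `post.fastq` (add
#'   `gzip = TRUE` for `.gz`).
#' @param seed Integer seed (UMI assignment, read order, errors).
#' @param reads_per_umi Reads emitted per distinct UMI.
#' @param error_rate Per-base substitution probability.
#' @param gzip Compress outputs.
#' @return Named character vector with the two FASTQ paths.
#' @export
emit_reads <- function(experiment, layout, dir, seed = 1,
                       reads_per_umi = 1, error_rate = 0, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cds_of <- function(protein) {
    aa <- strsplit(protein, "")[[1]]
    paste(fs_codon_map()[aa], collapse = "")
  }
  withr_seed(seed, {
    paths <- c(pre = file.path(dir, paste0("pre.fastq", if (gzip) ".gz" else "")),
               post = file.path(dir, paste0("post.fastq", if (gzip) ".gz" else "")))
    for (tag in c("pre", "post")) {
      tab <- experiment[[tag]]
      n_umi <- sum(tab$count)
      umis <- int_to_umi(sample.int(4^layout$umi_length, n_umi),
                         layout$umi_length)
      cds <- vapply(tab$sequence, cds_of, "", USE.NAMES = FALSE)
      body <- paste0(layout$anchor5, rep(cds, tab$count), layout$anchor3)
      reads <- if (layout$umi_side == "5prime") {
        paste0(umis, body)
      } else {
        paste0(body, umis)
      }
      reads <- rep(reads, each = reads_per_umi)
      if (error_rate > 0) {
        n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
        for (i in which(n_err > 0)) {
          pos <- sample(nchar(reads[i]), n_err[i])
          chars <- strsplit(reads[i], "")[[1]]
          chars[pos] <- sample(c("A", "C", "G", "T", "N"), n_err[i],
                               replace = TRUE)
          reads[i] <- paste(chars, collapse = "")
        }
      }
      reads <- reads[sample.int(length(reads))]
      con <- if (gzip) gzfile(paths[[tag]], "w") else file(paths[[tag]], "w")
      writeLines(paste0("@", tag, "_", seq_along(reads), "\n", reads, "\n+\n",
                        strrep("I", nchar(reads))), con, sep = "\n")
      close(con)
    }
    paths
  })
}

#' Build the default nine-scaffold synthetic benchmark
#'
#' Generates `n_scaffolds` random scaffolds with distinct sequences and
#' planted critical sets, a full-coverage shotgun alanine-scan design
#' for each (every non-Cys, non-Ala position scans wild-type vs Ala),
#' and one simulated sort experiment per scaffold under shared
#' generation parameters. The manifest records each scaffold's length,
#' cysteines and planted criticals, plus the spread of pairwise
#' BLOSUM62 similarities across scaffolds.
#'
#' @param n_scaffolds Number of scaffolds (default 9).
#' @param seed Integer seed controlling everything.
#' @param library_size,depth Per-experiment sampling scale.
#' @param n_critical,beta,beta0 Planted-truth parameters (see
#'   [ground_truth()]).
#' @return Object of class `fs_benchmark_suite`: named list fields
#'   `experiments`, `manifest`, `similarity`.
#' @export
make_benchmark_suite <- function(n_scaffolds = 9, seed = 1,
                                 library_size = 500, depth = 50000,
                                 n_critical = 5, beta = 3, beta0 = NULL) {
  if (n_scaffolds < 2) abort("need at least 2 scaffolds")
  scafs <- withr_seed(seed, {
    lapply(seq_len(n_scaffolds), function(i) {
      random_scaffold(sprintf("S%02d", i), n_critical = n_critical)
    })
  })
  experiments <- list()
  for (i in seq_len(n_scaffolds)) {
    sc <- scafs[[i]]
    design <- build_alanine_scan_design(sc$scaffold, c(1, sc$scaffold$length))
    truth <- ground_truth(sc$scaffold, sc$critical_positions,
                          beta = beta, beta0 = beta0)
    experiments[[sc$scaffold$name]] <- simulate_sort_experiment(
      design, truth, library_size = library_size, depth = depth,
      seed = seed + 101L * i
    )
  }
  manifest <- purrr::map_dfr(experiments, function(e) {
    tibble(scaffold = e$truth$scaffold$name,
           length = e$truth$scaffold$length,
           n_cys = length(e$truth$scaffold$cys_positions),
           n_critical = length(e$truth$critical_positions),
           critical_positions = paste(e$truth$critical_positions,
                                      collapse = ","),
           n_variants = length(e$library))
  })
  seqs <- setNames(vapply(experiments, function(e) e$truth$scaffold$sequence, ""),
                   names(experiments))
  sim <- similarity_matrix(seqs)
  off <- sim[lower.tri(sim)]
  manifest$mean_similarity <- mean(off)
  structure(list(experiments = experiments, manifest = manifest,
                 similarity = sim, seed = seed),
            class = "fs_benchmark_suite")
}

#' @export
print.fs_benchmark_suite <- function(x, ...) {
  cat(sprintf("<fs_benchmark_suite> %d scaffolds (seed %d)\n",
              length(x$experiments), x$seed))
  print(x$manifest)
  invisible(x)
}
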