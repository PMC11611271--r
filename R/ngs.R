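#' Describe the layout of a merged amplicon read
#'
#' A merged sort-seq read carries a random UMI on one side, a fixed
#' anchor sequence immediately before the peptide-coding region, the
#' coding region itself, and a second anchor after it. The layout tells
#' the counting pipeline where to find each part.
#'
#' @param umi_length UMI length in bases (>= 0).
#' @param umi_side Side of the read carrying the UMI, `"5prime"` or
#'   `"3prime"`.
#' @param anchor5,anchor3 Constant nucleotide strings immediately
#'   flanking the coding sequence.
#' @param frame_check_length Number of terminal coding bases checked
#'   against the design's reading frame (kept configurable; primer
#'   layouts differ in whether these bases index the sample or anchor
#'   the frame).
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(umi_length = 10, umi_side = c("5prime", "3prime"),
                        anchor5 = "GCTAGC", anchor3 = "GGATCC",
                        frame_check_length = 9) {
  umi_side <- match.arg(umi_side)
  if (umi_length < 0) abort("umi_length must be >= 0")
  if (!nzchar(anchor5) || !nzchar(anchor3)) abort("anchors must be non-empty")
  structure(
    list(umi_length = as.integer(umi_length), umi_side = umi_side,
         anchor5 = toupper(anchor5), anchor3 = toupper(anchor3),
         frame_check_length = as.integer(frame_check_length)),
    class = "read_layout"
  )
}

#' Extract UMI and coding region from merged reads
#'
#' Takes the UMI from the configured side of each read and the coding
#' sequence strictly between the two anchors. The anchor adjacent to
#' the UMI sits at a fixed offset (it immediately flanks the coding
#' sequence), so a chance anchor-like k-mer inside the random UMI
#' cannot shift the frame; the far anchor is located by its outermost
#' occurrence. Failures are data, not exceptions: each read gets a
#' rejection reason (`"no-anchor"`, `"ambiguous-base"`, `"frame"`) or
#' `NA` when extraction succeeded.
#'
#' @param reads Character vector of merged, sense-strand A/C/G/T/N reads.
#' @param layout A [read_layout()].
#' @return Tibble with columns `umi`, `cds`, `reason`.
#' @export
extract_coding_region <- function(reads, layout) {
  reads <- toupper(as.character(reads))
  n <- length(reads)
  ul <- layout$umi_length
  n5 <- nchar(layout$anchor5)
  n3 <- nchar(layout$anchor3)
  if (layout$umi_side == "5prime") {
    umi <- substr(reads, 1L, ul)
    body <- substr(reads, ul + 1L, nchar(reads))
    ok5 <- substr(body, 1L, n5) == layout$anchor5
    rest <- substr(body, n5 + 1L, nchar(body))
    i3 <- vapply(gregexpr(layout$anchor3, rest, fixed = TRUE),
                 function(m) m[length(m)], integer(1))
    cds <- substr(rest, 1L, i3 - 1L)
    found <- ok5 & i3 > 0
  } else {
    umi <- substr(reads, nchar(reads) - ul + 1L, nchar(reads))
    body <- substr(reads, 1L, nchar(reads) - ul)
    ok3 <- substr(body, nchar(body) - n3 + 1L, nchar(body)) == layout$anchor3
    rest <- substr(body, 1L, nchar(body) - n3)
    i5 <- regexpr(layout$anchor5, rest, fixed = TRUE)
    cds <- substr(rest, i5 + n5, nchar(rest))
    found <- ok3 & i5 > 0
  }

  reason <- rep(NA_character_, n)
  reason[!found] <- "no-anchor"
  amb <- is.na(reason) &
    (grepl("[^ACGT]", umi) | grepl("[^ACGT]", cds))
  reason[amb] <- "ambiguous-base"
  reason[is.na(reason) & nchar(cds) %% 3L != 0L] <- "frame"

  keep <- is.na(reason)
  tibble(umi = ifelse(keep, umi, NA_character_),
         cds = ifelse(keep, cds, NA_character_),
         reason = reason)
}

#' Translate coding sequences under the standard genetic code
#'
#' Vectorized standard-code translation. Sequences containing an
#' internal (or terminal) stop codon translate to `NA`, the `"stop-codon"`
#' rejection of the counting pipeline; a length that is not a multiple of
#' three is a frame error.
#'
#' @param cds Character vector of A/C/G/T coding sequences.
#' @return Character vector of protein sequences (`NA` where a stop
#'   codon was encountered). The empty string translates to itself.
#' @export
translate_cds <- function(cds) {
  if (any(nchar(cds) %% 3L != 0L)) {
    abort("coding sequence length must be a multiple of 3",
          class = "foldscan_frame_error")
  }
  code <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- code[codons]
    if (anyNA(aa)) abort(sprintf("unrecognized codon in '%s'", s))
    if (any(aa == "*")) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

new_count_table <- function(counts, sample_id, total_reads, rejected,
                            scaffold_name = NA_character_,
                            denominator = NA_character_) {
  tibble::new_tibble(
    counts, nrow = nrow(counts), class = "fs_count_table",
    sample_id = sample_id, total_reads = as.integer(total_reads),
    rejected = rejected, scaffold_name = scaffold_name,
    denominator = denominator
  )
}

#' Count table metadata accessors
#'
#' @param table A count table produced by [count_sequences()],
#'   [normalize_counts()] or [as_count_table()].
#' @return `total_reads()` the number of input reads; `rejected_reads()`
#'   a named integer vector of rejection counters by reason.
#' @export
total_reads <- function(table) attr(table, "total_reads")

#' @rdname total_reads
#' @export
rejected_reads <- function(table) attr(table, "rejected")

#' Count unique protein sequences by distinct UMIs
#'
#' Processes merged FASTQ reads into a UMI-deduplicated protein count
#' table: extracts UMI and coding region, translates, drops reads whose
#' translation contains a stop codon or does not match the library
#' design, and counts each unique protein sequence as the number of
#' distinct UMIs observed with it (the copy-number estimate). Rejected
#' reads are tallied by reason (`no-anchor`, `ambiguous-base`, `frame`,
#' `stop-codon`, `design-mismatch`); matched reads plus rejected reads
#' always sum to the total input reads.
#'
#' @param reads Path to a FASTQ file (Phred+33, optionally gzipped) or a
#'   character vector of read sequences.
#' @param layout A [read_layout()].
#' @param design A `library_design`; translations failing
#'   [matches_design()] are excluded.
#' @param sample_id Identifier stored in the table metadata.
#' @return A count table: tibble with columns `sequence`, `count`, plus
#'   metadata accessible via [total_reads()] and [rejected_reads()].
#' @export
count_sequences <- function(reads, layout, design, sample_id = "sample") {
  if (length(reads) == 1 && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  rejected <- c("no-anchor" = 0L, "ambiguous-base" = 0L, frame = 0L,
                "stop-codon" = 0L, "design-mismatch" = 0L)
  ntot <- length(reads)
  if (ntot == 0) {
    return(new_count_table(tibble(sequence = character(), count = integer()),
                           sample_id, 0L, rejected, design$scaffold$name))
  }
  ex <- extract_coding_region(reads, layout)
  tab <- table(ex$reason)
  rejected[names(tab)] <- rejected[names(tab)] + as.integer(tab)
  ok <- ex[is.na(ex$reason), ]

  ucds <- unique(ok$cds)
  prot <- translate_cds(ucds)
  prot_of <- setNames(prot, ucds)
  ok$protein <- unname(prot_of[ok$cds])
  nstop <- sum(is.na(ok$protein))
  rejected["stop-codon"] <- rejected["stop-codon"] + nstop
  ok <- ok[!is.na(ok$protein), ]

  uprot <- unique(ok$protein)
  okdes <- setNames(matches_design(uprot, design), uprot)
  nmis <- sum(!okdes[ok$protein])
  rejected["design-mismatch"] <- rejected["design-mismatch"] + nmis
  ok <- ok[okdes[ok$protein], ]

  counts <- ok |>
    distinct(.data$protein, .data$umi) |>
    count(.data$protein, name = "count") |>
    rename(sequence = "protein") |>
    arrange(dplyr::desc(.data$count), .data$sequence)
  new_count_table(counts, sample_id, ntot, rejected, design$scaffold$name)
}

#' Build a count table from a sequence/count data frame
#'
#' Entry point for pre-computed count tables (e.g. TSV input with
#' `sequence` and `count` columns), bypassing read processing.
#'
#' @param df Data frame with `sequence` and `count` columns.
#' @inheritParams count_sequences
#' @param total Total read volume; defaults to the summed counts.
#' @return A count table.
#' @export
as_count_table <- function(df, sample_id = "sample", total = NULL,
                           scaffold_name = NA_character_) {
  counts <- tibble(sequence = as.character(df$sequence),
                   count = as.integer(df$count))
  rejected <- c("no-anchor" = 0L, "ambiguous-base" = 0L, frame = 0L,
                "stop-codon" = 0L, "design-mismatch" = 0L)
  new_count_table(counts, sample_id, total %||% sum(counts$count),
                  rejected, scaffold_name)
}

#' Normalize counts into per-sequence frequencies
#'
#' Adds a `frequency` column: count divided by the chosen denominator.
#' `matched_umis` (default) divides by the summed UMI counts so the
#' frequencies form a proper distribution over retained sequences;
#' `total_reads` divides by the total read volume of the sample.
#'
#' @param table A count table.
#' @param denominator `"matched_umis"` or `"total_reads"`.
#' @return The count table with a `frequency` column; the denominator
#'   choice is recorded in the table metadata.
#' @export
normalize_counts <- function(table,
                             denominator = c("matched_umis", "total_reads")) {
  denominator <- match.arg(denominator)
  denom <- switch(denominator,
                  matched_umis = sum(table$count),
                  total_reads = total_reads(table))
  if (is.null(denom) || is.na(denom) || denom == 0) {
    abort("cannot normalize an empty sample (zero denominator)",
          class = "foldscan_empty_sample")
  }
  out <- table
  out$frequency <- out$count / denom
  attr(out, "denominator") <- denominator
  out
}

#' Write / read a count table as TSV with a JSON sidecar
#'
#' The TSV holds `sequence`, `count` and (when normalized) `frequency`;
#' the sidecar `<path>.json` holds sample id, total reads, rejection
#' counters and the normalization denominator, so a round trip is exact.
#'
#' @param table A count table.
#' @param path TSV output path.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` the restored count table.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  meta <- list(sample_id = attr(table, "sample_id"),
               total_reads = total_reads(table),
               rejected = as.list(rejected_reads(table)),
               scaffold_name = attr(table, "scaffold_name"),
               denominator = attr(table, "denominator"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- new_count_table(
    tibble(sequence = df$sequence, count = as.integer(df$count)),
    meta$sample_id, meta$total_reads,
    setNames(as.integer(meta$rejected), names(meta$rejected)),
    meta$scaffold_name,
    meta$denominator %||% NA_character_
  )
  if ("frequency" %in% names(df)) out$frequency <- df$frequency
  out
}
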