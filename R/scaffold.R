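#' Define a peptide scaffold
#'
#' A scaffold is the parent peptide that a combinatorial library is built
#' from: its amino-acid sequence, the 1-based positions of its cysteines
#' (which are never randomized because they form the stabilizing disulfide
#' bonds), and optional named regions such as loops chosen for
#' randomization. All positional quantities in the package (enrichment
#' scores, attribution profiles, non-touchable maps, library designs) are
#' expressed in this 1-based coordinate frame.
#'
#' @param name Identifier for the scaffold.
#' @param sequence Amino-acid string over the 20-letter alphabet
#'   (uppercase). Supported scaffolds are 20-50 residues long.
#' @param cys_positions Integer vector of 1-based cysteine positions. If
#'   `NULL` (default), positions are located from the sequence.
#' @param regions Named list of length-2 integer vectors `c(start, end)`,
#'   1-based inclusive.
#'
#' @return An object of class `scaffold_spec`.
#' @examples
#' s <- scaffold_spec("toy", "GACAKENCTQDERHGASTKN")
#' s$cys_positions
#' @export
scaffold_spec <- function(name, sequence, cys_positions = NULL,
                          regions = list()) {
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  if (!all(residues %in% AMINO_ACIDS)) {
    abort(paste0("sequence contains characters outside the 20-letter ",
                 "amino-acid alphabet: ",
                 paste(unique(setdiff(residues, AMINO_ACIDS)), collapse = ", ")))
  }
  len <- length(residues)
  if (len < 20 || len > 50) {
    abort(sprintf("scaffold length must be in [20, 50], got %d", len))
  }
  found_cys <- which(residues == "C")
  if (is.null(cys_positions)) {
    cys_positions <- found_cys
  } else {
    cys_positions <- sort(as.integer(cys_positions))
    if (!all(residues[cys_positions] == "C")) {
      abort("every cys_position must hold 'C' in the sequence")
    }
  }
  if (length(regions) > 0) {
    ok <- vapply(regions, function(r) {
      length(r) == 2 && r[1] >= 1 && r[2] <= len
    }, logical(1))
    if (!all(ok)) abort("regions must be c(start, end) pairs within [1, length]")
  }
  structure(
    list(name = name, sequence = sequence, residues = residues,
         length = len, cys_positions = cys_positions, regions = regions),
    class = "scaffold_spec"
  )
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("<scaffold_spec> %s (%d aa, %d Cys)\n",
              x$name, x$length, length(x$cys_positions)))
  cat(" ", x$sequence, "\n")
  if (length(x$regions)) {
    for (nm in names(x$regions)) {
      cat(sprintf("  region %s: %d-%d\n", nm, x$regions[[nm]][1],
                  x$regions[[nm]][2]))
    }
  }
  invisible(x)
}

#' The 5JI4 hyperstable constrained peptide scaffold
#'
#' Parent sequence of the de novo designed HCP with PDB code 5JI4: a
#' 36-residue peptide with six cysteines (three disulfide bonds). The
#' named regions are the two loop regions found amenable to randomization
#' by alanine scanning (positions 5-13 and 24-30).
#'
#' @return A [scaffold_spec()].
#' @examples
#' scaffold_5ji4()
#' @export
scaffold_5ji4 <- function() {
  scaffold_spec(
    name = "5JI4",
    sequence = "PCECDVNGETTYTVSSEECERLCRKLGVTNCRVHCG",
    regions = list(region1 = c(5L, 13L), region2 = c(24L, 30L))
  )
}

# IUPAC nucleotide degeneracy map, restricted to codes valid in codons.
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    abort(sprintf("invalid IUPAC nucleotide code '%s'", code),
          class = "foldscan_invalid_codon")
  }
  strsplit(map[[code]], "")[[1]]
}

#' Expand a degenerate codon into its amino acids
#'
#' Enumerates every concrete codon compatible with a 3-letter IUPAC
#' degenerate codon (e.g. `NNK`, `KMT`, `GMT`) under the standard genetic
#' code, and reports the encoded amino-acid set together with the number
#' of concrete codons and stop codons. Degenerate codons are how
#' combinatorial libraries confine the mutated amino acids at a position
#' to a small set (two or four residues for shotgun alanine scanning, all
#' twenty for NNK hard randomization).
#'
#' @param codon 3-character IUPAC nucleotide string.
#' @return An object of class `codon_expansion` with fields `codon`,
#'   `amino_acids` (sorted, stops excluded), `n_codons`, `n_stop_codons`.
#' @examples
#' expand_degenerate_codon("NNK")  # 20 amino acids, 32 codons, 1 stop
#' expand_degenerate_codon("GMT")  # Ala or Asp: the shotgun-scan pair
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3) {
    abort("codon must be exactly 3 IUPAC nucleotide codes",
          class = "foldscan_invalid_codon")
  }
  parts <- strsplit(codon, "")[[1]]
  bases <- lapply(parts, iupac_bases)
  grid <- expand.grid(bases[[1]], bases[[2]], bases[[3]],
                      stringsAsFactors = FALSE)
  concrete <- paste0(grid[[1]], grid[[2]], grid[[3]])
  aa <- unname(Biostrings::GENETIC_CODE[concrete])
  structure(
    list(codon = codon,
         amino_acids = sort(unique(aa[aa != "*"])),
         n_codons = length(concrete),
         n_stop_codons = sum(aa == "*"),
         stop_codons = concrete[aa == "*"]),
    class = "codon_expansion"
  )
}

#' @export
print.codon_expansion <- function(x, ...) {
  cat(sprintf("<codon_expansion> %s: %d codons, %d stop(s), {%s}\n",
              x$codon, x$n_codons, x$n_stop_codons,
              paste(x$amino_acids, collapse = "")))
  invisible(x)
}

new_library_design <- function(scaffold, allowed, codons = NULL) {
  stopifnot(length(allowed) == scaffold$length)
  for (p in scaffold$cys_positions) {
    if (!identical(allowed[[p]], "C")) {
      abort("cysteine positions must be fixed to {'C'} in a library design")
    }
  }
  if (any(lengths(allowed) == 0)) abort("every position needs a non-empty allowed set")
  structure(
    list(scaffold = scaffold, allowed = allowed, codons = codons),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  nrand <- sum(lengths(x$allowed) > 1)
  cat(sprintf("<library_design> on %s: %d randomized position(s), diversity %.3g\n",
              x$scaffold$name, nrand, theoretical_diversity(x)))
  invisible(x)
}

#' Wild-type-only design (every position fixed)
#' @param scaffold A [scaffold_spec()].
#' @return A `library_design` admitting only the parent sequence.
#' @export
wildtype_design <- function(scaffold) {
  new_library_design(scaffold, as.list(scaffold$residues))
}

#' Build a shotgun alanine-scan design over a region
#'
#' In a shotgun alanine scan each scanned position carries either the
#' wild-type residue or alanine, encoded by a degenerate codon, so a
#' single library interrogates every position in the region
#' combinatorially. Cysteines are never scanned (they form the disulfide
#' bonds) and positions that are already alanine are left fixed (an
#' Ala-to-Ala scan is vacuous). All positions outside the region stay
#' wild type.
#'
#' @param scaffold A [scaffold_spec()].
#' @param region Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive; `end < start` denotes an empty region.
#' @return A `library_design`.
#' @examples
#' d <- build_alanine_scan_design(scaffold_5ji4(), c(5, 13))
#' theoretical_diversity(d)
#' @export
build_alanine_scan_design <- function(scaffold, region) {
  region <- as.integer(region)
  empty <- region[2] < region[1]
  if (!empty && (region[1] < 1 || region[2] > scaffold$length)) {
    abort(sprintf("region %d-%d out of bounds for scaffold of length %d",
                  region[1], region[2], scaffold$length),
          class = "foldscan_range_error")
  }
  allowed <- as.list(scaffold$residues)
  if (!empty) {
    for (p in seq(region[1], region[2])) {
      wt <- scaffold$residues[p]
      if (wt != "C" && wt != "A") allowed[[p]] <- sort(c(wt, "A"))
    }
  }
  new_library_design(scaffold, allowed)
}

#' Build a randomization design from a non-touchable map
#'
#' Given a binary non-touchable map over the scaffold (1 = keep, 0 =
#' amenable), builds the "positive" library in which amenable, non-Cys
#' positions are randomized with the amino acids of a degenerate codon
#' (NNK by default) while all other positions stay wild type. The
#' inverted `negative = TRUE` variant instead randomizes the
#' non-touchable positions (excluding cysteines) and keeps amenable
#' residues unchanged; comparing display levels of the two libraries
#' tests whether the map captured the folding-critical residues.
#'
#' @param scaffold A [scaffold_spec()].
#' @param nontouchable Binary vector over all scaffold positions, or a
#'   tibble with `position` and `flag` columns as returned by
#'   [call_nontouchable()].
#' @param codon Degenerate codon used at randomized positions.
#' @param negative Build the inverted (negative-control) design.
#' @return A `library_design`.
#' @export
build_randomization_design <- function(scaffold, nontouchable,
                                       codon = "NNK", negative = FALSE) {
  if (is.data.frame(nontouchable)) {
    flags <- nontouchable$flag[order(nontouchable$position)]
  } else {
    flags <- as.integer(nontouchable)
  }
  if (length(flags) != scaffold$length) {
    abort("nontouchable map must cover every scaffold position")
  }
  aa_set <- expand_degenerate_codon(codon)$amino_acids
  target <- if (negative) flags == 1 else flags == 0
  allowed <- as.list(scaffold$residues)
  codons <- vector("list", scaffold$length)
  for (p in seq_len(scaffold$length)) {
    if (target[p] && scaffold$residues[p] != "C") {
      allowed[[p]] <- aa_set
      codons[[p]] <- codon
    }
  }
  new_library_design(scaffold, allowed, codons)
}

#' Theoretical diversity of a library design
#'
#' Product over positions of the number of allowed amino acids; e.g. a
#' design with 12 positions confined to 4 residues each has diversity
#' 4^12 ~ 10^7, the practical ceiling for yeast-display library
#' construction.
#'
#' @param design A `library_design`.
#' @return A number (double, to allow diversities beyond integer range).
#' @export
theoretical_diversity <- function(design) {
  prod(lengths(design$allowed))
}

#' Does a protein sequence match a library design?
#'
#' TRUE iff the sequence has the scaffold's length and every residue lies
#' in that position's allowed set. Sort-seq reads whose translation fails
#' this test are excluded from analysis as synthesis or sequencing
#' artifacts; mismatch is a `FALSE`, never an error.
#'
#' @param protein Character vector of amino-acid sequences.
#' @param design A `library_design`.
#' @return Logical vector.
#' @export
matches_design <- function(protein, design) {
  len <- design$scaffold$length
  vapply(protein, function(s) {
    if (is.na(s) || nchar(s) != len) return(FALSE)
    res <- strsplit(s, "")[[1]]
    for (p in seq_len(len)) {
      if (!res[p] %in% design$allowed[[p]]) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Sample sequences uniformly from a design
#'
#' Each position is drawn independently and uniformly from its allowed
#' set, i.e. uniform over the design's combinatorial space.
#'
#' @param design A `library_design`.
#' @param n Number of sequences.
#' @return Character vector of length `n`.
#' @export
sample_design <- function(design, n) {
  cols <- lapply(design$allowed, function(a) {
    if (length(a) == 1) rep(a, n) else sample(a, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

#' Write / read a library design as JSON
#'
#' The JSON form holds the scaffold (name, sequence, cys_positions,
#' regions), the per-position allowed amino-acid strings, and any
#' per-position degenerate codons. Keys are emitted in a fixed order so
#' files round-trip bit-stably.
#'
#' @param design A `library_design`.
#' @param path Output file.
#' @return `write_design_json` returns `path` invisibly;
#'   `read_design_json` returns a `library_design`.
#' @export
write_design_json <- function(design, path) {
  sc <- design$scaffold
  regions <- sc$regions
  if (length(regions)) regions <- regions[order(names(regions))]
  obj <- list(
    name = sc$name,
    sequence = sc$sequence,
    cys_positions = as.integer(sc$cys_positions),
    regions = regions,
    allowed = as.list(setNames(
      vapply(design$allowed, paste, "", collapse = ""),
      as.character(seq_along(design$allowed))
    )),
    codons = if (is.null(design$codons)) {
      setNames(list(), character())
    } else {
      keep <- !vapply(design$codons, is.null, logical(1))
      setNames(design$codons[keep], as.character(which(keep)))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(obj$regions, as.integer)
  sc <- scaffold_spec(obj$name, obj$sequence,
                      cys_positions = obj$cys_positions,
                      regions = regions)
  al <- obj$allowed
  if (!is.null(names(al))) al <- al[as.character(seq_len(sc$length))]
  allowed <- lapply(al, function(s) strsplit(s, "")[[1]])
  codons <- NULL
  if (length(obj$codons) > 0) {
    codons <- vector("list", sc$length)
    for (p in names(obj$codons)) codons[[as.integer(p)]] <- obj$codons[[p]]
  }
  new_library_design(sc, unname(allowed), codons)
}
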