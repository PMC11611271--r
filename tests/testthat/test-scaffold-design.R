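test_that("degenerate codons expand to the right amino-acid sets", {
  gct <- expand_degenerate_codon("GCT")
  expect_equal(gct$amino_acids, "A")
  expect_equal(gct$n_codons, 1L)
  expect_equal(gct$n_stop_codons, 0L)

  nnk <- expand_degenerate_codon("NNK")
  expect_length(nnk$amino_acids, 20)
  expect_equal(nnk$n_codons, 32L)
  expect_equal(nnk$n_stop_codons, 1L)
  expect_equal(nnk$stop_codons, "TAG")

  kmt <- expand_degenerate_codon("KMT")
  expect_equal(kmt$amino_acids, c("A", "D", "S", "Y"))
  expect_equal(kmt$n_codons, 4L)
  expect_equal(kmt$n_stop_codons, 0L)

  gmt <- expand_degenerate_codon("GMT")
  expect_equal(gmt$amino_acids, c("A", "D"))
  expect_equal(gmt$n_codons, 2L)

  expect_error(expand_degenerate_codon("NXK"), class = "foldscan_invalid_codon")
  expect_error(expand_degenerate_codon("NN"), class = "foldscan_invalid_codon")
})

test_that("codon expansion agrees with brute-force enumeration on all IUPAC triplets", {
  # independent oracle: nested loops over concrete bases, tallying
  # translations directly from the standard code table
  iupac <- Biostrings::IUPAC_CODE_MAP
  code <- Biostrings::GENETIC_CODE
  codes <- names(iupac)
  for (c1 in codes) {
    for (c2 in codes) {
      for (c3 in codes) {
        aa <- character()
        nstop <- 0L
        ncod <- 0L
        for (b1 in strsplit(iupac[[c1]], "")[[1]]) {
          for (b2 in strsplit(iupac[[c2]], "")[[1]]) {
            for (b3 in strsplit(iupac[[c3]], "")[[1]]) {
              ncod <- ncod + 1L
              tr <- code[[paste0(b1, b2, b3)]]
              if (tr == "*") nstop <- nstop + 1L else aa <- c(aa, tr)
            }
          }
        }
        got <- expand_degenerate_codon(paste0(c1, c2, c3))
        expect_identical(got$amino_acids, sort(unique(aa)))
        expect_identical(got$n_codons, ncod)
        expect_identical(got$n_stop_codons, nstop)
      }
    }
  }
})

test_that("alanine-scan designs randomize the region, sparing Cys and Ala", {
  sc <- toy_scaffold()  # GACAKENCTQDERHGASTKN, Cys at 3 and 8
  d <- build_alanine_scan_design(sc, c(5, 7))
  expect_equal(lengths(d$allowed)[5:7], c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(sort(d$allowed[[5]]), c("A", "K"))
  expect_true(all(lengths(d$allowed)[-(5:7)] == 1))

  # Cys inside the region stays fixed to C
  d2 <- build_alanine_scan_design(sc, c(7, 9))
  expect_identical(d2$allowed[[8]], "C")
  expect_equal(sort(d2$allowed[[9]]), c("A", "T"))

  # wild-type Ala positions are vacuous and left fixed
  d3 <- build_alanine_scan_design(sc, c(1, sc$length))
  expect_identical(d3$allowed[[2]], "A")

  # empty region equals the wild-type-only design
  d0 <- build_alanine_scan_design(sc, c(1, 0))
  expect_identical(d0$allowed, wildtype_design(sc)$allowed)

  expect_error(build_alanine_scan_design(sc, c(5, 99)),
               class = "foldscan_range_error")
})

test_that("randomization designs follow the non-touchable map", {
  sc <- toy_scaffold()
  all_nt <- rep(1L, sc$length)
  expect_identical(build_randomization_design(sc, all_nt)$allowed,
                   wildtype_design(sc)$allowed)

  map <- all_nt
  map[c(5, 6)] <- 0L
  d <- build_randomization_design(sc, map, codon = "NNK")
  expect_length(d$allowed[[5]], 20)
  expect_length(d$allowed[[6]], 20)
  expect_true(all(lengths(d$allowed)[-c(5, 6)] == 1))

  # negative design randomizes non-touchable positions, sparing Cys
  map2 <- rep(0L, sc$length)
  map2[c(3, 4, 8)] <- 1L  # 3 and 8 are Cys
  dn <- build_randomization_design(sc, map2, codon = "NNK", negative = TRUE)
  expect_identical(dn$allowed[[3]], "C")
  expect_identical(dn$allowed[[8]], "C")
  expect_length(dn$allowed[[4]], 20)
  expect_true(all(lengths(dn$allowed)[-c(3, 4, 8)] == 1))

  expect_error(build_randomization_design(sc, map, codon = "XXX"),
               class = "foldscan_invalid_codon")
  expect_error(build_randomization_design(sc, map[-1]))
})

test_that("theoretical diversity multiplies allowed-set sizes", {
  sc <- toy_scaffold()
  expect_equal(theoretical_diversity(wildtype_design(sc)), 1)

  # 12 positions x 4 amino acids: the ~1e7 design ceiling
  d <- wildtype_design(sc)
  for (p in setdiff(seq_len(12 + 2), sc$cys_positions)[1:12]) {
    d$allowed[[p]] <- c("A", "D", "S", "Y")
  }
  expect_equal(theoretical_diversity(d), 16777216)

  d2 <- wildtype_design(sc)
  for (p in setdiff(seq_len(12), sc$cys_positions)[1:10]) {
    d2$allowed[[p]] <- c(sc$residues[p], "G")
  }
  expect_equal(theoretical_diversity(d2), 1024)

  # shotgun scan over k scannable positions gives 2^k
  scan <- build_alanine_scan_design(sc, c(1, sc$length))
  k <- sum(!sc$residues %in% c("C", "A"))
  expect_equal(theoretical_diversity(scan), 2^k)
})

test_that("design membership gates length and per-position residues", {
  sc <- toy_scaffold()
  d <- build_alanine_scan_design(sc, c(5, 7))
  expect_true(matches_design(sc$sequence, d))

  mut_fixed <- sc$residues
  mut_fixed[1] <- "W"
  expect_false(matches_design(paste(mut_fixed, collapse = ""), d))
  expect_false(matches_design(substr(sc$sequence, 1, 10), d))

  # every uniform draw from the design matches it
  scan <- build_alanine_scan_design(sc, c(1, sc$length))
  draws <- withr::with_seed(1, sample_design(scan, 1000))
  expect_true(all(matches_design(draws, scan)))
})

test_that("scaffold specs validate their invariants", {
  expect_error(scaffold_spec("x", "ACDB"), "alphabet")
  expect_error(scaffold_spec("x", "ACDE"), "length")
  expect_error(scaffold_spec("x", toy_scaffold()$sequence,
                             cys_positions = c(1, 3)), "cys_position")
  sc <- scaffold_spec("x", toy_scaffold()$sequence,
                      regions = list(loop = c(5, 9)))
  expect_equal(sc$regions$loop, c(5, 9))
  expect_error(scaffold_spec("x", toy_scaffold()$sequence,
                             regions = list(bad = c(0, 5))))
})

test_that("design JSON round-trips", {
  sc <- scaffold_spec("toy", toy_scaffold()$sequence,
                      regions = list(loop1 = c(5L, 9L)))
  d <- build_alanine_scan_design(sc, c(5, 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_design_json(d, path)
  d2 <- read_design_json(path)
  expect_identical(d2$allowed, d$allowed)
  expect_identical(d2$scaffold$sequence, d$scaffold$sequence)
  expect_identical(d2$scaffold$cys_positions, d$scaffold$cys_positions)
  expect_equal(d2$scaffold$regions$loop1, c(5L, 9L))

  # bit-stable: writing the re-read design reproduces the file
  path2 <- withr::local_tempfile(fileext = ".json")
  write_design_json(d2, path2)
  expect_identical(readLines(path), readLines(path2))
})
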