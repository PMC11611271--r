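# a layout and design shared by the counting tests
ngs_fixture <- function() {
  sc <- toy_scaffold()
  design <- build_alanine_scan_design(sc, c(1, sc$length))
  layout <- read_layout(umi_length = 8)
  cds_of <- function(protein) {
    paste(foldscan:::fs_codon_map()[strsplit(protein, "")[[1]]], collapse = "")
  }
  make_read <- function(umi, protein) {
    paste0(umi, layout$anchor5, cds_of(protein), layout$anchor3)
  }
  list(sc = sc, design = design, layout = layout, make_read = make_read,
       cds_of = cds_of)
}

test_that("coding-region extraction finds UMI and cds between anchors", {
  fx <- ngs_fixture()
  read <- fx$make_read("ACGTACGT", fx$sc$sequence)
  ex <- extract_coding_region(read, fx$layout)
  expect_equal(ex$umi, "ACGTACGT")
  expect_equal(ex$cds, fx$cds_of(fx$sc$sequence))
  expect_true(is.na(ex$reason))

  # missing 5' anchor
  no_anchor <- paste0("ACGTACGT", "TTTTTT", fx$cds_of(fx$sc$sequence),
                      fx$layout$anchor3)
  expect_equal(extract_coding_region(no_anchor, fx$layout)$reason, "no-anchor")

  # ambiguous base inside the cds
  amb_cds <- fx$cds_of(fx$sc$sequence)
  substr(amb_cds, 4, 4) <- "N"
  amb <- paste0("ACGTACGT", fx$layout$anchor5, amb_cds, fx$layout$anchor3)
  expect_equal(extract_coding_region(amb, fx$layout)$reason, "ambiguous-base")

  # off-frame cds
  off <- paste0("ACGTACGT", fx$layout$anchor5, "TGTGA", fx$layout$anchor3)
  expect_equal(extract_coding_region(off, fx$layout)$reason, "frame")

  # 3' UMI layouts take the UMI from the end
  lay3 <- read_layout(umi_length = 4, umi_side = "3prime")
  r3 <- paste0(lay3$anchor5, "TGTGAATGT", lay3$anchor3, "GGCC")
  ex3 <- extract_coding_region(r3, lay3)
  expect_equal(ex3$umi, "GGCC")
  expect_equal(ex3$cds, "TGTGAATGT")
})

test_that("translation follows the standard code and rejects stops", {
  expect_equal(translate_cds("TGTGAATGT"), "CEC")
  expect_true(is.na(translate_cds("TGAGAATGT")))  # stop at codon 1
  expect_equal(translate_cds(""), "")
  expect_error(translate_cds("TGTGA"), class = "foldscan_frame_error")
})

test_that("counting deduplicates by UMI and excludes design mismatches", {
  fx <- ngs_fixture()
  x <- fx$sc$sequence                    # wild type
  y_res <- strsplit(x, "")[[1]]
  y_res[5] <- "A"                        # in-design Ala variant
  y <- paste(y_res, collapse = "")
  reads <- c(fx$make_read("AAAAAAAA", x),
             fx$make_read("AAAAAAAA", x),  # duplicate UMI
             fx$make_read("CCCCCCCC", x),
             fx$make_read("GGGGGGGG", y))
  tab <- count_sequences(reads, fx$layout, fx$design)
  expect_equal(total_reads(tab), 4L)
  expect_equal(tab$count[tab$sequence == x], 2L)
  expect_equal(tab$count[tab$sequence == y], 1L)
  expect_equal(sum(rejected_reads(tab)), 0L)

  # a translation violating the design is excluded and tallied
  z_res <- y_res
  z_res[6] <- "W"                        # W not allowed at position 6
  z <- paste(z_res, collapse = "")
  tab2 <- count_sequences(c(reads, fx$make_read("TTTTTTTT", z)),
                          fx$layout, fx$design)
  expect_equal(rejected_reads(tab2)[["design-mismatch"]], 1L)
  expect_false(z %in% tab2$sequence)

  # empty input gives an empty table
  tab0 <- count_sequences(character(), fx$layout, fx$design)
  expect_equal(nrow(tab0), 0L)
  expect_equal(total_reads(tab0), 0L)
})

test_that("matched plus rejected reads always equals total reads", {
  fx <- ngs_fixture()
  reads <- c(
    fx$make_read("AAAAAAAA", fx$sc$sequence),
    "GGGGGGGGTTTTCCCC",                                     # no anchors
    paste0("NNNNNNNN", fx$layout$anchor5,
           fx$cds_of(fx$sc$sequence), fx$layout$anchor3),   # N in UMI
    paste0("ACACACAC", fx$layout$anchor5, "TGATGA",
           fx$layout$anchor3)                               # stop codons
  )
  tab <- count_sequences(reads, fx$layout, fx$design)
  expect_equal(sum(tab$count) + sum(rejected_reads(tab)), length(reads))
  expect_equal(rejected_reads(tab)[["stop-codon"]], 1L)
})

test_that("normalization divides by the chosen denominator", {
  tab <- as_count_table(tibble::tibble(sequence = c("X", "Y"), count = c(2, 1)),
                        total = 4)
  m <- normalize_counts(tab, "matched_umis")
  expect_equal(m$frequency, c(2 / 3, 1 / 3))
  t <- normalize_counts(tab, "total_reads")
  expect_equal(t$frequency, c(0.5, 0.25))
  expect_equal(attr(t, "denominator"), "total_reads")

  one <- as_count_table(tibble::tibble(sequence = "X", count = 7))
  expect_equal(normalize_counts(one, "matched_umis")$frequency, 1)

  empty <- as_count_table(tibble::tibble(sequence = character(),
                                         count = integer()))
  expect_error(normalize_counts(empty), class = "foldscan_empty_sample")
})

test_that("count tables round-trip through TSV with their metadata", {
  fx <- ngs_fixture()
  reads <- c(fx$make_read("AAAAAAAA", fx$sc$sequence),
             fx$make_read("CCCCCCCC", fx$sc$sequence),
             "TTTTTTTTTTTTTTTT")
  tab <- normalize_counts(count_sequences(reads, fx$layout, fx$design,
                                          sample_id = "s1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(total_reads(back), total_reads(tab))
  expect_identical(rejected_reads(back), rejected_reads(tab))
  expect_identical(attr(back, "denominator"), attr(tab, "denominator"))
})
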