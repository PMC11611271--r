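# hand-made ES profile object for the threshold tests
fake_profile <- function(es, cys = integer()) {
  n <- length(es)
  structure(
    list(summary = tibble::tibble(position = seq_len(n),
                                  residue = rep("A", n), es = es),
         scaffold = list(name = "fake", length = n, cys_positions = cys)),
    class = "fs_es_profile"
  )
}

test_that("position frequencies sum sequence frequencies per residue", {
  sc <- toy_scaffold()
  design <- build_alanine_scan_design(sc, c(1, sc$length))
  wt <- sc$sequence
  v <- strsplit(wt, "")[[1]]
  v[5] <- "A"
  alt <- paste(v, collapse = "")
  tab <- normalize_counts(as_count_table(
    tibble::tibble(sequence = c(wt, alt), count = c(1, 3))
  ))
  pf <- position_frequencies(tab, design)
  expect_equal(pf$frequency[pf$position == 5 & pf$residue == "K"], 0.25)
  expect_equal(pf$frequency[pf$position == 5 & pf$residue == "A"], 0.75)
  expect_equal(pf$frequency[pf$position == 9 & pf$residue == "T"], 1)

  # frequencies at every position sum to 1
  sums <- tapply(pf$frequency, pf$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # single-sequence table puts frequency 1 everywhere
  one <- normalize_counts(as_count_table(
    tibble::tibble(sequence = wt, count = 5)
  ))
  pf1 <- position_frequencies(one, design)
  expect_true(all(pf1$frequency == 1))

  empty <- as_count_table(tibble::tibble(sequence = character(),
                                         count = integer()))
  expect_error(position_frequencies(empty, design),
               class = "foldscan_empty_sample")
})

test_that("the enrichment score follows the conditional formula", {
  expect_equal(enrichment_score(0.5, 0.5), 0)
  expect_equal(enrichment_score(1.0, 0.25), 1.0)
  expect_equal(enrichment_score(0.1, 0.4), -0.75)
  expect_equal(enrichment_score(0, 0), 0)     # 0/0 convention
  expect_equal(enrichment_score(0.3, 0), 0.3) # first branch, finite
  expect_error(enrichment_score(1.2, 0.5), class = "foldscan_domain_error")
  expect_error(enrichment_score(0.5, -0.1), class = "foldscan_domain_error")
})

test_that("enrichment score is monotone in f_exp and zero iff no change", {
  withr::with_seed(1, {
    fo <- runif(200)
    fe1 <- runif(200)
    fe2 <- pmin(fe1 + runif(200, 0, 1 - fe1), 1)
    expect_true(all(enrichment_score(fe2, fo) >= enrichment_score(fe1, fo)))
    expect_true(all(abs(enrichment_score(fe1, fo)) <= 1))
    expect_true(all(enrichment_score(fo, fo) == 0))
    nz <- fe1 != fo
    expect_true(all(enrichment_score(fe1, fo)[nz] != 0))
  })
})

test_that("es_profile applies the score element-wise with a wild-type summary", {
  sc <- toy_scaffold()
  design <- build_alanine_scan_design(sc, c(1, sc$length))
  wt <- sc$sequence
  v <- strsplit(wt, "")[[1]]
  v[c(5, 9)] <- "A"
  alt <- paste(v, collapse = "")
  pre <- normalize_counts(as_count_table(
    tibble::tibble(sequence = c(wt, alt), count = c(2, 2))
  ))
  post <- normalize_counts(as_count_table(
    tibble::tibble(sequence = c(wt, alt), count = c(3, 1))
  ))
  prof <- es_profile(position_frequencies(pre, design),
                     position_frequencies(post, design))
  # identity sort: all-zero profile
  prof0 <- es_profile(position_frequencies(pre, design),
                      position_frequencies(pre, design))
  expect_true(all(prof0$scores$es == 0))

  # hand-computed: wild type goes 0.5 -> 0.75 at scanned positions 5 and 9
  expect_equal(prof$summary$es[5], (0.75 - 0.5) / (1 - 0.5))
  expect_equal(prof$summary$es[9], 0.5)
  # never-randomized positions have no measurable ES
  expect_true(all(is.na(prof$summary$es[sc$cys_positions])))
  expect_true(all(prof$scores$es >= -1 & prof$scores$es <= 1))
})

test_that("with a two-letter alphabet wild-type and substitute ES oppose", {
  e <- tiny_experiment(seed = 21)
  prof <- measure_es(e)
  scanned <- prof$scores |>
    dplyr::group_by(position) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(s = prod(sign(es)), both0 = all(es == 0))
  expect_true(all(scanned$s <= 0 | scanned$both0))
})

test_that("max normalization rescales the summary to peak at 1", {
  p <- fake_profile(c(0.2, 0.4))
  n1 <- max_normalize_profile(p)
  expect_equal(n1$summary$es_normalized, c(0.5, 1.0))
  # idempotent on the normalized scores
  p2 <- fake_profile(n1$summary$es_normalized)
  expect_equal(max_normalize_profile(p2)$summary$es_normalized, c(0.5, 1.0))
  # scale-equivariant
  p3 <- fake_profile(c(0.02, 0.04))
  expect_equal(max_normalize_profile(p3)$summary$es_normalized, c(0.5, 1.0))
  # degenerate all-non-positive profile: unchanged with warning
  expect_warning(z <- max_normalize_profile(fake_profile(c(0, -0.5))),
                 "unnormalized")
  expect_equal(z$summary$es_normalized, c(0, -0.5))
})

test_that("critical calls threshold the wild-type ES at the cutoff", {
  p <- fake_profile(c(0.8, 0.39, 0.4))
  expect_equal(call_critical(p), c(1L, 3L))
  expect_equal(call_critical(fake_profile(c(0.1, 0.2))), integer())
  expect_equal(call_critical(fake_profile(c(0.1, 0.2)), cutoff = 0),
               c(1L, 2L))
})

test_that("non-touchable calls threshold at the scaffold average", {
  m <- call_nontouchable(c(0.8, 0.2, 0.5, 0.1))
  expect_equal(m$flag, c(1L, 0L, 1L, 0L))
  expect_equal(attr(m, "threshold_value"), 0.4)

  expect_equal(call_nontouchable(c(0.3, 0.3, 0.3))$flag, c(1L, 1L, 1L))
  expect_equal(call_nontouchable(c(1, 0))$flag, c(1L, 0L))

  # median variant
  md <- call_nontouchable(c(0, 0.1, 0.2, 0.9), threshold = "median")
  expect_equal(attr(md, "threshold_value"), 0.15)
  expect_equal(md$flag, c(0L, 0L, 1L, 1L))

  # excluded positions are flagged non-touchable but marked excluded,
  # and do not move the threshold
  e <- call_nontouchable(c(NA, 0.8, 0.2, 0.5, 0.1), exclude = 4)
  expect_true(e$excluded[1] && e$excluded[4])
  expect_equal(e$flag, c(1L, 1L, 0L, 1L, 0L))
  expect_equal(attr(e, "threshold_value"), mean(c(0.8, 0.2, 0.1)))
})
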