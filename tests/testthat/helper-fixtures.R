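# Shared fixtures, built in code: a fixed toy scaffold, a small
# simulated sort experiment, and a small trained classifier cached for
# the attribution tests.

toy_scaffold <- function() {
  # 20 aa, cysteines at 3 and 8
  scaffold_spec("toy", "GACAKENCTQDERHGASTKN")
}

tiny_experiment <- function(seed = 11, beta = 3, n_critical = 3,
                            library_size = 200, depth = 15000, ...) {
  rs <- withr::with_seed(seed, random_scaffold(paste0("T", seed),
                                               n_critical = n_critical))
  design <- build_alanine_scan_design(rs$scaffold, c(1, rs$scaffold$length))
  truth <- ground_truth(rs$scaffold, rs$critical_positions, beta = beta, ...)
  simulate_sort_experiment(design, truth, library_size = library_size,
                           depth = depth, seed = seed + 1)
}

# small architecture that trains in seconds; used where the test needs
# a real trained model but not the full desk capacity
small_config <- function(...) {
  training_config("desk", emb_dim = 16L, n_heads = 2L, ffn_dim = 32L,
                  dense_dim = 16L, batch_size = 8L, ...)
}

# 3-class toy dataset separable by residue composition
composition_toyset <- function(n_per_class = 10, len = 21, seed = 5) {
  withr::with_seed(seed, {
    mk <- function(pool) {
      vapply(seq_len(n_per_class), function(i) {
        paste(sample(pool, len, replace = TRUE), collapse = "")
      }, "")
    }
    tibble::tibble(
      sequence = c(mk(c("A", "S", "T")), mk(c("G", "N", "Q")),
                   mk(c("W", "F", "Y"))),
      label = rep(c("Low", "Mid", "High"), each = n_per_class)
    )
  })
}

# cached trained model on the composition toy set (shared by IG tests)
cached_toy_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      model <<- train_classifier(composition_toyset(),
                                 small_config(epochs = 60L, seed = 9L))
    }
    model
  }
})
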