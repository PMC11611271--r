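#' Tokenize peptide sequences
#'
#' Maps each residue to a token id over the vocabulary (20 amino acids,
#' a null/mask token used as the attribution baseline, and padding) and
#' pads every sequence to `max_length`. Tokenization is deterministic
#' and invertible via [decode_tokens()].
#'
#' @param sequences Character vector over the 20-letter amino-acid
#'   alphabet, each at most `max_length` long.
#' @param max_length Padded length (default 64).
#' @return An object of class `fs_tokenized`: list with integer matrix
#'   `ids` (sequences x positions), binary `mask`, and `lengths`.
#' @export
encode_sequences <- function(sequences, max_length = 64) {
  n <- length(sequences)
  ids <- matrix(PAD_ID, n, max_length)
  mask <- matrix(0L, n, max_length)
  lengths <- integer(n)
  vocab <- fs_vocab()
  for (i in seq_len(n)) {
    res <- strsplit(sequences[i], "")[[1]]
    if (length(res) > max_length) {
      abort(sprintf("sequence %d exceeds max_length %d", i, max_length),
            class = "foldscan_encoding_error")
    }
    tok <- match(res, vocab[1:20])
    if (anyNA(tok)) {
      abort(sprintf("illegal character in sequence '%s'", sequences[i]),
            class = "foldscan_encoding_error")
    }
    L <- length(tok)
    if (L > 0) {
      ids[i, seq_len(L)] <- tok
      mask[i, seq_len(L)] <- 1L
    }
    lengths[i] <- L
  }
  structure(list(ids = ids, mask = mask, lengths = lengths,
                 max_length = max_length),
            class = "fs_tokenized")
}

#' @rdname encode_sequences
#' @param batch An `fs_tokenized` object.
#' @export
decode_tokens <- function(batch) {
  vocab <- fs_vocab()
  vapply(seq_len(nrow(batch$ids)), function(i) {
    L <- batch$lengths[i]
    if (L == 0) return("")
    paste(vocab[batch$ids[i, seq_len(L)]], collapse = "")
  }, character(1))
}

#' Training configuration for the foldability classifier
#'
#' Two presets bundle the optimizer hyperparameters with the compact
#' encoder architecture (2 self-attention blocks, embedding width 64, 4
#' heads, GELU MLPs). `"published"` is the published fine-tuning recipe for
#' a pretrained backbone: AdamW with learning rate 1e-5, weight decay
#' 0.01, dropout 0.1, 10 epochs. `"desk"` keeps weight decay and
#' dropout but uses learning rate 1e-3 over 30 epochs, the step size a
#' small encoder trained from scratch needs. Any field can be
#' overridden.
#'
#' @param preset `"desk"` (default) or `"published"`.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `fs_training_config`.
#' @export
training_config <- function(preset = c("desk", "published"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    learning_rate = if (preset == "published") 1e-5 else 1e-3,
    weight_decay = 0.01,
    dropout = 0.1,
    epochs = if (preset == "published") 10L else 30L,
    emb_dim = 64L, n_blocks = 2L, n_heads = 4L,
    ffn_dim = 128L, dense_dim = 64L,
    max_length = 64L, batch_size = 32L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown config field(s):",
                               paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  if (cfg$emb_dim %% cfg$n_heads != 0) {
    abort("emb_dim must be divisible by n_heads")
  }
  stopifnot(cfg$learning_rate > 0, cfg$epochs > 0, cfg$dropout >= 0,
            cfg$weight_decay >= 0)
  structure(cfg, class = "fs_training_config")
}

#' Train the three-class foldability classifier
#'
#' Minimizes the cross-entropy of the (Low, Mid, High) labels with
#' AdamW over shuffled minibatches, all layers trainable. All
#' randomness (initialization, shuffling, dropout) flows through
#' `config$seed`, so equal seeds give identical models. The class order
#' is fixed as Low, Mid, High so that attribution can target the High
#' class unambiguously.
#'
#' @param data Tibble with `sequence` and `label` columns (labels in
#'   Low/Mid/High); the output of [assign_labels()]/[balance_mid()].
#' @param config A [training_config()].
#' @return An object of class `foldability_classifier` with the learned
#'   parameters, the resolved config, and the per-epoch training loss.
#' @export
train_classifier <- function(data, config = training_config()) {
  if (nrow(data) == 0) abort("empty training set")
  labels <- factor(as.character(data$label), levels = c("Low", "Mid", "High"))
  if (anyNA(labels)) abort("labels must be Low, Mid or High")
  if (length(unique(labels)) < 2) {
    abort("training set must contain at least 2 classes",
          class = "foldscan_degenerate_labels")
  }
  batch <- encode_sequences(data$sequence, config$max_length)
  y <- as.integer(labels)
  n <- nrow(data)

  withr_seed(config$seed, {
    params <- fs_init_params(config)
    adam <- fs_init_adam(params)
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        take <- ord[s:min(s + config$batch_size - 1L, n)]
        acc <- fs_zero_grads(params)
        for (i in take) {
          ids <- batch$ids[i, seq_len(batch$lengths[i])]
          Temb <- params$emb[ids, , drop = FALSE]
          fw <- fs_forward(params, Temb, config, dropout = config$dropout,
                           keep_cache = TRUE)
          p <- exp(fw$logits - max(fw$logits))
          p <- p / sum(p)
          total_loss <- total_loss - log(max(p[y[i]], 1e-12))
          dlogits <- p
          dlogits[y[i]] <- dlogits[y[i]] - 1
          dTemb <- fs_backward(params, fw$cache, dlogits, config, acc)
          rs <- rowsum(dTemb, ids)
          u <- as.integer(rownames(rs))
          acc$emb[u, ] <- acc$emb[u, , drop = FALSE] + rs
        }
        for (nm in names(params)) acc[[nm]] <- acc[[nm]] / length(take)
        params <- fs_adamw_step(params, acc, adam, config)
      }
      loss_history[epoch] <- total_loss / n
    }
    structure(
      list(params = params, config = config,
           classes = c("Low", "Mid", "High"),
           loss_history = loss_history, n_train = n),
      class = "foldability_classifier"
    )
  })
}

#' @export
print.foldability_classifier <- function(x, ...) {
  cat(sprintf(
    "<foldability_classifier> %d blocks x %d heads, width %d; trained %d epochs on %d sequences (final loss %.4f)\n",
    x$config$n_blocks, x$config$n_heads, x$config$emb_dim,
    x$config$epochs, x$n_train, tail(x$loss_history, 1)))
  invisible(x)
}

#' @method tidy foldability_classifier
#' @export
tidy.foldability_classifier <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @method glance foldability_classifier
#' @export
glance.foldability_classifier <- function(x, ...) {
  tibble(preset = x$config$preset,
         n_parameters = sum(vapply(x$params, length, integer(1))),
         epochs = x$config$epochs,
         n_train = x$n_train,
         final_loss = tail(x$loss_history, 1))
}

#' Predict foldability class probabilities
#'
#' Runs the trained classifier over sequences and returns the softmax
#' probability of each foldability class; rows sum to 1 and the argmax
#' is the predicted class. Outputs are deterministic and independent of
#' batch order.
#'
#' @param model A `foldability_classifier`.
#' @param sequences Character vector of peptide sequences.
#' @return Tibble with columns `sequence`, `p_Low`, `p_Mid`, `p_High`,
#'   `.pred_class`.
#' @export
predict_proba <- function(model, sequences) {
  cfg <- model$config
  batch <- encode_sequences(sequences, cfg$max_length)
  probs <- matrix(NA_real_, length(sequences), 3L,
                  dimnames = list(NULL, model$classes))
  for (i in seq_along(sequences)) {
    ids <- batch$ids[i, seq_len(batch$lengths[i])]
    Temb <- model$params$emb[ids, , drop = FALSE]
    logits <- fs_forward(model$params, Temb, cfg)$logits
    p <- exp(logits - max(logits))
    probs[i, ] <- p / sum(p)
  }
  tibble(sequence = sequences,
         p_Low = probs[, 1], p_Mid = probs[, 2], p_High = probs[, 3],
         .pred_class = factor(model$classes[max.col(probs, ties.method = "first")],
                              levels = model$classes))
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a single RDS archive holding the configuration and
#' weights.
#'
#' @param model A `foldability_classifier`.
#' @param path Checkpoint file.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   the restored model.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "foldability_classifier")) {
    abort("file does not contain a foldability_classifier")
  }
  model
}
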