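# Compact self-attention encoder for peptide sequences.
#
# The classifier backbone is a small transformer encoder trained from
# scratch: residue + position embeddings, `n_blocks` residual blocks
# (multi-head self-attention with a fused QKV projection, then a GELU
# MLP; no normalization layers at this depth), mean pooling, a dense
# GELU layer and a projection to 3 class logits. Forward and backward
# passes are explicit so that Integrated Gradients can differentiate
# the class probability with respect to the input token embeddings.
# Everything is written against BLAS-backed primitives (crossprod /
# tcrossprod) because training loops over sequences in R.

# Token vocabulary: 20 amino acids, then the null/mask token used as the
# attribution baseline, then padding.
fs_vocab <- function() c(AMINO_ACIDS, ".", "-")
NULL_ID <- 21L
PAD_ID <- 22L

sigmoid <- function(x) 1 / (1 + exp(-x))

# GELU via the sigmoid approximation x * sigmoid(1.702 x); cheaper than
# the exact Gaussian form and standard in transformer implementations.
gelu <- function(x) x * sigmoid(1.702 * x)
dgelu <- function(x) {
  s <- sigmoid(1.702 * x)
  s * (1 + 1.702 * x * (1 - s))
}

# Row-wise softmax with a global shift: attention scores here are far
# from the +-700 overflow range, so the cheaper global max is exact.
softmax_rows <- function(S) {
  E <- exp(S - max(S))
  E / rowSums(E)
}

# add a row vector to every row (column-major recycling)
addrow <- function(M, v) M + rep(v, each = nrow(M))

fs_block_names <- local({
  cache <- list()
  function(nb) {
    key <- as.character(nb)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- lapply(seq_len(nb), function(b) {
        nms <- c("Wqkv", "Wo", "W1", "b1", "W2", "b2")
        setNames(as.list(paste0("blk", b, "_", nms)), nms)
      })
    }
    cache[[key]]
  }
})

fs_init_params <- function(cfg) {
  E <- cfg$emb_dim
  rn <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  p <- list(
    emb = rn(length(fs_vocab()), E),
    pos = rn(cfg$max_length, E),
    Wd = rn(E, cfg$dense_dim), bd = numeric(cfg$dense_dim),
    Wp = rn(cfg$dense_dim, 3L), bp = numeric(3L)
  )
  bn <- fs_block_names(cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    p[[bn[[b]]$Wqkv]] <- rn(E, 3L * E)
    p[[bn[[b]]$Wo]] <- rn(E, E)
    p[[bn[[b]]$W1]] <- rn(E, cfg$ffn_dim)
    p[[bn[[b]]$b1]] <- numeric(cfg$ffn_dim)
    p[[bn[[b]]$W2]] <- rn(cfg$ffn_dim, E)
    p[[bn[[b]]$b2]] <- numeric(E)
  }
  p
}

# Forward pass over one sequence. `Temb` is the L x E matrix of token
# embeddings (the attribution input); position embeddings are added
# internally. Returns logits and, when `keep_cache`, every intermediate
# needed by fs_backward. Dropout masks are drawn when dropout > 0.
fs_forward <- function(params, Temb, cfg, dropout = 0, keep_cache = FALSE) {
  L <- nrow(Temb)
  E <- cfg$emb_dim
  H <- cfg$n_heads
  dk <- E / H
  scale <- 1 / sqrt(dk)
  bn <- fs_block_names(cfg$n_blocks)
  X <- Temb + params$pos[seq_len(L), , drop = FALSE]
  cache <- if (keep_cache) list(blocks = vector("list", cfg$n_blocks))

  for (b in seq_len(cfg$n_blocks)) {
    nm <- bn[[b]]
    QKV <- X %*% params[[nm$Wqkv]]
    Hcat <- matrix(0, L, E)
    A_list <- if (keep_cache) vector("list", H)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      A <- softmax_rows(tcrossprod(QKV[, idx, drop = FALSE],
                                   QKV[, E + idx, drop = FALSE]) * scale)
      Hcat[, idx] <- A %*% QKV[, 2L * E + idx, drop = FALSE]
      if (keep_cache) A_list[[h]] <- A
    }
    X1 <- X + Hcat %*% params[[nm$Wo]]
    Z <- addrow(X1 %*% params[[nm$W1]], params[[nm$b1]])
    G <- gelu(Z)
    mask_f <- NULL
    if (dropout > 0) {
      mask_f <- matrix((runif(length(G)) >= dropout) / (1 - dropout),
                       nrow(G), ncol(G))
      G <- G * mask_f
    }
    X2 <- X1 + addrow(G %*% params[[nm$W2]], params[[nm$b2]])
    if (keep_cache) {
      cache$blocks[[b]] <- list(X_in = X, QKV = QKV, A = A_list,
                                Hcat = Hcat, X1 = X1, Z = Z, G = G,
                                mask_f = mask_f)
    }
    X <- X2
  }

  hvec <- colMeans(X)
  Zd <- drop(hvec %*% params$Wd) + params$bd
  dvec <- gelu(Zd)
  mask_d <- NULL
  if (dropout > 0) {
    mask_d <- (runif(length(dvec)) >= dropout) / (1 - dropout)
    dvec <- dvec * mask_d
  }
  logits <- drop(dvec %*% params$Wp) + params$bp
  if (keep_cache) {
    cache$L <- L
    cache$hvec <- hvec
    cache$Zd <- Zd
    cache$dvec <- dvec
    cache$mask_d <- mask_d
  }
  list(logits = logits, cache = cache)
}

# Backward pass matching fs_forward. `dlogits` is the gradient of the
# scalar objective with respect to the logits. Adds parameter gradients
# into the environment `acc` (same names as params) and returns the
# gradient with respect to the token-embedding input.
fs_backward <- function(params, cache, dlogits, cfg, acc) {
  L <- cache$L
  E <- cfg$emb_dim
  H <- cfg$n_heads
  dk <- E / H
  scale <- 1 / sqrt(dk)
  bn <- fs_block_names(cfg$n_blocks)

  acc$Wp <- acc$Wp + outer(cache$dvec, dlogits)
  acc$bp <- acc$bp + dlogits
  d_dvec <- drop(params$Wp %*% dlogits)
  if (!is.null(cache$mask_d)) d_dvec <- d_dvec * cache$mask_d
  dZd <- d_dvec * dgelu(cache$Zd)
  acc$Wd <- acc$Wd + outer(cache$hvec, dZd)
  acc$bd <- acc$bd + dZd
  dX <- outer(rep.int(1 / L, L), drop(params$Wd %*% dZd))

  for (b in rev(seq_len(cfg$n_blocks))) {
    nm <- bn[[b]]
    cb <- cache$blocks[[b]]

    dX2 <- dX
    dG <- tcrossprod(dX2, params[[nm$W2]])
    acc[[nm$W2]] <- acc[[nm$W2]] + crossprod(cb$G, dX2)
    acc[[nm$b2]] <- acc[[nm$b2]] + colSums(dX2)
    if (!is.null(cb$mask_f)) dG <- dG * cb$mask_f
    dZ <- dG * dgelu(cb$Z)
    acc[[nm$W1]] <- acc[[nm$W1]] + crossprod(cb$X1, dZ)
    acc[[nm$b1]] <- acc[[nm$b1]] + colSums(dZ)
    dX1 <- dX2 + tcrossprod(dZ, params[[nm$W1]])

    dHcat <- tcrossprod(dX1, params[[nm$Wo]])
    acc[[nm$Wo]] <- acc[[nm$Wo]] + crossprod(cb$Hcat, dX1)
    dQKV <- matrix(0, L, 3L * E)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cb$A[[h]]
      dO <- dHcat[, idx, drop = FALSE]
      dA <- tcrossprod(dO, cb$QKV[, 2L * E + idx, drop = FALSE])
      dQKV[, 2L * E + idx] <- crossprod(A, dO)
      dS <- A * (dA - rowSums(dA * A)) * scale
      dQKV[, idx] <- dS %*% cb$QKV[, E + idx, drop = FALSE]
      dQKV[, E + idx] <- crossprod(dS, cb$QKV[, idx, drop = FALSE])
    }
    acc[[nm$Wqkv]] <- acc[[nm$Wqkv]] + crossprod(cb$X_in, dQKV)
    dX <- dX1 + tcrossprod(dQKV, params[[nm$Wqkv]])
  }
  acc$pos[seq_len(L), ] <- acc$pos[seq_len(L), , drop = FALSE] + dX
  dX
}

fs_zero_grads <- function(params) {
  acc <- new.env(parent = emptyenv())
  for (nm in names(params)) acc[[nm]] <- params[[nm]] * 0
  acc
}

fs_init_adam <- function(params) {
  st <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    st[[paste0("m_", nm)]] <- params[[nm]] * 0
    st[[paste0("v_", nm)]] <- params[[nm]] * 0
  }
  st$t <- 0L
  st
}

# Decoupled weight decay (AdamW): the decay term is applied directly to
# the weights, outside the adaptive update; bias vectors are not decayed.
fs_adamw_step <- function(params, acc, st, cfg) {
  st$t <- st$t + 1L
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- acc[[nm]]
    m <- b1 * st[[paste0("m_", nm)]] + (1 - b1) * g
    v <- b2 * st[[paste0("v_", nm)]] + (1 - b2) * g * g
    st[[paste0("m_", nm)]] <- m
    st[[paste0("v_", nm)]] <- v
    upd <- (m / c1) / (sqrt(v / c2) + eps)
    if (!is.null(dim(params[[nm]])) && cfg$weight_decay > 0) {
      upd <- upd + cfg$weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - cfg$learning_rate * upd
  }
  params
}
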