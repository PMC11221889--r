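# Independent loop-based oracles.  These deliberately avoid the
# package's vectorized code paths: softmax, attention and the min-max
# transform are computed with explicit element loops.

oracle_softmax_row <- function(s) {
  e <- numeric(length(s))
  m <- s[1]
  for (j in seq_along(s)) if (s[j] > m) m <- s[j]
  for (j in seq_along(s)) e[j] <- exp(s[j] - m)
  e / sum(e)
}

# multi-head scaled dot-product attention with explicit loops.
# residual=TRUE reproduces the self-attention update; FALSE the mutual
# one.  Returns the output matrix and the head-averaged attention map.
oracle_attention <- function(Hq, Hk, Wq, Wk, Wv, Wo, n_heads,
                             residual = FALSE) {
  d <- ncol(Hq)
  dk <- d / n_heads
  Q <- Hq %*% Wq; K <- Hk %*% Wk; V <- Hk %*% Wv
  O <- matrix(0, nrow(Hq), d)
  map <- matrix(0, nrow(Hq), nrow(Hk))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dk + seq_len(dk)
    A <- matrix(0, nrow(Hq), nrow(Hk))
    for (i in seq_len(nrow(Hq))) {
      s <- numeric(nrow(Hk))
      for (j in seq_len(nrow(Hk))) {
        acc <- 0
        for (c in idx) acc <- acc + Q[i, c] * K[j, c]
        s[j] <- acc / sqrt(dk)
      }
      A[i, ] <- oracle_softmax_row(s)
    }
    for (i in seq_len(nrow(Hq)))
      for (c in idx)
        O[i, c] <- sum(A[i, ] * V[, c])
    map <- map + A
  }
  out <- O %*% Wo
  if (residual) out <- out + Hq
  list(out = out, map = map / n_heads)
}

# Eq-by-eq min-max / difference / renormalize transform with loops
oracle_delta <- function(W_wt, W_mt) {
  norm_loop <- function(W) {
    mn <- W[1, 1]; mx <- W[1, 1]
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
      if (W[i, j] < mn) mn <- W[i, j]
      if (W[i, j] > mx) mx <- W[i, j]
    }
    out <- W
    for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
      out[i, j] <- if (mx == mn) 0 else (W[i, j] - mn) / (mx - mn)
    out
  }
  norm_loop(norm_loop(W_mt) - norm_loop(W_wt))
}

# a tiny model whose d = 3 * hidden_size; weights overwritten with small
# random values for oracle comparisons
tiny_attention_model <- function(hidden_size = 2L, n_heads = 1L,
                                 seed = 1L) {
  m <- init_model(model_config(hidden_size = hidden_size,
                               n_heads = n_heads,
                               fc_sizes = c(4L, 3L, 2L),
                               dropout_rate = 0, seed = seed))
  d <- 3L * hidden_size
  withr::with_seed(seed + 100L, {
    for (nm in c("sa_Wq", "sa_Wk", "sa_Wv", "sa_Wo",
                 "ma_Wq", "ma_Wk", "ma_Wv", "ma_Wo"))
      m$par[[nm]] <- matrix(rnorm(d * d, sd = 0.3), d, d)
  })
  m
}
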