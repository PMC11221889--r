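# The three-block network: gated convolutional embedding,
# self-/mutual-attention, and the wild/mutant prediction head.
#
# No deep-learning framework is used: forward passes cache their
# intermediates and hand-written backward passes (backprop.R) consume
# them.  All heavy steps are BLAS matrix products.  Sequences are
# processed at their true length; the exported wrappers accept padded
# inputs with an `n_valid` marker and trim before computing, which makes
# padding invariance exact by construction.

LN_EPS <- 1e-5

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model hyperparameter configuration
#'
#' @param hidden_size Channels per convolution branch; the per-residue
#'   representation width is `3 * hidden_size`.
#' @param kernel_sizes Three odd window widths for the convolution
#'   branches.
#' @param n_heads Attention heads; must divide `3 * hidden_size`.
#' @param dropout_rate Dropout probability on the self-attention output
#'   (training only).
#' @param use_attention `FALSE` gives the ablation variant: the attention
#'   block is skipped and pooled embeddings feed the head directly, with
#'   unchanged head input width.
#' @param fc_sizes Widths of the three fully connected hidden layers of
#'   the prediction head; a final affine map yields the scalar ddG.
#' @param mutual_residual Add a residual connection in mutual attention
#'   (off by default: the mutual-attention update carries no residual and
#'   no dropout).
#' @param pooling How per-residue representations become one vector per
#'   protein: mask-aware `"mean"` (default) or `"max"`.
#' @param seed Seed for parameter initialization.
#' @return A `ddg_model_config` list.
#' @export
model_config <- function(hidden_size = 64L, kernel_sizes = c(3L, 5L, 7L),
                         n_heads = 4L, dropout_rate = 0.1,
                         use_attention = TRUE, fc_sizes = c(64L, 32L, 16L),
                         mutual_residual = FALSE,
                         pooling = c("mean", "max"), seed = 1L) {
  stopifnot(hidden_size >= 1, length(kernel_sizes) == 3L,
            all(kernel_sizes %% 2 == 1), all(kernel_sizes >= 1),
            n_heads >= 1, (3L * hidden_size) %% n_heads == 0L,
            dropout_rate >= 0, dropout_rate < 1,
            length(fc_sizes) == 3L, all(fc_sizes >= 1))
  structure(list(hidden_size = as.integer(hidden_size),
                 kernel_sizes = as.integer(kernel_sizes),
                 n_heads = as.integer(n_heads),
                 dropout_rate = dropout_rate,
                 use_attention = isTRUE(use_attention),
                 fc_sizes = as.integer(fc_sizes),
                 mutual_residual = isTRUE(mutual_residual),
                 pooling = match.arg(pooling),
                 seed = as.integer(seed)),
            class = "ddg_model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' All weight matrices are Glorot-uniform from `config$seed`; biases are
#' zero, layer-norm gain/offset are 1/0.  The same embedding, attention
#' and head parameters are shared across the four input sequences
#' (wild/mutant x antibody/antigen).
#'
#' @param config A [model_config()].
#' @return A `ddg_model` with elements `config` and `par`.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "ddg_model_config"))
  h <- config$hidden_size
  d <- 3L * h
  f <- config$fc_sizes
  withr::with_seed(config$seed, {
    par <- list()
    for (b in 1:3) {
      k <- config$kernel_sizes[b]
      par[[paste0("conv", b, "_W")]] <- glorot(k * 40L, 2L * h)
      par[[paste0("conv", b, "_b")]] <- numeric(2L * h)
    }
    par$ln_g <- rep(1, d)
    par$ln_b <- numeric(d)
    for (pre in c("sa", "ma")) {
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        par[[paste0(pre, "_", w)]] <- glorot(d, d)
    }
    par$fc1_W <- glorot(4L * d, f[1]); par$fc1_b <- numeric(f[1])
    par$fc2_W <- glorot(f[1], f[2]);   par$fc2_b <- numeric(f[2])
    par$fc3_W <- glorot(f[2], f[3]);   par$fc3_b <- numeric(f[3])
    par$out_W <- glorot(f[3], 1L);     par$out_b <- 0
  })
  structure(list(config = config, par = par), class = "ddg_model")
}

#' @export
print.ddg_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, numeric(1)))
  cat(sprintf(
    "<ddg_model: hidden %d (d=%d), heads %d, kernels %s, attention %s, %d parameters>\n",
    x$config$hidden_size, 3L * x$config$hidden_size, x$config$n_heads,
    paste(x$config$kernel_sizes, collapse = "/"),
    ifelse(x$config$use_attention, "on", "off (ablation)"), np))
  invisible(x)
}

# ---- embedding block ------------------------------------------------------

# unfold a (n, c) matrix into (n, k*c) windows with zero 'same' padding
unfold_seq <- function(X, k) {
  n <- nrow(X); nc <- ncol(X)
  pad <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, nc), X, matrix(0, pad, nc))
  do.call(cbind, lapply(0:(k - 1L), function(o) Xp[o + seq_len(n), , drop = FALSE]))
}

fold_back <- function(dXu, k, n, nc) {
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, n + 2L * pad, nc)
  for (o in 0:(k - 1L))
    dXp[o + seq_len(n), ] <- dXp[o + seq_len(n), ] +
      dXu[, o * nc + seq_len(nc), drop = FALSE]
  dXp[pad + seq_len(n), , drop = FALSE]
}

# row indices of branch b's weight matrix inside the combined
# max-kernel weight layout (branch windows are centered in the widest
# window; all kernels odd)
branch_row_idx <- function(k, kmax) {
  shift <- (kmax - k) %/% 2L
  rep((shift + 0:(k - 1L)) * 40L, each = 40L) + rep(1:40, k)
}

# the three branch convolutions as one (kmax*40) x (6h) matrix so a
# single unfold + matmul serves all branches
combined_conv_W <- function(par, cfg) {
  h <- cfg$hidden_size
  kmax <- max(cfg$kernel_sizes)
  Wc <- matrix(0, kmax * 40L, 6L * h)
  for (b in 1:3)
    Wc[branch_row_idx(cfg$kernel_sizes[b], kmax),
       (b - 1L) * 2L * h + seq_len(2L * h)] <- par[[paste0("conv", b, "_W")]]
  Wc
}

# one protein through the three gated-convolution branches + layer norm
embed_fwd <- function(X, par, cfg) {
  n <- nrow(X); h <- cfg$hidden_size
  kmax <- max(cfg$kernel_sizes)
  Xu <- unfold_seq(X, kmax)
  Wc <- combined_conv_W(par, cfg)
  Z <- Xu %*% Wc + rep(c(par$conv1_b, par$conv2_b, par$conv3_b), each = n)
  outs <- vector("list", 3L); caches <- vector("list", 3L)
  for (b in 1:3) {
    Zb <- Z[, (b - 1L) * 2L * h + seq_len(2L * h), drop = FALSE]
    a <- Zb[, seq_len(h), drop = FALSE]
    s <- sigmoid(Zb[, h + seq_len(h), drop = FALSE])
    outs[[b]] <- a * s
    caches[[b]] <- list(a = a, s = s)
  }
  E0 <- do.call(cbind, outs)
  mu <- rowMeans(E0)
  xc <- E0 - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  E <- xhat * rep(par$ln_g, each = n) + rep(par$ln_b, each = n)
  list(out = E, cache = list(branches = caches, Xu = Xu, Wc = Wc,
                             xhat = xhat, inv = inv, n = n))
}

# ---- attention ------------------------------------------------------------

softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  P <- exp(S - rmax)
  P / rowSums(P)
}

# scaled dot-product attention, multi-head over column sub-spaces.
# prefix selects the parameter set ("sa" self, "ma" mutual); queries come
# from Hq, keys/values from Hk.
attn_fwd <- function(Hq, Hk, par, prefix, cfg, residual, dropout, training) {
  d <- ncol(Hq); nh <- cfg$n_heads; dk <- d %/% nh
  Wq <- par[[paste0(prefix, "_Wq")]]
  Wk <- par[[paste0(prefix, "_Wk")]]
  Wv <- par[[paste0(prefix, "_Wv")]]
  Wo <- par[[paste0(prefix, "_Wo")]]
  is_self <- identical(Hq, Hk)
  if (is_self) {
    QKV <- Hq %*% cbind(Wq, Wk, Wv)
    Q <- QKV[, seq_len(d), drop = FALSE]
    K <- QKV[, d + seq_len(d), drop = FALSE]
    V <- QKV[, 2L * d + seq_len(d), drop = FALSE]
  } else {
    Q <- Hq %*% Wq
    KV <- Hk %*% cbind(Wk, Wv)
    K <- KV[, seq_len(d), drop = FALSE]
    V <- KV[, d + seq_len(d), drop = FALSE]
  }
  O <- matrix(0, nrow(Hq), d)
  heads <- vector("list", nh)
  for (hh in seq_len(nh)) {
    idx <- (hh - 1L) * dk + seq_len(dk)
    A <- softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                 K[, idx, drop = FALSE]) / sqrt(dk))
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[hh]] <- A
  }
  mix <- O %*% Wo
  mask <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    mask <- matrix(stats::rbinom(length(mix), 1L, keep) / keep,
                   nrow(mix), ncol(mix))
    mix <- mix * mask
  }
  out <- if (residual) mix + Hq else mix
  list(out = out,
       map = Reduce(`+`, heads) / nh,
       cache = list(Hq = Hq, Hk = Hk, Q = Q, K = K, V = V, O = O,
                    heads = heads, mask = mask, residual = residual,
                    is_self = is_self))
}

# ---- pooling and head -----------------------------------------------------

pool_fwd <- function(M, cfg) {
  if (cfg$pooling == "mean") {
    list(out = colMeans(M), cache = list(n = nrow(M)))
  } else {
    am <- max.col(t(M), ties.method = "first")
    list(out = M[cbind(am, seq_len(ncol(M)))], cache = list(argmax = am,
                                                            n = nrow(M)))
  }
}

head_fwd <- function(x, par) {
  z1 <- x %*% par$fc1_W + rep(par$fc1_b, each = nrow(x)); r1 <- pmax(z1, 0)
  z2 <- r1 %*% par$fc2_W + rep(par$fc2_b, each = nrow(x)); r2 <- pmax(z2, 0)
  z3 <- r2 %*% par$fc3_W + rep(par$fc3_b, each = nrow(x)); r3 <- pmax(z3, 0)
  y <- r3 %*% par$out_W + par$out_b
  list(out = drop(y), cache = list(x = x, z1 = z1, r1 = r1, z2 = z2, r2 = r2,
                                   z3 = z3, r3 = r3))
}

# ---- full record forward --------------------------------------------------

ROLE_ORDER <- c("ab_wt", "ag_wt", "ab_mt", "ag_mt")

forward_record <- function(par, cfg, feats, training = FALSE) {
  stopifnot(all(ROLE_ORDER %in% names(feats)))
  for (r in ROLE_ORDER) {
    if (!is.matrix(feats[[r]]) || ncol(feats[[r]]) != 40L)
      stop("feature matrix '", r, "' must have 40 columns", call. = FALSE)
    if (nrow(feats[[r]]) < 1L)
      stop("empty feature matrix '", r, "'", call. = FALSE)
  }
  emb <- lapply(feats[ROLE_ORDER], embed_fwd, par = par, cfg = cfg)
  maps <- list(wt = NULL, mt = NULL)
  if (cfg$use_attention) {
    sa <- lapply(emb, function(e)
      attn_fwd(e$out, e$out, par, "sa", cfg, residual = TRUE,
               dropout = cfg$dropout_rate, training = training))
    ma <- list(
      ab_wt = attn_fwd(sa$ab_wt$out, sa$ag_wt$out, par, "ma", cfg,
                       residual = cfg$mutual_residual, dropout = 0,
                       training = training),
      ag_wt = attn_fwd(sa$ag_wt$out, sa$ab_wt$out, par, "ma", cfg,
                       residual = cfg$mutual_residual, dropout = 0,
                       training = training),
      ab_mt = attn_fwd(sa$ab_mt$out, sa$ag_mt$out, par, "ma", cfg,
                       residual = cfg$mutual_residual, dropout = 0,
                       training = training),
      ag_mt = attn_fwd(sa$ag_mt$out, sa$ab_mt$out, par, "ma", cfg,
                       residual = cfg$mutual_residual, dropout = 0,
                       training = training))
    maps$wt <- ma$ag_wt$map  # (len_ag, len_ab) antigen x antibody
    maps$mt <- ma$ag_mt$map
    reps <- lapply(ma, `[[`, "out")
  } else {
    sa <- NULL; ma <- NULL
    reps <- lapply(emb, `[[`, "out")
  }
  pools <- lapply(reps, pool_fwd, cfg = cfg)
  x <- matrix(unlist(lapply(pools[ROLE_ORDER], `[[`, "out")), nrow = 1L)
  hd <- head_fwd(x, par)
  if (!is.finite(hd$out))
    stop("non-finite model output", call. = FALSE)
  list(yhat = hd$out, maps = maps,
       cache = list(emb = emb, sa = sa, ma = ma, pools = pools, head = hd))
}

# ---- exported wrappers ----------------------------------------------------

trim_pad <- function(X, n_valid) {
  if (is.null(n_valid) || n_valid == nrow(X)) return(X)
  stopifnot(n_valid >= 1L, n_valid <= nrow(X))
  X[seq_len(n_valid), , drop = FALSE]
}

repad <- function(M, n_total) {
  if (nrow(M) == n_total) return(M)
  rbind(M, matrix(0, n_total - nrow(M), ncol(M)))
}

#' Gated-convolution embedding of one feature matrix
#'
#' Three 1-D convolution branches (one per kernel size), each gated by a
#' logistic sigmoid over half of its channels, concatenated to
#' `3 * hidden_size` channels and layer-normalized.  Positions beyond
#' `n_valid` are treated as padding and returned as zero rows.
#'
#' @param model A `ddg_model`.
#' @param X `(n, 40)` feature matrix from [featurize()].
#' @param n_valid Number of real (non-padded) leading rows; default all.
#' @return `(n, 3 * hidden_size)` representation matrix.
#' @export
embed_features <- function(model, X, n_valid = NULL) {
  if (!is.matrix(X) || ncol(X) != 40L)
    stop("feature matrix must have 40 columns", call. = FALSE)
  Xv <- trim_pad(X, n_valid)
  repad(embed_fwd(Xv, model$par, model$config)$out, nrow(X))
}

#' Multi-head self-attention over one protein
#'
#' Per head, `A = softmax(Q K' / sqrt(d_k))` over unmasked key positions;
#' the head outputs are concatenated, linearly mixed, passed through
#' dropout (training only) and added to the input (residual).
#'
#' @inheritParams embed_features
#' @param H `(n, d)` representation with `d = 3 * hidden_size`.
#' @param training Enable dropout.
#' @param return_attn Also return the per-head attention matrices.
#' @return The `(n, d)` output matrix, or a list `(output, attn)` when
#'   `return_attn = TRUE`.
#' @export
self_attention <- function(model, H, n_valid = NULL, training = FALSE,
                           return_attn = FALSE) {
  Hv <- trim_pad(H, n_valid)
  if (!all(is.finite(Hv))) stop("non-finite input", call. = FALSE)
  r <- attn_fwd(Hv, Hv, model$par, "sa", model$config, residual = TRUE,
                dropout = model$config$dropout_rate, training = training)
  out <- repad(r$out, nrow(H))
  if (return_attn) list(output = out, attn = r$cache$heads) else out
}

#' Multi-head mutual attention between the two proteins of a complex
#'
#' Queries come from `H_i`, keys and values from its partner `H_j`; the
#' update carries no residual connection and no dropout (configurable via
#' `model_config(mutual_residual = TRUE)`).  The head-averaged attention
#' map is returned for interpretability; with `i` = antigen and `j` =
#' antibody its shape is `(len_ag, len_ab)`.
#'
#' @inheritParams self_attention
#' @param H_i,H_j `(n_i, d)` and `(n_j, d)` representations.
#' @param n_valid_i,n_valid_j True lengths of the two inputs.
#' @return List with `output` (`(n_i, d)`), `map` (head-averaged,
#'   `(n_valid_i, n_valid_j)`) and `attn` (per-head maps).
#' @export
mutual_attention <- function(model, H_i, H_j, n_valid_i = NULL,
                             n_valid_j = NULL, training = FALSE) {
  Hi <- trim_pad(H_i, n_valid_i)
  Hj <- trim_pad(H_j, n_valid_j)
  if (!all(is.finite(Hi)) || !all(is.finite(Hj)))
    stop("non-finite input", call. = FALSE)
  r <- attn_fwd(Hi, Hj, model$par, "ma", model$config,
                residual = model$config$mutual_residual, dropout = 0,
                training = training)
  list(output = repad(r$out, nrow(H_i)), map = r$map, attn = r$cache$heads)
}

#' Predict the binding affinity change for one wild/mutant pair
#'
#' Runs the full pipeline: embedding, self-attention of all four
#' sequences, mutual attention within the wild-type and within the mutant
#' complex, mask-aware pooling, and the fully connected head over the
#' concatenated `[ab_wt, ag_wt, ab_mt, ag_mt]` pooled vectors.  With
#' `use_attention = FALSE` the attention block is skipped and pooled
#' embeddings feed the head directly (head input width unchanged).
#'
#' @param model A `ddg_model`.
#' @param features List with `(n, 40)` matrices `ab_wt`, `ag_wt`,
#'   `ab_mt`, `ag_mt` (see [featurize_record()]).
#' @param n_valid Optional named list of true lengths for padded inputs.
#' @param training Enable dropout.
#' @return List with `ddg` (predicted change, kcal/mol) and `maps`
#'   (antigen x antibody mutual-attention maps `wt` and `mt`; `NULL` for
#'   the ablation variant).
#' @export
predict_ddg <- function(model, features, n_valid = NULL, training = FALSE) {
  stopifnot(inherits(model, "ddg_model"))
  feats <- features[ROLE_ORDER]
  if (!is.null(n_valid))
    for (r in names(n_valid))
      feats[[r]] <- trim_pad(feats[[r]], n_valid[[r]])
  fw <- forward_record(model$par, model$config, feats, training = training)
  list(ddg = fw$yhat, maps = fw$maps)
}

#' Predict ddG for every record of a dataset
#'
#' @param object A `ddg_model`.
#' @param dataset A `mutation_dataset`.
#' @param features Optional precomputed list of feature lists (as from
#'   [featurize_record()]), one per record.
#' @param ... Unused.
#' @return Numeric vector of predicted ddG values.
#' @export
predict.ddg_model <- function(object, dataset, features = NULL, ...) {
  if (is.null(features))
    features <- lapply(seq_len(nrow(dataset)), function(i)
      featurize_record(dataset_record(dataset, i)))
  vapply(features, function(f)
    forward_record(object$par, object$config, f)$yhat, numeric(1))
}
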