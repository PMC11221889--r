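# Hand-written backward passes for the network.  Each *_bwd consumes the
# cache stored by its forward counterpart and accumulates parameter
# gradients into the environment `g` (same names as the parameter list).
# Correctness is pinned by a finite-difference gradient test.

acc_grad <- function(g, name, value) {
  g[[name]] <- if (is.null(g[[name]])) value else g[[name]] + value
  invisible(NULL)
}

zero_grads <- function(par) {
  g <- new.env(parent = emptyenv())
  for (nm in names(par)) g[[nm]] <- par[[nm]] * 0
  g
}

embed_bwd <- function(dE, cache, par, cfg, g) {
  n <- cache$n; h <- cfg$hidden_size
  xhat <- cache$xhat; inv <- cache$inv
  acc_grad(g, "ln_g", colSums(dE * xhat))
  acc_grad(g, "ln_b", colSums(dE))
  dxhat <- dE * rep(par$ln_g, each = n)
  dE0 <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  kmax <- max(cfg$kernel_sizes)
  dZ <- matrix(0, n, 6L * h)
  for (b in 1:3) {
    cb <- cache$branches[[b]]
    dO <- dE0[, (b - 1L) * h + seq_len(h), drop = FALSE]
    da <- dO * cb$s
    dg_pre <- dO * cb$a * cb$s * (1 - cb$s)
    dZ[, (b - 1L) * 2L * h + seq_len(2L * h)] <- cbind(da, dg_pre)
  }
  dWc <- crossprod(cache$Xu, dZ)
  dbc <- colSums(dZ)
  for (b in 1:3) {
    cols <- (b - 1L) * 2L * h + seq_len(2L * h)
    acc_grad(g, paste0("conv", b, "_W"),
             dWc[branch_row_idx(cfg$kernel_sizes[b], kmax), cols,
                 drop = FALSE])
    acc_grad(g, paste0("conv", b, "_b"), dbc[cols])
  }
  dXu <- tcrossprod(dZ, cache$Wc)
  fold_back(dXu, kmax, n, 40L)
}

attn_bwd <- function(dout, cache, par, prefix, cfg, g) {
  d <- ncol(cache$Hq); nh <- cfg$n_heads; dk <- d %/% nh
  Wq <- par[[paste0(prefix, "_Wq")]]
  Wk <- par[[paste0(prefix, "_Wk")]]
  Wv <- par[[paste0(prefix, "_Wv")]]
  Wo <- par[[paste0(prefix, "_Wo")]]
  dmix <- dout
  if (!is.null(cache$mask)) dmix <- dmix * cache$mask
  acc_grad(g, paste0(prefix, "_Wo"), crossprod(cache$O, dmix))
  dO <- tcrossprod(dmix, Wo)
  dQ <- matrix(0, nrow(cache$Hq), d)
  dK <- matrix(0, nrow(cache$Hk), d)
  dV <- matrix(0, nrow(cache$Hk), d)
  for (hh in seq_len(nh)) {
    idx <- (hh - 1L) * dk + seq_len(dk)
    A <- cache$heads[[hh]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  if (cache$is_self) {
    dQKV <- cbind(dQ, dK, dV)
    dW <- crossprod(cache$Hq, dQKV)
    acc_grad(g, paste0(prefix, "_Wq"), dW[, seq_len(d), drop = FALSE])
    acc_grad(g, paste0(prefix, "_Wk"), dW[, d + seq_len(d), drop = FALSE])
    acc_grad(g, paste0(prefix, "_Wv"), dW[, 2L * d + seq_len(d), drop = FALSE])
    dH <- tcrossprod(dQKV, cbind(Wq, Wk, Wv))
    dHq <- if (cache$residual) dH + dout else dH
    # queries and keys/values are the same tensor: dHk already folded in
    return(list(dHq = dHq, dHk = matrix(0, nrow(cache$Hk), d)))
  }
  acc_grad(g, paste0(prefix, "_Wq"), crossprod(cache$Hq, dQ))
  dKV <- cbind(dK, dV)
  dWkv <- crossprod(cache$Hk, dKV)
  acc_grad(g, paste0(prefix, "_Wk"), dWkv[, seq_len(d), drop = FALSE])
  acc_grad(g, paste0(prefix, "_Wv"), dWkv[, d + seq_len(d), drop = FALSE])
  dHq <- tcrossprod(dQ, Wq)
  if (cache$residual) dHq <- dHq + dout
  dHk <- tcrossprod(dKV, cbind(Wk, Wv))
  list(dHq = dHq, dHk = dHk)
}

pool_bwd <- function(dp, cache, cfg, d_cols) {
  if (cfg$pooling == "mean") {
    matrix(rep(dp / cache$n, each = cache$n), cache$n, d_cols)
  } else {
    dM <- matrix(0, cache$n, d_cols)
    dM[cbind(cache$argmax, seq_len(d_cols))] <- dp
    dM
  }
}

head_bwd <- function(dy, cache, par, g) {
  dr3 <- dy %*% t(par$out_W)
  acc_grad(g, "out_W", crossprod(cache$r3, dy))
  acc_grad(g, "out_b", sum(dy))
  dz3 <- dr3 * (cache$z3 > 0)
  acc_grad(g, "fc3_W", crossprod(cache$r2, dz3))
  acc_grad(g, "fc3_b", colSums(dz3))
  dr2 <- tcrossprod(dz3, par$fc3_W)
  dz2 <- dr2 * (cache$z2 > 0)
  acc_grad(g, "fc2_W", crossprod(cache$r1, dz2))
  acc_grad(g, "fc2_b", colSums(dz2))
  dr1 <- tcrossprod(dz2, par$fc2_W)
  dz1 <- dr1 * (cache$z1 > 0)
  acc_grad(g, "fc1_W", crossprod(cache$x, dz1))
  acc_grad(g, "fc1_b", colSums(dz1))
  tcrossprod(dz1, par$fc1_W)
}

# dyhat: scalar gradient of the loss wrt the predicted ddg
backward_record <- function(par, cfg, cache, dyhat, g) {
  d <- 3L * cfg$hidden_size
  dy <- matrix(dyhat, 1L, 1L)
  dx <- head_bwd(dy, cache$head$cache, par, g)
  dpools <- list()
  for (i in seq_along(ROLE_ORDER))
    dpools[[ROLE_ORDER[i]]] <- dx[1L, (i - 1L) * d + seq_len(d)]
  dreps <- lapply(ROLE_ORDER, function(r)
    pool_bwd(dpools[[r]], cache$pools[[r]]$cache, cfg, d))
  names(dreps) <- ROLE_ORDER
  if (cfg$use_attention) {
    # mutual attention: each protein was the query in its own call and
    # the key/value source in its partner's call
    partner <- c(ab_wt = "ag_wt", ag_wt = "ab_wt",
                 ab_mt = "ag_mt", ag_mt = "ab_mt")
    dHs <- stats::setNames(vector("list", 4L), ROLE_ORDER)
    for (r in ROLE_ORDER) {
      bwd <- attn_bwd(dreps[[r]], cache$ma[[r]]$cache, par, "ma", cfg, g)
      dHs[[r]] <- if (is.null(dHs[[r]])) bwd$dHq else dHs[[r]] + bwd$dHq
      p <- partner[[r]]
      dHs[[p]] <- if (is.null(dHs[[p]])) bwd$dHk else dHs[[p]] + bwd$dHk
    }
    dE <- lapply(ROLE_ORDER, function(r) {
      bwd <- attn_bwd(dHs[[r]], cache$sa[[r]]$cache, par, "sa", cfg, g)
      bwd$dHq + bwd$dHk  # queries and keys/values are the same tensor
    })
    names(dE) <- ROLE_ORDER
  } else {
    dE <- dreps
  }
  for (r in ROLE_ORDER)
    embed_bwd(dE[[r]], cache$emb[[r]]$cache, par, cfg, g)
  invisible(NULL)
}
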