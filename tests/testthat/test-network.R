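test_that("embedding maps (n, 40) to (n, 3*hidden) and zeroes stay zero", {
  m <- small_model(hidden_size = 8L)
  X <- matrix(rnorm(10 * 40), 10, 40)
  E <- embed_features(m, X)
  expect_equal(dim(E), c(10L, 24L))

  # zero input + zero-initialized biases: gate * value = sigmoid(0) * 0,
  # so activations (and the normalized output, with beta = 0) are zero
  Z <- embed_features(m, matrix(0, 6, 40))
  expect_equal(Z, matrix(0, 6, 24))

  # batch of sequences as a list, mirrored shapes
  out <- lapply(list(X, X[1:5, ]), function(x) embed_features(m, x))
  expect_equal(dim(out[[2]]), c(5L, 24L))

  expect_error(embed_features(m, matrix(0, 4, 39)), "40 columns")
})

test_that("self-attention matches the loop oracle and is residual", {
  for (heads in c(1L, 2L)) {
    m <- tiny_attention_model(hidden_size = 2L, n_heads = heads,
                              seed = heads)
    d <- 6L
    for (n in c(1L, 3L, 5L)) {
      H <- withr::with_seed(n + 10L, matrix(rnorm(n * d, sd = 0.5), n, d))
      got <- self_attention(m, H)
      want <- oracle_attention(H, H, m$par$sa_Wq, m$par$sa_Wk, m$par$sa_Wv,
                               m$par$sa_Wo, heads, residual = TRUE)
      expect_equal(got, want$out, tolerance = 1e-6)
    }
  }
  # N = 1: softmax over a single key is exactly 1
  m <- tiny_attention_model(n_heads = 1L)
  H1 <- matrix(rnorm(6), 1, 6)
  r <- self_attention(m, H1, return_attn = TRUE)
  expect_equal(r$attn[[1]], matrix(1, 1, 1))
  expect_equal(r$output,
               (H1 %*% m$par$sa_Wv) %*% m$par$sa_Wo + H1)
})

test_that("mutual attention matches the loop oracle, no residual, map shape (len_ag, len_ab)", {
  m <- tiny_attention_model(hidden_size = 2L, n_heads = 1L, seed = 3L)
  H_ag <- withr::with_seed(1, matrix(rnorm(2 * 6, sd = 0.5), 2, 6))
  H_ab <- withr::with_seed(2, matrix(rnorm(3 * 6, sd = 0.5), 3, 6))
  got <- mutual_attention(m, H_ag, H_ab)
  want <- oracle_attention(H_ag, H_ab, m$par$ma_Wq, m$par$ma_Wk,
                           m$par$ma_Wv, m$par$ma_Wo, 1L, residual = FALSE)
  expect_equal(got$output, want$out, tolerance = 1e-6)
  expect_equal(got$map, want$map, tolerance = 1e-6)
  expect_equal(dim(got$map), c(2L, 3L))

  # single key: attention column of ones, output = projected single row
  H1 <- matrix(rnorm(6), 1, 6)
  r1 <- mutual_attention(m, H_ag, H1)
  expect_equal(r1$attn[[1]], matrix(1, 2, 1))
  expect_equal(r1$output,
               matrix(1, 2, 1) %*% (H1 %*% m$par$ma_Wv) %*% m$par$ma_Wo)
})

test_that("raw attention rows are probability vectors over keys", {
  m <- small_model(hidden_size = 4L, n_heads = 3L)
  withr::with_seed(77, {
    for (rep in 1:5) {
      n_i <- sample(2:9, 1); n_j <- sample(2:9, 1)
      H_i <- matrix(rnorm(n_i * 12), n_i, 12)
      H_j <- matrix(rnorm(n_j * 12), n_j, 12)
      sa <- self_attention(m, H_i, return_attn = TRUE)
      ma <- mutual_attention(m, H_i, H_j)
      for (A in c(sa$attn, ma$attn)) {
        expect_true(all(A >= 0))
        expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
      }
      expect_equal(rowSums(ma$map), rep(1, n_i), tolerance = 1e-6)
    }
  })
})

test_that("predict_ddg is deterministic in evaluation mode and finite", {
  m <- small_model()
  f <- random_features(12, 9)
  p1 <- predict_ddg(m, f)
  p2 <- predict_ddg(m, f)
  expect_identical(p1$ddg, p2$ddg)
  expect_true(is.finite(p1$ddg))
  expect_equal(dim(p1$maps$wt), c(9L, 12L))
})

test_that("appending padded positions leaves predictions unchanged", {
  m <- small_model()
  f <- random_features(12, 9, seed = 4L)
  base <- predict_ddg(m, f)$ddg
  padded <- list(
    ab_wt = rbind(f$ab_wt, matrix(0, 3, 40)),
    ag_wt = rbind(f$ag_wt, matrix(0, 5, 40)),
    ab_mt = rbind(f$ab_mt, matrix(0, 3, 40)),
    ag_mt = rbind(f$ag_mt, matrix(0, 5, 40)))
  got <- predict_ddg(m, padded,
                     n_valid = list(ab_wt = 12L, ag_wt = 9L,
                                    ab_mt = 12L, ag_mt = 9L))$ddg
  expect_lt(abs(got - base), 1e-5)
})

test_that("batch predictions are order-stable under permutation", {
  m <- small_model()
  gen <- small_dataset(mutations_per_complex = 3L)
  feats <- lapply(seq_len(nrow(gen$dataset)), function(i)
    featurize_record(dataset_record(gen$dataset, i)))
  preds <- predict(m, gen$dataset, features = feats)
  perm <- rev(seq_along(feats))
  preds_perm <- predict(m, gen$dataset[perm, ], features = feats[perm])
  expect_equal(preds_perm, preds[perm])
})

test_that("the ablation variant runs the same head with unchanged input width", {
  m_full <- small_model(seed = 8L)
  m_abl <- small_model(use_attention = FALSE, seed = 8L)
  expect_equal(dim(m_abl$par$fc1_W), dim(m_full$par$fc1_W))
  f <- random_features(10, 8, seed = 2L)
  p_full <- predict_ddg(m_full, f)
  p_abl <- predict_ddg(m_abl, f)
  expect_true(is.finite(p_full$ddg) && is.finite(p_abl$ddg))
  expect_null(p_abl$maps$wt)
})

test_that("parameter shapes audit across configurations", {
  for (cfg in list(model_config(hidden_size = 4L, n_heads = 2L,
                                fc_sizes = c(8L, 6L, 4L)),
                   model_config(hidden_size = 6L, n_heads = 3L,
                                kernel_sizes = c(1L, 3L, 5L)),
                   model_config(hidden_size = 8L, n_heads = 8L))) {
    m <- init_model(cfg)
    expect_true(check_model_shapes(m))
    n <- 7L
    E <- embed_features(m, matrix(rnorm(n * 40), n, 40))
    expect_equal(dim(E), c(n, 3L * cfg$hidden_size))
  }
  expect_error(model_config(hidden_size = 4L, n_heads = 5L))
  expect_error(model_config(kernel_sizes = c(2L, 4L, 6L)))
})

test_that("backpropagated gradients match finite differences", {
  m <- small_model(hidden_size = 4L, n_heads = 2L)
  gen <- small_dataset()
  f <- featurize_record(dataset_record(gen$dataset, 1))
  fw <- seqddg:::forward_record(m$par, m$config, f)
  g <- seqddg:::zero_grads(m$par)
  seqddg:::backward_record(m$par, m$config, fw$cache, 1, g)
  eps <- 1e-5
  withr::with_seed(123, {
    picks <- c("conv1_W", "conv3_b", "ln_g", "sa_Wq", "ma_Wv", "ma_Wo",
               "fc1_W", "fc3_b", "out_W")
    for (nm in picks) {
      i <- sample.int(length(m$par[[nm]]), 1)
      par2 <- m$par
      par2[[nm]][i] <- par2[[nm]][i] + eps
      up <- seqddg:::forward_record(par2, m$config, f)$yhat
      par2[[nm]][i] <- par2[[nm]][i] - 2 * eps
      dn <- seqddg:::forward_record(par2, m$config, f)$yhat
      num <- (up - dn) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   label = paste("gradient of", nm))
    }
  })
})

test_that("checkpoints round-trip through save/load with a shape audit", {
  m <- small_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  feats <- random_features(8, 6, seed = 9L)
  expect_identical(predict_ddg(m, feats)$ddg, predict_ddg(m2, feats)$ddg)
  m_bad <- m
  m_bad$par$fc2_W <- m_bad$par$fc2_W[, -1]
  expect_error(check_model_shapes(m_bad), "fc2_W")
})
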