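# Optimization of the model against ddG labels with MSE loss.

#' Mean squared error
#'
#' @param pred,true Equal-length numeric vectors.
#' @return `mean((pred - true)^2)`.
#' @examples
#' mse_loss(c(1, 2, 3), c(2, 2, 5))
#' @export
mse_loss <- function(pred, true) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (length(pred) != length(true))
    stop("length mismatch: ", length(pred), " vs ", length(true),
         call. = FALSE)
  mean((pred - true)^2)
}

#' Training hyperparameters
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Records per mini-batch.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param seed Seed for shuffling and dropout.
#' @param early_stop_patience Optional: stop after this many epochs
#'   without validation improvement (requires a validation set).
#' @return A `ddg_train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-4, weight_decay = 0,
                         seed = 1L, early_stop_patience = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "ddg_train_config")
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, g, opt, lr, wd, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(par)) {
    grad <- g[[nm]]
    if (wd > 0) grad <- grad + wd * par[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grad
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grad^2
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(par = par, opt = opt)
}

dataset_features <- function(dataset) {
  lapply(seq_len(nrow(dataset)), function(i)
    featurize_record(dataset_record(dataset, i)))
}

#' Train a model on a mutation dataset
#'
#' Adam on shuffled mini-batches minimizing [mse_loss()].  Fully
#' reproducible from `model_cfg$seed` (parameter init) and
#' `train_cfg$seed` (shuffling, dropout).  When a validation set is
#' given, the state with the best validation loss is returned and
#' optional early stopping applies; otherwise the final state is
#' returned.
#'
#' @param train_set A `mutation_dataset`.
#' @param model_cfg A [model_config()], or an already initialized
#'   `ddg_model` to continue training.
#' @param train_cfg A [train_config()].
#' @param val_set Optional validation `mutation_dataset`.
#' @param features,val_features Optional precomputed per-record feature
#'   lists (see [featurize_record()]); computed on the fly if omitted.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained `ddg_model`) and `history` (one
#'   row per epoch run: `train_loss`, and `val_loss`/`val_pcc` when a
#'   validation set is given).
#' @export
train_model <- function(train_set, model_cfg, train_cfg, val_set = NULL,
                        features = NULL, val_features = NULL,
                        verbose = FALSE) {
  stopifnot(nrow(train_set) >= 1L)
  model <- if (inherits(model_cfg, "ddg_model")) model_cfg
           else init_model(model_cfg)
  cfg <- model$config
  par <- model$par
  if (is.null(features)) features <- dataset_features(train_set)
  if (!is.null(val_set) && is.null(val_features))
    val_features <- dataset_features(val_set)
  y <- train_set$ddg
  n <- nrow(train_set)
  opt <- adam_init(par)
  hist <- list()
  best <- list(loss = Inf, par = NULL, stale = 0L)

  withr::with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / train_cfg$batch_size))
      batch_losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        g <- zero_grads(par)
        losses <- numeric(length(b))
        for (j in seq_along(b)) {
          i <- b[j]
          fw <- forward_record(par, cfg, features[[i]], training = TRUE)
          err <- fw$yhat - y[i]
          losses[j] <- err^2
          backward_record(par, cfg, fw$cache, 2 * err / length(b), g)
        }
        batch_losses[bi] <- mean(losses)
        if (!is.finite(batch_losses[bi]))
          stop(sprintf(
            "non-finite training loss in epoch %d, batch %d (exploding gradients?)",
            epoch, bi), call. = FALSE)
        st <- adam_step(par, g, opt, train_cfg$learning_rate,
                        train_cfg$weight_decay)
        par <- st$par; opt <- st$opt
      }
      row <- data.frame(epoch = epoch, train_loss = mean(batch_losses))
      if (!is.null(val_set)) {
        vp <- vapply(val_features, function(f)
          forward_record(par, cfg, f)$yhat, numeric(1))
        row$val_loss <- mse_loss(vp, val_set$ddg)
        row$val_pcc <- tryCatch(pearson(val_set$ddg, vp),
                                error = function(e) NA_real_)
        if (row$val_loss < best$loss) {
          best$loss <- row$val_loss; best$par <- par; best$stale <- 0L
        } else best$stale <- best$stale + 1L
      }
      hist[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %d: %s", epoch,
                        paste(sprintf("%s=%.4g", names(row)[-1],
                                      unlist(row[-1])), collapse = " ")))
      if (!is.null(val_set) && !is.null(train_cfg$early_stop_patience) &&
          best$stale >= train_cfg$early_stop_patience) break
    }
  })
  if (!is.null(val_set) && !is.null(best$par)) par <- best$par
  model$par <- par
  list(model = model, history = do.call(rbind, hist))
}
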