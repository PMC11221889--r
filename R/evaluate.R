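# Evaluation protocols (K-fold and label-ascending splits) and metrics
# (Pearson correlation, coefficient of determination, rank consistency).

#' Random K-fold split plan
#'
#' Records are shuffled with `seed` and dealt into `k` near-equal folds
#' (sizes differ by at most one).
#'
#' @param dataset A `mutation_dataset` (or any data.frame of records).
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Shuffle seed.
#' @return A `split_plan` with `scheme = "kfold"` and per-record fold
#'   assignments.
#' @export
kfold_split <- function(dataset, k, seed = 1L) {
  n <- nrow(dataset)
  if (k < 2L || k > n) stop("k must be in [2, n records]", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[idx] <- rep_len(seq_len(k), n)
  structure(list(scheme = "kfold", assignments = fold, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Label-ascending train/test split
#'
#' Within each complex, records are sorted by ddG ascending (ties broken
#' by stable input order) and the `ceiling(test_fraction * group size)`
#' records with the highest labels go to the test set, probing
#' extrapolation to stronger affinity changes.  Single-record complexes
#' go to the training set with a warning.
#'
#' @param dataset A `mutation_dataset`.
#' @param test_fraction Fraction of each complex held out, in (0, 1).
#' @return A `split_plan` with `scheme = "label_ascending"` and
#'   per-record `"train"`/`"test"` assignments.
#' @export
label_ascending_split <- function(dataset, test_fraction = 0.2) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  assign <- rep("train", nrow(dataset))
  singletons <- 0L
  for (cx in unique(dataset$complex_id)) {
    rows <- which(dataset$complex_id == cx)
    if (length(rows) == 1L) { singletons <- singletons + 1L; next }
    ord <- rows[order(dataset$ddg[rows])]  # stable: ties keep input order
    n_test <- ceiling(test_fraction * length(rows))
    assign[ord[(length(ord) - n_test + 1L):length(ord)]] <- "test"
  }
  if (singletons > 0L)
    warning(singletons, " single-record complex(es) assigned to train",
            call. = FALSE)
  structure(list(scheme = "label_ascending", assignments = assign,
                 test_fraction = test_fraction),
            class = "split_plan")
}

#' Pearson correlation coefficient
#'
#' @param y,yhat Equal-length numeric vectors (length >= 2, both
#'   non-constant).
#' @return Product-moment correlation in [-1, 1].
#' @export
pearson <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(y, yhat)
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; at most 1, may be
#' negative for predictions worse than the mean.
#'
#' @inheritParams pearson
#' @return R-squared value.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R-squared undefined for constant y", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Rank consistency (R-squared on rank vectors)
#'
#' Both vectors are converted to ascending ranks (average ranks for
#' ties) and [r_squared()] is applied to the ranks; used to score how
#' well a predicted ddG ordering reproduces an experimental ordering of
#' candidate mutations.
#'
#' @inheritParams pearson
#' @return Rank-based R-squared.
#' @export
rank_consistency <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  r_squared(rank(y, ties.method = "average"),
            rank(yhat, ties.method = "average"))
}

safe_metric <- function(f, y, yhat) {
  tryCatch(f(y, yhat), error = function(e) NA_real_)
}

#' Cross-validate a model configuration over a split plan
#'
#' For each fold of a K-fold plan (or the single train/test split of a
#' label-ascending plan) a fresh model is trained on the training
#' portion and predicts the held-out portion.  Pooled metrics are
#' computed over the concatenation of all out-of-fold predictions;
#' per-fold metrics are also reported (NA where undefined, e.g. fewer
#' than 2 test records).
#'
#' @param dataset A `mutation_dataset`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param plan A `split_plan` covering the dataset.
#' @param features Optional precomputed per-record features.
#' @param verbose Print fold progress.
#' @return An `eval_report` list: `predictions` (record, complex_id,
#'   y_true, y_pred, fold), `per_fold` metric table, and pooled `pcc`
#'   and `r2`.
#' @export
cross_validate <- function(dataset, model_cfg, train_cfg, plan,
                           features = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"),
            length(plan$assignments) == nrow(dataset))
  if (is.null(features)) features <- dataset_features(dataset)
  folds <- if (plan$scheme == "kfold") sort(unique(plan$assignments))
           else "test"
  pred <- rep(NA_real_, nrow(dataset))
  fold_of <- rep(NA_character_, nrow(dataset))
  per_fold <- list()
  for (f in folds) {
    test_idx <- which(plan$assignments == f)
    train_idx <- setdiff(seq_len(nrow(dataset)), test_idx)
    if (plan$scheme == "label_ascending")
      train_idx <- which(plan$assignments == "train")
    if (verbose)
      message("fold ", f, ": ", length(train_idx), " train / ",
              length(test_idx), " test")
    fit <- train_model(dataset[train_idx, ], model_cfg, train_cfg,
                       features = features[train_idx])
    pred[test_idx] <- vapply(features[test_idx], function(ft)
      forward_record(fit$model$par, fit$model$config, ft)$yhat, numeric(1))
    fold_of[test_idx] <- as.character(f)
    per_fold[[as.character(f)]] <- data.frame(
      fold = as.character(f), n_test = length(test_idx),
      pcc = safe_metric(pearson, dataset$ddg[test_idx], pred[test_idx]),
      r2 = safe_metric(r_squared, dataset$ddg[test_idx], pred[test_idx]),
      stringsAsFactors = FALSE)
  }
  covered <- !is.na(fold_of)
  predictions <- data.frame(
    record = which(covered),
    complex_id = dataset$complex_id[covered],
    y_true = dataset$ddg[covered],
    y_pred = pred[covered],
    fold = fold_of[covered],
    stringsAsFactors = FALSE)
  structure(list(
    predictions = predictions,
    per_fold = do.call(rbind, per_fold),
    pcc = safe_metric(pearson, predictions$y_true, predictions$y_pred),
    r2 = safe_metric(r_squared, predictions$y_true, predictions$y_pred)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d predictions, pooled PCC %.3f, R2 %.3f>\n",
              nrow(x$predictions), x$pcc, x$r2))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
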