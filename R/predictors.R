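#' Train an age predictor on one data source
#'
#' Minimizes the mean squared error between predicted and chronological age
#' with the configured optimizer, evaluating the validation MSE after every
#' epoch and returning the checkpoint with the lowest validation MSE.
#' The per-epoch learning rate is `learning_rate / (1 + lr_decay * epoch)`.
#' Deterministic per seed; `epochs = 0` returns the Xavier initialization
#' unchanged.
#'
#' @param train,val participant tables; `val` may be `NULL`, in which case
#'   the final-epoch parameters are returned.
#' @param config a [predictor_config()].
#' @param epochs training epochs (>= 0).
#' @param batch_size minibatch size.
#' @param seed integer seed (initialization, shuffling, dropout).
#' @return A [param_vector()]; attribute `"history"` holds a tibble of
#'   per-epoch training loss and validation MSE/MAE.
#' @export
train_predictor <- function(train, val, config, epochs, batch_size = 8L, seed = 1L) {
  pp <- preprocess_stats(train)
  adapter <- make_model_adapter(config, train, preprocess = pp)
  params <- adapter$init(seed)
  attr(params, "preprocess") <- pp
  if (epochs == 0) return(params)
  best <- params
  best_val <- Inf
  hist <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    lr <- config$learning_rate / (1 + config$lr_decay * (e - 1))
    up <- local_update(params, adapter, train, epochs = 1L,
                       batch_size = batch_size,
                       seed = derive_seed(seed, "epoch", e),
                       learning_rate = lr)
    params <- up$params
    if (!is.finite(up$loss)) stop(sprintf("non-finite training loss at epoch %d", e),
                                  call. = FALSE)
    vmse <- if (!is.null(val) && nrow(val) > 0) adapter$loss(params, val) else NA_real_
    vmae <- if (!is.null(val) && nrow(val) > 0) mae(adapter$predict(params, val), val$age) else NA_real_
    hist[[e]] <- tibble::tibble(epoch = e, train_loss = up$loss,
                                val_mse = vmse, val_mae = vmae)
    if (is.na(vmse) || vmse <= best_val) {
      best <- params
      best_val <- if (is.na(vmse)) Inf else vmse
    }
  }
  out <- if (is.null(val) || nrow(val) == 0) params else best
  attr(out, "history") <- do.call(rbind, hist)
  attr(out, "preprocess") <- pp
  out
}

#' Predict age for every participant
#'
#' @param params trained [param_vector()] whose layout matches the adapter
#'   implied by `config` and the table's feature dimension.
#' @param table a participant table.
#' @param config the [predictor_config()] used in training.
#' @return Numeric vector of predicted ages (years), one per row.
#' @export
predict_age <- function(params, table, config) {
  adapter <- make_model_adapter(config, table,
                                preprocess = attr(params, "preprocess"))
  if (!same_layout(params, adapter$init(1L))) {
    stop("parameter layout does not match this config/feature dimension", call. = FALSE)
  }
  out <- adapter$predict(params, table)
  if (any(!is.finite(out))) stop("non-finite predictions", call. = FALSE)
  out
}

#' Mean absolute error in years
#' @param pred,age equal-length numeric vectors.
#' @return `mean(abs(pred - age))`.
#' @export
mae <- function(pred, age) {
  if (length(pred) != length(age)) stop("`pred` and `age` differ in length", call. = FALSE)
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  mean(abs(pred - age))
}

#' Percentile bootstrap confidence interval for the MAE
#'
#' Resamples participants with replacement and takes the percentile interval
#' of the resampled MAEs at the requested level.
#'
#' @param pred,age equal-length numeric vectors.
#' @param resamples bootstrap resamples (default 1000).
#' @param level interval level in (0, 1) (default 0.95).
#' @param seed integer seed.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci_mae <- function(pred, age, resamples = 1000L, level = 0.95, seed = 1L) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (resamples < 1) stop("`resamples` must be >= 1", call. = FALSE)
  err <- abs(pred - age)
  n <- length(err)
  if (n == 0) stop("empty input", call. = FALSE)
  stats_ <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(resamples), function(i) mean(err[sample.int(n, replace = TRUE)]),
           numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats_, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' k-fold cross-validated MAE
#'
#' Folds are disjoint by `participant_id`. `trainer` is called with the
#' training portion and must return a prediction function
#' `function(table) -> numeric`.
#'
#' @param table participant table with `n >= k` participants.
#' @param k folds (>= 2).
#' @param trainer `function(train_table)` returning a predictor function.
#' @param seed integer seed for fold assignment.
#' @return Numeric vector of per-fold MAEs (years).
#' @export
kfold_cv <- function(table, k = 3L, trainer, seed = 1L) {
  ids <- unique(table$participant_id)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > length(ids)) stop("`k` exceeds the number of participants", call. = FALSE)
  fold_of <- with_seed(derive_seed(seed, "kfold"), {
    stats::setNames(sample(rep(seq_len(k), length.out = length(ids))), ids)
  })
  vapply(seq_len(k), function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    test <- table[table$participant_id %in% test_ids, , drop = FALSE]
    train <- table[!table$participant_id %in% test_ids, , drop = FALSE]
    predict_fn <- trainer(train)
    mae(predict_fn(test), test$age)
  }, numeric(1))
}
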