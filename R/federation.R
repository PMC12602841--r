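#' Configure a federated training run
#'
#' Defaults mirror the round protocol used throughout the package: 20
#' communication rounds of 3 local epochs each at minibatch size 8, with
#' sample-size-weighted server aggregation. Training also stops early when
#' the size-weighted validation MAE changes by less than `convergence_tol`
#' between rounds (the round cap is normally the binding criterion).
#'
#' @param rounds communication rounds (>= 1).
#' @param local_epochs local passes per round (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param aggregation `"n_weighted"` or `"equal"`.
#' @param convergence_tol absolute change in aggregated validation MAE below
#'   which training stops (>= 0).
#' @param seed master seed; client shuffling is keyed by
#'   (seed, cohort, round) so results do not depend on client ordering.
#' @return An object of class `federation_config`.
#' @export
federation_config <- function(rounds = 20L, local_epochs = 3L, batch_size = 8L,
                              aggregation = c("n_weighted", "equal"),
                              convergence_tol = 1e-6, seed = 1L) {
  aggregation <- match.arg(aggregation)
  if (rounds < 1 || local_epochs < 1 || batch_size < 1) {
    stop("rounds, local_epochs and batch_size must all be >= 1", call. = FALSE)
  }
  check_scalar_number(convergence_tol, "convergence_tol", lower = 0)
  structure(list(rounds = as.integer(rounds), local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size), aggregation = aggregation,
                 convergence_tol = convergence_tol, seed = as.integer(seed)),
            class = "federation_config")
}

#' One client's local training pass
#'
#' Starting from the shared parameters, runs `epochs` passes of minibatch
#' optimization on the client's data and returns the updated parameters with
#' the final full-data training loss. The input parameter vector is not
#' modified; `epochs = 0` returns it unchanged. Optimizer state (Adam
#' moments) is local to the call, as each round restarts from freshly
#' aggregated parameters.
#'
#' @param params shared [param_vector()].
#' @param adapter a [make_model_adapter()] object.
#' @param data non-empty participant table.
#' @param epochs local epochs (>= 0).
#' @param batch_size minibatch size; use `batch_size >= nrow(data)` for
#'   full-batch gradient steps.
#' @param seed seed for minibatch shuffling (and dropout masks).
#' @param learning_rate optional override of the adapter config's rate; no
#'   per-epoch decay is applied within a local update (rounds are short).
#' @return List with `params` (updated [param_vector()]) and `loss`
#'   (training MSE at the returned parameters).
#' @export
local_update <- function(params, adapter, data, epochs, batch_size,
                         seed = 1L, learning_rate = NULL) {
  if (nrow(data) == 0) stop("client data is empty", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (epochs == 0) {
    return(list(params = params, loss = adapter$loss(params, data)))
  }
  lr <- learning_rate %||% adapter$config$learning_rate
  n <- nrow(data)
  vals <- params$values
  state <- list(m = numeric(length(vals)), v = numeric(length(vals)), t = 0L)
  with_seed(derive_seed(seed, "local_update"), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1, n)]
        g <- adapter$grad(pv_replace(params, vals), data[rows, , drop = FALSE],
                          training = TRUE)
        st <- optimizer_step(vals, g, lr, adapter$config, state)
        vals <- st$values; state <- st$state
      }
    }
  })
  out <- pv_replace(params, vals)
  list(params = out, loss = adapter$loss(out, data))
}

#' Run federated averaging over simulated clients
#'
#' Executes the round protocol: the server broadcasts the current
#' parameters; every client runs [local_update()] on its training data; the
#' server aggregates the returned parameters ([aggregate_params()]); the
#' aggregated model is evaluated on every client's validation set. Training
#' stops at `config$rounds` or when the size-weighted validation MAE changes
#' by less than `config$convergence_tol`.
#'
#' @param clients named list; each element is a list with `train` and `val`
#'   participant tables.
#' @param model_factory zero-argument function returning a shared
#'   `model_adapter` (initialization is Xavier, seeded by `config$seed`).
#' @param config a [federation_config()].
#' @return List of class `federated_fit` with `params` (final aggregated
#'   [param_vector()]), `log` (tibble: round, cohort, n_train, train_loss,
#'   val_mae, checksum), `history` (aggregated parameters per round) and
#'   `adapter`.
#' @export
run_federated <- function(clients, model_factory, config = federation_config()) {
  if (length(clients) < 1) stop("need at least one client", call. = FALSE)
  nms <- names(clients) %||% paste0("client", seq_along(clients))
  if (any(!nzchar(nms))) nms <- paste0("client", seq_along(clients))
  adapter <- model_factory()
  params <- adapter$init(config$seed)
  sizes <- vapply(clients, function(cl) nrow(cl$train), integer(1))
  log_rows <- list()
  history <- vector("list", config$rounds)
  prev_wmae <- Inf
  rounds_run <- 0L
  for (r in seq_len(config$rounds)) {
    locals <- vector("list", length(clients))
    losses <- numeric(length(clients))
    for (j in seq_along(clients)) {
      up <- local_update(params, adapter, clients[[j]]$train,
                         epochs = config$local_epochs,
                         batch_size = config$batch_size,
                         seed = derive_seed(config$seed, nms[j], r))
      if (!is.finite(up$loss)) {
        stop(sprintf("training diverged at round %d in cohort '%s'", r, nms[j]),
             call. = FALSE)
      }
      locals[[j]] <- up$params
      losses[j] <- up$loss
    }
    params <- aggregate_params(locals, sizes = sizes, scheme = config$aggregation)
    attr(params, "preprocess") <- adapter$preprocess
    val_mae <- vapply(seq_along(clients), function(j) {
      v <- clients[[j]]$val
      if (is.null(v) || nrow(v) == 0) return(NA_real_)
      mae(adapter$predict(params, v), v$age)
    }, numeric(1))
    val_sizes <- vapply(clients, function(cl) {
      if (is.null(cl$val)) 0L else nrow(cl$val)
    }, integer(1))
    log_rows[[r]] <- tibble::tibble(
      round = r, cohort = nms, n_train = sizes, train_loss = losses,
      val_mae = val_mae, checksum = sum(params$values))
    history[[r]] <- params
    rounds_run <- r
    ok <- !is.na(val_mae) & val_sizes > 0
    wmae <- if (any(ok)) sum(val_mae[ok] * val_sizes[ok]) / sum(val_sizes[ok]) else NA_real_
    if (!is.na(wmae) && abs(prev_wmae - wmae) < config$convergence_tol) break
    if (!is.na(wmae)) prev_wmae <- wmae
  }
  structure(list(params = params,
                 log = do.call(rbind, log_rows[seq_len(rounds_run)]),
                 history = history[seq_len(rounds_run)],
                 adapter = adapter, config = config),
            class = "federated_fit")
}

#' Pick the best round from a federation log
#'
#' `global_val_mae` returns the round minimizing the size-weighted mean
#' validation MAE across cohorts. `per_cohort_min` returns, per cohort, the
#' round at which that cohort's validation MAE was lowest (cohorts may
#' disagree; reconciliation is left to the caller).
#'
#' @param log the `log` tibble of a [run_federated()] result.
#' @param rule `"global_val_mae"` or `"per_cohort_min"`.
#' @return An integer round index, or a named integer vector for
#'   `per_cohort_min`.
#' @export
select_best_round <- function(log, rule = c("global_val_mae", "per_cohort_min")) {
  rule <- match.arg(rule)
  if (is.null(log) || nrow(log) == 0) stop("round log is empty", call. = FALSE)
  if (rule == "global_val_mae") {
    ok <- !is.na(log$val_mae)
    agg <- stats::aggregate(cbind(num = val_mae * n_train, den = n_train) ~ round,
                            data = as.data.frame(log[ok, ]), FUN = sum)
    wm <- agg$num / agg$den
    return(as.integer(agg$round[which.min(wm)]))
  }
  cohorts <- unique(log$cohort)
  out <- vapply(cohorts, function(ch) {
    sub <- log[log$cohort == ch & !is.na(log$val_mae), ]
    as.integer(sub$round[which.min(sub$val_mae)])
  }, integer(1))
  stats::setNames(out, cohorts)
}
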