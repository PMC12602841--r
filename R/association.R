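#' Covariate sets of the association ladder
#'
#' Six nested adjustment sets for the regression of a metabolomic score on
#' the brain-based age score: M1 none; M2 age; M3 sex, diabetes, lag time;
#' M4 = M3 + age; M5 = M3 + BMI and education dummies; M6 = M5 + age.
#' Education enters one-hot relative to the medium level (EC1 = low,
#' EC3 = high).
#'
#' @param set one of `"M1"`..`"M6"`.
#' @return Character vector of covariate names (possibly empty).
#' @export
association_covariates <- function(set) {
  sets <- list(
    M1 = character(0),
    M2 = "Age",
    M3 = c("Sex", "DM", "LagTime"),
    M4 = c("Age", "Sex", "DM", "LagTime"),
    M5 = c("Sex", "DM", "LagTime", "BMI", "EC1", "EC3"),
    M6 = c("Age", "Sex", "DM", "LagTime", "BMI", "EC1", "EC3"))
  if (!set %in% names(sets)) stop("unknown covariate set: ", set, call. = FALSE)
  sets[[set]]
}

#' Specify one federated association fit
#'
#' The association model regresses the metabolomic score on the brain-based
#' age score plus a covariate set, all variables standardized, fit by the
#' federated gradient-descent protocol: per round each cohort takes one
#' full-batch gradient-descent step on its standardized data and the server
#' n-weights the returned betas. Defaults follow the emulated analysis:
#' step size `eta = 0.1`, 10 random restarts with the lowest-MAE model kept,
#' iteration until the MAE change falls below `tol`.
#'
#' @param response `"metaboage"` or `"metabohealth"`.
#' @param covariate_set `"M1"`..`"M6"`.
#' @param eta gradient-descent step size (> 0).
#' @param max_rounds round cap.
#' @param tol absolute MAE-change stopping threshold.
#' @param restarts number of random initializations (>= 1).
#' @param seed integer seed for the restart initializations.
#' @return An object of class `association_spec`.
#' @export
association_spec <- function(response = c("metaboage", "metabohealth"),
                             covariate_set = "M2",
                             eta = 0.1, max_rounds = 5000L, tol = 1e-8,
                             restarts = 10L, seed = 1L) {
  response <- match.arg(response)
  check_scalar_number(eta, "eta", lower = 1e-12)
  if (restarts < 1) stop("`restarts` must be >= 1", call. = FALSE)
  association_covariates(covariate_set)  # validates
  structure(list(response = response, covariate_set = covariate_set,
                 eta = eta, max_rounds = as.integer(max_rounds), tol = tol,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "association_spec")
}

# Analysis-variable accessor: maps model-term names to table columns.
assoc_variable <- function(table, name) {
  switch(name,
    BrainAge = table$brainage,
    MetaboAge = table$metaboage,
    MetaboHealth = table$metabohealth,
    Age = table$age,
    Sex = table$sex,
    DM = table$dm,
    LagTime = table$lag_time,
    BMI = table$bmi,
    EC1 = as.numeric(table$ec == "low"),
    EC3 = as.numeric(table$ec == "high"),
    stop("unknown analysis variable: ", name, call. = FALSE))
}

response_term <- function(response) {
  c(metaboage = "MetaboAge", metabohealth = "MetaboHealth")[[response]]
}

#' Federated standardization statistics
#'
#' Pooled mean and SD per variable from per-cohort sufficient statistics
#' (sum, sum of squares, count) — exactly equal to computing them on the
#' concatenated table, without pooling rows. SD uses the n-1 denominator.
#'
#' @param tables list of participant tables.
#' @param variables character vector of analysis-variable names (see
#'   [association_covariates()]; also `"BrainAge"`, `"MetaboAge"`,
#'   `"MetaboHealth"`).
#' @return An object of class `standardization_stats`: tibble with
#'   variable, mean, sd, n.
#' @export
federated_standardize <- function(tables, variables) {
  rows <- lapply(variables, function(v) {
    s <- 0; ss <- 0; n <- 0
    for (tab in tables) {
      x <- assoc_variable(tab, v)
      if (anyNA(x)) stop("missing values in variable ", v, call. = FALSE)
      s <- s + sum(x); ss <- ss + sum(x^2); n <- n + length(x)
    }
    m <- s / n
    var_ <- (ss - n * m^2) / (n - 1)
    sd_ <- sqrt(max(var_, 0))
    if (sd_ < 1e-12) stop("zero pooled variance for variable ", v, call. = FALSE)
    tibble::tibble(variable = v, mean = m, sd = sd_, n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("standardization_stats", class(out))
  out
}

std_lookup <- function(stats, v) {
  i <- match(v, stats$variable)
  if (is.na(i)) stop("no standardization stats for variable ", v, call. = FALSE)
  list(mean = stats$mean[i], sd = stats$sd[i])
}

# Standardized design matrix and response for one cohort.
# Columns: (Intercept), BrainAge, covariates. After standardization the true
# intercept is 0; it is kept in the design as a self-check.
assoc_design <- function(table, response, covariate_set, stats) {
  terms <- c("BrainAge", association_covariates(covariate_set))
  X <- cbind(`(Intercept)` = rep(1, nrow(table)))
  for (v in terms) {
    st <- std_lookup(stats, v)
    X <- cbind(X, (assoc_variable(table, v) - st$mean) / st$sd)
  }
  colnames(X) <- c("(Intercept)", terms)
  rv <- response_term(response)
  st <- std_lookup(stats, rv)
  y <- (assoc_variable(table, rv) - st$mean) / st$sd
  list(X = X, y = y)
}

assoc_stats_for <- function(tables, response, covariate_set) {
  federated_standardize(tables, unique(c(response_term(response), "BrainAge",
                                         association_covariates(covariate_set))))
}

new_association_result <- function(betas, ses, pvalues, mae, rounds_used,
                                   restart_index, n, df) {
  structure(list(betas = betas, ses = ses, pvalues = pvalues, mae = mae,
                 rounds_used = rounds_used, restart_index = restart_index,
                 n = n, df = df),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result: n = %d, MAE = %.4f, rounds = %s>\n",
              x$n, x$mae, x$rounds_used %||% "closed-form"))
  print(tibble::tibble(term = names(x$betas), beta = x$betas,
                       se = x$ses, p = x$pvalues))
  invisible(x)
}

# Pooled sufficient statistics XtX, Xty, yty, n over cohorts.
pooled_suffstats <- function(designs) {
  XtX <- 0; Xty <- 0; yty <- 0; n <- 0
  for (d in designs) {
    XtX <- XtX + crossprod(d$X)
    Xty <- Xty + crossprod(d$X, d$y)
    yty <- yty + sum(d$y^2)
    n <- n + length(d$y)
  }
  list(XtX = XtX, Xty = Xty, yty = yty, n = n)
}

assoc_se_p <- function(beta, ss) {
  k <- length(beta)
  rss <- max(ss$yty - 2 * sum(beta * ss$Xty) + drop(t(beta) %*% ss$XtX %*% beta), 0)
  df <- ss$n - k
  sigma2 <- if (df > 0) rss / df else 0
  XtXinv <- solve(ss$XtX)
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  p <- ifelse(se > 0, 2 * stats::pt(abs(beta / se), df = max(df, 1), lower.tail = FALSE),
              ifelse(beta == 0, 1, 0))
  list(se = se, p = p, df = df, degenerate = sigma2 == 0)
}

#' Federated linear regression of the association model
#'
#' Fits the standardized association regression by the federated protocol:
#' each round every cohort computes one full-batch gradient-descent update
#' `beta_l = beta_g - eta * grad MSE` on its own standardized data (gradient
#' convention `(2/n) X'(X beta - y)`), and the server replaces `beta_g` by
#' the sample-size-weighted average of the returned `beta_l`. Rounds
#' continue until the pooled MAE changes by less than `spec$tol` or
#' `spec$max_rounds` is reached; the whole process is repeated over
#' `spec$restarts` random initializations (standard-normal scaled by 0.01)
#' and the lowest-MAE model is kept.
#'
#' Standard errors and p-values come from the closed-form
#' sufficient-statistic path evaluated at the reported betas (residual
#' variance with the n - k denominator, t-distribution p-values).
#'
#' @param tables list of participant tables (one per cohort) carrying
#'   `brainage` and the response score column.
#' @param spec an [association_spec()].
#' @param stats optional [federated_standardize()] result; computed from
#'   `tables` when `NULL`.
#' @return An `association_result`.
#' @export
federated_linreg <- function(tables, spec, stats = NULL) {
  if (is.null(stats)) stats <- assoc_stats_for(tables, spec$response, spec$covariate_set)
  designs <- lapply(tables, assoc_design, response = spec$response,
                    covariate_set = spec$covariate_set, stats = stats)
  ns <- vapply(designs, function(d) length(d$y), numeric(1))
  N <- sum(ns)
  k <- ncol(designs[[1]]$X)
  # per-cohort sufficient statistics make the full-batch gradient exact and cheap
  cstats <- lapply(designs, function(d) list(XtX = crossprod(d$X),
                                             Xty = drop(crossprod(d$X, d$y))))
  pooled_mae <- function(beta) {
    s <- 0
    for (d in designs) s <- s + sum(abs(d$y - drop(d$X %*% beta)))
    s / N
  }
  best <- NULL
  for (r in seq_len(spec$restarts)) {
    beta <- with_seed(derive_seed(spec$seed, "restart", r), 0.01 * stats::rnorm(k))
    prev_mae <- Inf
    rounds <- 0L
    for (t in seq_len(spec$max_rounds)) {
      # Eq.-style round: local step per cohort, then n-weighted server average
      upd <- 0
      for (j in seq_along(designs)) {
        g <- (2 / ns[j]) * (cstats[[j]]$XtX %*% beta - cstats[[j]]$Xty)
        upd <- upd + ns[j] * (beta - spec$eta * drop(g))
      }
      beta <- upd / N
      if (any(!is.finite(beta))) {
        stop("federated regression diverged; try a smaller eta", call. = FALSE)
      }
      m <- pooled_mae(beta)
      rounds <- t
      if (abs(prev_mae - m) < spec$tol) break
      prev_mae <- m
    }
    m <- pooled_mae(beta)
    if (is.null(best) || m < best$mae) {
      best <- list(beta = beta, mae = m, rounds = rounds, restart = r)
    }
  }
  ss <- pooled_suffstats(designs)
  beta <- stats::setNames(drop(best$beta), colnames(designs[[1]]$X))
  sp <- assoc_se_p(beta, ss)
  new_association_result(beta, stats::setNames(sp$se, names(beta)),
                         stats::setNames(sp$p, names(beta)),
                         mae = best$mae, rounds_used = best$rounds,
                         restart_index = best$restart, n = as.integer(N),
                         df = sp$df)
}

#' Closed-form pooled OLS from per-cohort sufficient statistics
#'
#' The meta-analytical oracle for the federated fit: betas
#' `(X'X)^-1 X'y` from per-cohort aggregated `X'X` and `X'y`, identical to
#' OLS on the concatenated table; SEs from `sigma^2 (X'X)^-1` with pooled
#' residual variance and t-distribution p-values. A zero-residual fit
#' yields SEs of 0 and is flagged with attribute `degenerate`.
#'
#' @inheritParams federated_linreg
#' @return An `association_result`.
#' @export
closed_form_pooled_ols <- function(tables, spec, stats = NULL) {
  if (is.null(stats)) stats <- assoc_stats_for(tables, spec$response, spec$covariate_set)
  designs <- lapply(tables, assoc_design, response = spec$response,
                    covariate_set = spec$covariate_set, stats = stats)
  ss <- pooled_suffstats(designs)
  qr_ <- qr(ss$XtX)
  if (qr_$rank < ncol(ss$XtX)) {
    bad <- colnames(designs[[1]]$X)[-seq_len(qr_$rank)]
    stop("singular pooled X'X; collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- drop(solve(ss$XtX, ss$Xty))
  names(beta) <- colnames(designs[[1]]$X)
  sp <- assoc_se_p(beta, ss)
  m <- 0
  for (d in designs) m <- m + sum(abs(d$y - drop(d$X %*% beta)))
  res <- new_association_result(beta, stats::setNames(sp$se, names(beta)),
                                stats::setNames(sp$p, names(beta)),
                                mae = m / ss$n, rounds_used = NULL,
                                restart_index = NULL, n = as.integer(ss$n),
                                df = sp$df)
  attr(res, "degenerate") <- sp$degenerate
  res
}

#' Run the six-model covariate ladder
#'
#' Fits the association regression under all six covariate sets M1..M6 for
#' one response, mirroring the standard report layout (one row per model,
#' one beta column per term, MAE last).
#'
#' @param tables list of scored participant tables.
#' @param response `"metaboage"` or `"metabohealth"`.
#' @param method `"federated"` (gradient-descent protocol) or
#'   `"closed_form"` (pooled OLS).
#' @param eta,max_rounds,tol,restarts,seed passed to [association_spec()].
#' @return Tidy tibble: model_id, term, beta, se, p, mae, n.
#' @export
run_covariate_ladder <- function(tables, response = "metaboage",
                                 method = c("federated", "closed_form"),
                                 eta = 0.1, max_rounds = 5000L, tol = 1e-9,
                                 restarts = 10L, seed = 1L) {
  method <- match.arg(method)
  rows <- lapply(paste0("M", 1:6), function(set) {
    spec <- association_spec(response, set, eta = eta, max_rounds = max_rounds,
                             tol = tol, restarts = restarts, seed = seed)
    fit <- if (method == "federated") federated_linreg(tables, spec)
           else closed_form_pooled_ols(tables, spec)
    tibble::tibble(model_id = set, term = names(fit$betas), beta = fit$betas,
                   se = fit$ses, p = fit$pvalues, mae = fit$mae, n = fit$n)
  })
  do.call(rbind, rows)
}

#' Format a covariate ladder in report layout
#'
#' One row per model M1..M6, one column per term carrying the beta with a
#' significance marker (`*` for p <= 0.05, `**` for p <= 5e-10, `=`
#' otherwise), and the MAE last. The intercept column is dropped (its true
#' value after standardization is 0).
#'
#' @param ladder output of [run_covariate_ladder()].
#' @param digits rounding for display.
#' @return A tibble in wide layout.
#' @export
format_association_table <- function(ladder, digits = 2) {
  mark <- function(p) ifelse(p <= 5e-10, "**", ifelse(p <= 0.05, "*", "="))
  terms <- c("BrainAge", "Age", "Sex", "DM", "LagTime", "BMI", "EC1", "EC3")
  rows <- lapply(unique(ladder$model_id), function(mid) {
    sub <- ladder[ladder$model_id == mid, ]
    vals <- stats::setNames(rep("-", length(terms)), terms)
    for (i in seq_len(nrow(sub))) {
      tm <- sub$term[i]
      if (tm %in% terms) {
        vals[tm] <- sprintf(paste0("%.", digits, "f%s"), sub$beta[i], mark(sub$p[i]))
      }
    }
    tibble::as_tibble(c(list(model_id = mid), as.list(vals),
                        list(mae = round(sub$mae[1], digits))))
  })
  do.call(rbind, rows)
}
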