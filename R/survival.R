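#' Biological age gaps
#'
#' Adds the brain-age gap (`bag = brainage - age`) and metabolomic-age gap
#' (`mag = metaboage - age`) columns, computed from the uncorrected scores
#' (the survival models adjust for age explicitly instead).
#'
#' @param table participant table with `brainage` and `metaboage` columns.
#' @return The table with `bag` and `mag` appended.
#' @export
compute_gaps <- function(table) {
  for (col in c("brainage", "metaboage")) {
    if (!col %in% names(table)) stop("missing score column: ", col, call. = FALSE)
  }
  table$bag <- table$brainage - table$age
  table$mag <- table$metaboage - table$age
  table
}

# ---- Cox partial likelihood (Breslow ties) ---------------------------------

# Sufficient quantities at beta: log partial likelihood, score vector and
# observed information, computed with reverse cumulative sums over the
# descending-time ordering. Risk set of an event at t is {j : t_j >= t}.
cox_quantities <- function(beta, time, event, X) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]; ev <- event[ord]; Xs <- X[ord, , drop = FALSE]
  k <- ncol(X)
  lp <- drop(Xs %*% beta)
  lp_c <- lp - max(lp)  # overflow guard; constants cancel in all ratios
  ex <- exp(lp_c)
  cum0 <- cumsum(ex)
  cum1 <- apply(Xs * ex, 2, cumsum)
  cum1 <- matrix(cum1, nrow = length(ts), ncol = k)
  cum2 <- array(0, c(length(ts), k, k))
  for (a in seq_len(k)) for (b in a:k) {
    cs <- cumsum(Xs[, a] * Xs[, b] * ex)
    cum2[, a, b] <- cs; cum2[, b, a] <- cs
  }
  ei <- which(ev == 1)
  m <- findInterval(-ts[ei], sort(-ts))  # size of each event's risk set
  s0 <- cum0[m]
  s1 <- cum1[m, , drop = FALSE]
  loglik <- sum(lp_c[ei] - log(s0))
  score <- colSums(Xs[ei, , drop = FALSE]) - colSums(s1 / s0)
  info <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    v <- sum(cum2[m, a, b] / s0 - (s1[, a] / s0) * (s1[, b] / s0))
    info[a, b] <- v; info[b, a] <- v
  }
  list(loglik = loglik, score = score, info = info)
}

# Newton-Raphson with step halving on the Breslow partial likelihood.
cox_newton <- function(time, event, X, tol = 1e-10, max_iter = 100L) {
  beta <- numeric(ncol(X))
  q <- cox_quantities(beta, time, event, X)
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(q$score^2))
    if (gnorm < tol) {
      return(list(beta = beta, info = q$info, loglik = q$loglik,
                  score_norm = gnorm, iter = it - 1L))
    }
    step <- tryCatch(solve(q$info, q$score),
                     error = function(e) stop("singular information matrix in Cox fit",
                                              call. = FALSE))
    h <- 1
    repeat {
      cand <- beta + h * step
      qc <- cox_quantities(cand, time, event, X)
      if (is.finite(qc$loglik) && qc$loglik >= q$loglik - 1e-12) break
      h <- h / 2
      if (h < 1e-10) stop(sprintf(
        "Cox fit failed to improve; last gradient norm %.3e", gnorm), call. = FALSE)
    }
    beta <- cand; q <- qc
  }
  gnorm <- sqrt(sum(q$score^2))
  if (gnorm >= tol) {
    stop(sprintf("Cox fit did not converge in %d iterations; last gradient norm %.3e",
                 max_iter, gnorm), call. = FALSE)
  }
  list(beta = beta, info = q$info, loglik = q$loglik, score_norm = gnorm,
       iter = max_iter)
}

# Breslow step-function baseline cumulative hazard at beta.
cox_basehaz <- function(beta, time, event, X) {
  lp <- drop(X %*% beta)
  ex <- exp(lp)
  etimes <- sort(unique(time[event == 1]))
  jumps <- vapply(etimes, function(t) {
    sum(time[event == 1] == t) / sum(ex[time >= t])
  }, numeric(1))
  tibble::tibble(time = etimes, hazard = cumsum(jumps))
}

cox_covariate_names <- function(covariate_set) {
  switch(covariate_set,
    none = character(0),
    age_only = "Age",
    full = c("Age", "Sex", "DM", "LagTime", "BMI", "EC1", "EC3"),
    stop("unknown covariate set: ", covariate_set, call. = FALSE))
}

cox_column <- function(table, term) {
  if (term %in% c("bag", "mag", "metabohealth")) {
    col <- table[[term]]
    if (is.null(col)) stop("missing score column: ", term, call. = FALSE)
    return(col)
  }
  assoc_variable(table, term)
}

#' Fit a Cox proportional-hazards model on gap scores
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson (convergence:
#' score norm below `1e-10`), with standard errors from the inverse observed
#' information and the Breslow step-function baseline cumulative hazard.
#' Hazard terms are the requested gap scores (per year for `bag`/`mag`, per
#' SD for `metabohealth`) plus a covariate set: `"none"`, `"age_only"`
#' (age), or `"full"` (age, sex, diabetes, lag time, BMI, education
#' dummies). Covariates that are constant in the data (for example lag time
#' in an all-zero-lag cohort) are dropped with a message.
#'
#' @param table participant table with gap scores ([compute_gaps()]) and
#'   outcome columns.
#' @param outcome `"mortality"` or `"dementia"`.
#' @param terms character vector of score terms, e.g. `c("bag", "mag")`.
#' @param covariate_set `"none"`, `"age_only"` or `"full"`.
#' @return An object of class `cox_fit`: coefficients, ses, pvalues (Wald),
#'   hazard ratios, baseline cumulative hazard, event counts, the reference
#'   covariate values used for profile curves (continuous at the mean,
#'   categorical at the mode), and fit diagnostics.
#' @export
fit_cox <- function(table, outcome = c("mortality", "dementia"),
                    terms = c("bag", "mag"),
                    covariate_set = c("full", "age_only", "none")) {
  outcome <- match.arg(outcome)
  covariate_set <- match.arg(covariate_set)
  tcol <- if (outcome == "mortality") "time_mort" else "time_dem"
  ecol <- if (outcome == "mortality") "event_mort" else "event_dem"
  if (!all(c(tcol, ecol) %in% names(table))) {
    stop("outcome columns missing for ", outcome, call. = FALSE)
  }
  time <- table[[tcol]]; event <- table[[ecol]]
  if (any(time <= 0)) stop("all survival times must be > 0", call. = FALSE)
  if (sum(event) < 1) stop("no events for outcome ", outcome, call. = FALSE)
  covs <- cox_covariate_names(covariate_set)
  all_terms <- c(terms, covs)
  X <- vapply(all_terms, function(tm) cox_column(table, tm), numeric(nrow(table)))
  X <- matrix(X, nrow(table), length(all_terms), dimnames = list(NULL, all_terms))
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    message("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    all_terms <- colnames(X)
  }
  fit <- cox_newton(time, event, X)
  se <- sqrt(diag(solve(fit$info)))
  beta <- stats::setNames(fit$beta, all_terms)
  se <- stats::setNames(se, all_terms)
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  reference <- vapply(all_terms, function(tm) {
    x <- X[, tm]
    if (tm %in% c("Sex", "DM", "EC1", "EC3")) as.numeric(stat_mode(x)) else mean(x)
  }, numeric(1))
  structure(list(
    coefficients = beta, ses = se, pvalues = p, hr = exp(beta),
    basehaz = cox_basehaz(fit$beta, time, event, X),
    n = nrow(table), events = as.integer(sum(event)),
    terms = intersect(terms, all_terms), covariate_set = covariate_set,
    outcome = outcome, reference = reference,
    loglik = fit$loglik, score_norm = fit$score_norm, iterations = fit$iter
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit: %s, %d/%d events, covariates: %s>\n",
              x$outcome, x$events, x$n, x$covariate_set))
  print(tibble::tibble(term = names(x$coefficients), beta = x$coefficients,
                       hr = x$hr, se = x$ses, p = x$pvalues))
  invisible(x)
}

#' Quartile-combination covariate profile
#'
#' Builds the covariate vector for one of the four profiles obtained by
#' crossing the 1st and 3rd empirical quartiles of the two gap scores
#' (linear-interpolation sample quantiles, `stats::quantile` type 7 by
#' default). Non-score covariates are fixed at the fit's reference values
#' (continuous at the mean, categorical at the mode).
#'
#' @param fit a [fit_cox()] result with exactly two score terms.
#' @param table the analysis table the quartiles are computed on.
#' @param level1,level2 `"Q1"` or `"Q3"` for the first and second score term.
#' @param qtype sample-quantile convention passed to [stats::quantile()].
#' @return An object of class `quartile_profile` with the named covariate
#'   values and the level labels.
#' @export
quartile_profile <- function(fit, table, level1 = c("Q1", "Q3"),
                             level2 = c("Q1", "Q3"), qtype = 7) {
  level1 <- match.arg(level1); level2 <- match.arg(level2)
  if (length(fit$terms) != 2) stop("profiles need a pairwise fit (two score terms)",
                                   call. = FALSE)
  vals <- fit$reference
  for (i in 1:2) {
    tm <- fit$terms[i]
    lev <- c(level1, level2)[i]
    x <- cox_column(table, tm)
    qq <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = qtype)
    if (qq[1] >= qq[2]) stop("degenerate quartiles for ", tm, call. = FALSE)
    vals[tm] <- if (lev == "Q1") qq[1] else qq[2]
  }
  structure(list(values = vals, levels = stats::setNames(c(level1, level2), fit$terms)),
            class = "quartile_profile")
}

#' Predicted survival curve at a covariate profile
#'
#' `S(t) = exp(-Lambda0(t) * exp(beta' x_profile))` over the fit's event
#' times, prepended with `S(0) = 1`. Non-increasing by construction.
#'
#' @param fit a [fit_cox()] result.
#' @param profile a [quartile_profile()] (or any list with a `values` vector
#'   named like the fit's coefficients).
#' @return Tibble with `time` and `surv`.
#' @export
predicted_survival <- function(fit, profile) {
  vals <- profile$values
  if (!setequal(names(vals), names(fit$coefficients))) {
    stop("profile covariates do not match the fitted model", call. = FALSE)
  }
  lp <- sum(fit$coefficients * vals[names(fit$coefficients)])
  tibble::tibble(time = c(0, fit$basehaz$time),
                 surv = exp(-c(0, fit$basehaz$hazard) * exp(lp)))
}

#' Run the full survival-profiling suite
#'
#' For each outcome and each score pair, fits the separate (one score at a
#' time) and pairwise Cox models under the requested covariate sets, and for
#' every pairwise fit emits the four quartile-combination survival curves.
#' Outcomes whose columns are absent or event-free are skipped with a
#' warning (some cohorts carry no long-term follow-up).
#'
#' @param table analysis table with gaps and outcome columns.
#' @param outcomes subset of `c("mortality", "dementia")`.
#' @param score_pairs list of length-2 character vectors.
#' @param covariate_sets subset of `c("age_only", "full")`.
#' @return List of class `survival_suite`: `coefficients` (term-level tidy
#'   tibble with betas, HRs, SEs, p-values, n, events) and `curves`
#'   (per-profile survival curves for the pairwise fits).
#' @export
run_survival_suite <- function(table,
                               outcomes = c("mortality", "dementia"),
                               score_pairs = list(c("bag", "mag"),
                                                  c("bag", "metabohealth")),
                               covariate_sets = c("age_only", "full")) {
  coef_rows <- list(); curve_rows <- list()
  for (oc in outcomes) {
    tcol <- if (oc == "mortality") "time_mort" else "time_dem"
    ecol <- if (oc == "mortality") "event_mort" else "event_dem"
    if (!all(c(tcol, ecol) %in% names(table)) || sum(table[[ecol]]) < 1) {
      warning("skipping outcome '", oc, "': no data or no events", call. = FALSE)
      next
    }
    for (pair in score_pairs) {
      for (cs in covariate_sets) {
        fits <- c(lapply(pair, function(tm) fit_cox(table, oc, tm, cs)),
                  list(fit_cox(table, oc, pair, cs)))
        types <- c(paste0("separate_", pair), "pairwise")
        for (i in seq_along(fits)) {
          f <- fits[[i]]
          coef_rows[[length(coef_rows) + 1L]] <- tibble::tibble(
            outcome = oc, scores = paste(pair, collapse = "+"),
            model_type = types[i], covariate_set = cs,
            term = names(f$coefficients), beta = f$coefficients,
            hr = f$hr, se = f$ses, p = f$pvalues, n = f$n, events = f$events)
        }
        pw <- fits[[length(fits)]]
        for (l1 in c("Q1", "Q3")) for (l2 in c("Q1", "Q3")) {
          prof <- quartile_profile(pw, table, l1, l2)
          sc <- predicted_survival(pw, prof)
          curve_rows[[length(curve_rows) + 1L]] <- tibble::tibble(
            outcome = oc, scores = paste(pair, collapse = "+"),
            covariate_set = cs,
            profile = sprintf("%s_%s/%s_%s", pair[1], l1, pair[2], l2),
            time = sc$time, surv = sc$surv)
        }
      }
    }
  }
  structure(list(coefficients = if (length(coef_rows)) do.call(rbind, coef_rows) else NULL,
                 curves = if (length(curve_rows)) do.call(rbind, curve_rows) else NULL),
            class = "survival_suite")
}
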