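#' Fit a linear age-bias correction
#'
#' Age predictors systematically overestimate the age of younger and
#' underestimate the age of older participants. The correction regresses
#' predicted age on chronological age over a training source,
#' `pred = a * age + b`, and later removes the fitted bias. Models are fit
#' per training source (each local cohort and the federated model) and
#' should only ever be fit on training-set predictions.
#'
#' @param pred,age equal-length numeric vectors (years), `n >= 2`; `age`
#'   must not be constant.
#' @param source label recording what the model was fit on.
#' @return An object of class `bias_correction` with slope `a`, intercept
#'   `b`, `fit_source` and `fit_n`.
#' @export
fit_bias_correction <- function(pred, age, source = "unspecified") {
  if (length(pred) != length(age)) stop("`pred` and `age` differ in length", call. = FALSE)
  if (length(age) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::var(age) == 0) stop("`age` is constant; slope undefined", call. = FALSE)
  a <- stats::cov(pred, age) / stats::var(age)
  b <- mean(pred) - a * mean(age)
  if (!is.finite(a) || !is.finite(b)) stop("non-finite bias-correction fit", call. = FALSE)
  structure(list(a = a, b = b, fit_source = source, fit_n = length(age)),
            class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf("<bias_correction: pred = %.4f * age + %.4f  (source: %s, n = %d)>\n",
              x$a, x$b, x$fit_source, x$fit_n))
  invisible(x)
}

#' Apply an age-bias correction
#'
#' Default is the additive residual-offset variant,
#' `corrected = pred + (age - (a * age + b))`: on the fit set the corrected
#' gap equals the regression residual and is exactly uncorrelated with age.
#' The rescaling variant `(pred - b) / a` is available for comparison but is
#' undefined at `a = 0`.
#'
#' @param model a [fit_bias_correction()] result.
#' @param pred,age numeric vectors (years).
#' @param variant `"additive"` (default) or `"rescale"`.
#' @return Corrected predicted ages (years).
#' @export
apply_correction <- function(model, pred, age, variant = c("additive", "rescale")) {
  variant <- match.arg(variant)
  if (!inherits(model, "bias_correction")) stop("`model` must be a bias_correction", call. = FALSE)
  if (variant == "additive") {
    pred + (age - (model$a * age + model$b))
  } else {
    if (model$a == 0) stop("rescale variant undefined for slope 0", call. = FALSE)
    (pred - model$b) / model$a
  }
}

#' Before/after MAE report for a bias correction
#'
#' Applies one correction model to several cohorts and reports each cohort's
#' MAE before and after correction. A correction fit on one source need not
#' help elsewhere; this harness makes that visible.
#'
#' @param model a [fit_bias_correction()] result.
#' @param predictions named list; each element a list with numeric `pred`
#'   and `age`.
#' @param variant passed to [apply_correction()].
#' @return Tibble with cohort, n, mae_before, mae_after.
#' @export
correction_report <- function(model, predictions, variant = "additive") {
  rows <- lapply(names(predictions), function(nm) {
    pr <- predictions[[nm]]
    tibble::tibble(
      cohort = nm, source = model$fit_source, n = length(pr$age),
      mae_before = mae(pr$pred, pr$age),
      mae_after = mae(apply_correction(model, pr$pred, pr$age, variant), pr$age))
  })
  do.call(rbind, rows)
}
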