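#' Fixed coefficients of a metabolomic scorer
#'
#' Container for the linear scorers applied to the 56-metabolite panel: a
#' metabolomic age score (output in years; 56 weights) or a metabolomic
#' mortality score (z-standardized linear predictor; 14 weights).
#'
#' @param intercept scalar intercept (years, or linear-predictor units).
#' @param weights named numeric vector; names must match metabolite columns.
#' @param output_kind `"age_years"` or `"mortality_score"`.
#' @return An object of class `scorer_coefficients`.
#' @export
scorer_coefficients <- function(intercept, weights,
                                output_kind = c("age_years", "mortality_score")) {
  output_kind <- match.arg(output_kind)
  check_scalar_number(intercept, "intercept")
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("`weights` must be fully named", call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("weights must be finite", call. = FALSE)
  structure(list(intercept = intercept, weights = weights,
                 output_kind = output_kind),
            class = "scorer_coefficients")
}

#' Apply a fixed-coefficient metabolite scorer
#'
#' Computes `intercept + sum(weight * metabolite)` per participant. Age
#' scorers return years; mortality scorers return the linear predictor
#' z-standardized over the scored table (a scale convention for
#' comparability with the age scores, not a claim about the original scale).
#'
#' @param coeffs a [scorer_coefficients()].
#' @param table participant table whose `metabolites` matrix covers all
#'   named weights.
#' @return Numeric score per row.
#' @export
score_metabolite_model <- function(coeffs, table) {
  M <- table$metabolites
  if (is.null(M)) stop("`metabolites` column missing", call. = FALSE)
  missing <- setdiff(names(coeffs$weights), colnames(M))
  if (length(missing)) {
    stop("missing metabolite column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  score <- coeffs$intercept + drop(M[, names(coeffs$weights), drop = FALSE] %*% coeffs$weights)
  if (coeffs$output_kind == "mortality_score") {
    s <- stats::sd(score)
    if (s == 0) stop("degenerate mortality score: zero variance", call. = FALSE)
    score <- (score - mean(score)) / s
  }
  score
}

#' Synthetic metabolomic age scorer matched to the generator
#'
#' The published 56-metabolite age model's coefficients are not public, so
#' the package derives a synthetic stand-in from the generator's own
#' metabolite loadings: the minimum-norm inverse `w / sum(w^2)`, which on
#' noise-free synthetic data returns exactly `age + metab_gap`.
#'
#' @param truth a [generator_truth()].
#' @return A [scorer_coefficients()] with `output_kind = "age_years"`.
#' @export
synthetic_metaboage_scorer <- function(truth) {
  w <- truth$w_metab
  weights <- w / sum(w^2)
  names(weights) <- sprintf("met_%02d", seq_along(w))
  scorer_coefficients(0, weights, "age_years")
}

#' Synthetic metabolomic mortality scorer (14-metabolite panel)
#'
#' Stand-in for the published 14-metabolite mortality score: the 14
#' metabolites with the largest absolute generator loadings, combined by the
#' restricted minimum-norm inverse so the raw score tracks
#' `age + metab_gap`; [score_metabolite_model()] z-standardizes it.
#'
#' @param truth a [generator_truth()].
#' @param n_panel panel size (default 14).
#' @return A [scorer_coefficients()] with `output_kind = "mortality_score"`.
#' @export
synthetic_metabohealth_scorer <- function(truth, n_panel = 14L) {
  w <- truth$w_metab
  sel <- order(abs(w), decreasing = TRUE)[seq_len(n_panel)]
  sel <- sort(sel)
  weights <- w[sel] / sum(w[sel]^2)
  names(weights) <- sprintf("met_%02d", sel)
  scorer_coefficients(0, weights, "mortality_score")
}

#' Attach all three biological-age scores to a table
#'
#' Adds `brainage` (trained predictor, uncorrected), `metaboage` and
#' `metabohealth` columns. Scores are left uncorrected for age bias here;
#' the association and survival analyses adjust for age explicitly.
#'
#' @param table participant table.
#' @param params trained predictor [param_vector()].
#' @param config the predictor's [predictor_config()].
#' @param metaboage_coeffs,metabohealth_coeffs [scorer_coefficients()].
#' @return The table with score columns appended.
#' @export
score_participants <- function(table, params, config,
                               metaboage_coeffs, metabohealth_coeffs) {
  table$brainage <- predict_age(params, table, config)
  table$metaboage <- score_metabolite_model(metaboage_coeffs, table)
  table$metabohealth <- score_metabolite_model(metabohealth_coeffs, table)
  table
}
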