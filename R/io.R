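# Delimited-text I/O. Doubles are serialized with "%.17g" so that tables
# round-trip bit-losslessly through write/read.

fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

flatten_participant_table <- function(table) {
  cols <- list()
  for (nm in names(table)) {
    col <- table[[nm]]
    if (is.matrix(col)) {
      m <- as.data.frame(col)
      names(m) <- colnames(col)
      cols <- c(cols, m)
    } else {
      cols[[nm]] <- col
    }
  }
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a participant table as CSV
#'
#' Matrix columns (`brain_features`, `metabolites`) are expanded into their
#' named component columns (`bf_*`, `met_*`) on write and reassembled on
#' read. Numeric values are written with 17 significant digits, so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table a participant table.
#' @param path CSV file path.
#' @return `write_participant_table()` returns `path` invisibly;
#'   `read_participant_table()` the restored tibble.
#' @export
write_participant_table <- function(table, path) {
  flat <- flatten_participant_table(table)
  for (nm in names(flat)) {
    if (is.double(flat[[nm]])) flat[[nm]] <- fmt_double(flat[[nm]])
  }
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_participant_table
#' @export
read_participant_table <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  bf <- grep("^bf_", names(flat), value = TRUE)
  met <- grep("^met_", names(flat), value = TRUE)
  plain <- setdiff(names(flat), c(bf, met))
  out <- tibble::as_tibble(flat[plain])
  if (length(bf)) {
    out$brain_features <- as.matrix(flat[bf])
  }
  if (length(met)) {
    out$metabolites <- as.matrix(flat[met])
  }
  # restore canonical column order where possible
  canon <- c("participant_id", "cohort", "age", "sex", "brain_features",
             "metabolites", "dm", "bmi", "ec", "lag_time", "has_blood",
             "time_mort", "event_mort", "time_dem", "event_dem",
             "true_brain_gap", "true_metab_gap")
  ord <- c(intersect(canon, names(out)), setdiff(names(out), canon))
  out <- out[ord]
  class(out) <- c("participant_table", class(out))
  out
}

#' Write / read fixed scorer coefficients
#'
#' Two-column delimited format: a `term,weight` header, one `(Intercept)`
#' row, then one row per metabolite weight.
#'
#' @param coeffs a [scorer_coefficients()] object.
#' @param path file path.
#' @param output_kind passed through on read (`"age_years"` or
#'   `"mortality_score"`).
#' @export
write_scorer <- function(coeffs, path) {
  df <- data.frame(term = c("(Intercept)", names(coeffs$weights)),
                   weight = fmt_double(c(coeffs$intercept, coeffs$weights)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path, output_kind = "age_years") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  i <- df$term == "(Intercept)"
  scorer_coefficients(intercept = as.numeric(df$weight[i]),
                      weights = stats::setNames(as.numeric(df$weight[!i]), df$term[!i]),
                      output_kind = output_kind)
}

#' Write a federation round log as CSV
#' @param log round-log tibble from [run_federated()].
#' @param path file path.
#' @export
write_round_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Persist / restore a bias-correction model
#'
#' Four-field delimited record: source, n, slope, intercept.
#' @param model a [fit_bias_correction()] result.
#' @param path file path.
#' @export
write_bias_correction <- function(model, path) {
  df <- data.frame(source = model$fit_source, n = model$fit_n,
                   a = fmt_double(model$a), b = fmt_double(model$b))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bias_correction
#' @export
read_bias_correction <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(a = as.numeric(df$a), b = as.numeric(df$b),
                 fit_source = df$source, fit_n = as.integer(df$n)),
            class = "bias_correction")
}
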