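#' Flat parameter vector with a named layout
#'
#' The unit of exchange between simulated clients and the server. All model
#' parameters (linear weights, network layers, regression betas) are stored
#' as one flat numeric vector together with a `layout`: a named list of
#' integer index vectors that must partition `seq_along(values)` exactly.
#' Aggregation and checkpointing operate on the flat vector; adapters use the
#' layout to address parameter groups.
#'
#' @param values numeric vector of finite parameter values.
#' @param layout named list of integer index vectors; the segments must
#'   partition `1:length(values)` with no gaps or overlaps.
#' @return An object of class `param_vector`.
#' @examples
#' pv <- param_vector(c(0.5, -1, 2), list(w = 1:2, b = 3L))
#' pv_segment(pv, "w")
#' @export
param_vector <- function(values, layout) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("param_vector values must be finite", call. = FALSE)
  if (is.null(names(layout)) || any(!nzchar(names(layout)))) {
    stop("layout must be a fully named list", call. = FALSE)
  }
  layout <- lapply(layout, as.integer)
  idx <- unlist(layout, use.names = FALSE)
  if (!identical(sort(idx), seq_along(values))) {
    stop("layout segments must partition the index range exactly", call. = FALSE)
  }
  structure(list(values = values, layout = layout), class = "param_vector")
}

#' @export
length.param_vector <- function(x) length(x$values)

#' @export
print.param_vector <- function(x, ...) {
  cat(sprintf("<param_vector: %d values, %d segments (%s)>\n",
              length(x$values), length(x$layout),
              paste(names(x$layout), collapse = ", ")))
  invisible(x)
}

#' Extract one named segment of a parameter vector
#' @param pv a [param_vector()].
#' @param name segment name present in the layout.
#' @return numeric vector of that segment's values.
#' @export
pv_segment <- function(pv, name) {
  if (!name %in% names(pv$layout)) {
    stop(sprintf("no segment named '%s' in layout", name), call. = FALSE)
  }
  pv$values[pv$layout[[name]]]
}

# Replace the flat values, keeping the layout.
pv_replace <- function(pv, values) {
  param_vector(values, pv$layout)
}

same_layout <- function(a, b) {
  identical(lapply(a$layout, as.integer), lapply(b$layout, as.integer)) &&
    identical(names(a$layout), names(b$layout))
}

#' Aggregate client parameter vectors on the simulated server
#'
#' Implements the server-side combination step of federated averaging. Under
#' `n_weighted` the aggregate is the sample-size-weighted mean
#' \eqn{\sum_j n_j \beta_j / \sum_j n_j}; under `equal` every client
#' contributes the same weight regardless of its size.
#'
#' @param params_list list of [param_vector()] objects with identical layouts.
#' @param sizes integer client sample sizes; required (and positive) when
#'   `scheme = "n_weighted"`.
#' @param scheme `"n_weighted"` or `"equal"`.
#' @return A [param_vector()] with the shared layout.
#' @examples
#' a <- param_vector(1, list(w = 1L)); b <- param_vector(3, list(w = 1L))
#' aggregate_params(list(a, b), sizes = c(1, 3))$values  # 2.5
#' aggregate_params(list(a, b), scheme = "equal")$values # 2
#' @export
aggregate_params <- function(params_list, sizes = NULL,
                             scheme = c("n_weighted", "equal")) {
  scheme <- match.arg(scheme)
  if (length(params_list) < 1) stop("need at least one parameter vector", call. = FALSE)
  ref <- params_list[[1]]
  for (p in params_list[-1]) {
    if (!same_layout(ref, p)) stop("parameter vector layouts do not match", call. = FALSE)
  }
  if (scheme == "n_weighted") {
    if (is.null(sizes) || length(sizes) != length(params_list) || any(sizes <= 0)) {
      stop("n_weighted aggregation needs one positive size per client", call. = FALSE)
    }
    w <- sizes / sum(sizes)
  } else {
    w <- rep(1 / length(params_list), length(params_list))
  }
  vals <- Reduce(`+`, Map(function(p, wi) p$values * wi, params_list, w))
  pv_replace(ref, vals)
}

#' Write / read a parameter checkpoint
#'
#' The flat values go to a raw little-endian double array (`<path>.bin`) and
#' the layout to a JSON sidecar (`<path>.json`), so a checkpoint is
#' self-describing.
#'
#' @param pv a [param_vector()].
#' @param path file stem; `.bin` and `.json` are appended.
#' @return `write_param_checkpoint()` returns `path` invisibly;
#'   `read_param_checkpoint()` returns the restored [param_vector()].
#' @export
write_param_checkpoint <- function(pv, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(pv$values, con, size = 8, endian = "little")
  jsonlite::write_json(pv$layout, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_param_checkpoint
#' @export
read_param_checkpoint <- function(path) {
  layout <- lapply(jsonlite::read_json(paste0(path, ".json")),
                   function(v) as.integer(unlist(v)))
  n <- length(unlist(layout))
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  values <- readBin(con, "double", n = n, size = 8, endian = "little")
  param_vector(values, layout)
}
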