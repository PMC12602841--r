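# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a character key.
# Keeps results reproducible per (seed, cohort, round, ...) without
# consuming the ambient RNG stream. Always < 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  if (nzchar(key)) {
    for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147480000
  }
  as.integer((as.numeric(seed) %% 2147480000 * 7919 + h + 1) %% 2147480000)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal draws by inverse-CDF; exact, vectorized, no rejection.
rtruncnorm <- function(n, mean, sd, low, high) {
  plo <- stats::pnorm(low, mean, sd)
  phi <- stats::pnorm(high, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

is_proportion <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

stat_mode <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
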