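#' Configure the trainable age predictor
#'
#' The predictor regresses chronological age on brain features, with the
#' participant's sex concatenated at the final dense layer. Three kinds are
#' available: `linear` (single dense layer on the feature vector), `mlp`
#' (fully connected ReLU hidden layers with dropout on the last hidden
#' layer), and `cnn3d_small` (one 3x3x3 convolution block with ReLU and
#' global mean pooling over the generator's volumetric mode, then the dense
#' output). All kinds train on the mean-squared-error loss.
#'
#' Default hyperparameters follow the tuned values of the study this package
#' emulates: initial learning rate 1e-3, per-epoch learning-rate decay
#' argument 1e-2 (lr_epoch = lr / (1 + decay * epoch)), dropout 0.5 in the
#' last layer, Adam optimization, Xavier (Glorot) uniform initialization.
#'
#' @param kind `"linear"`, `"mlp"` or `"cnn3d_small"`.
#' @param hidden_sizes integer vector of hidden-layer widths (mlp only).
#' @param dropout_last dropout probability on the last hidden layer during
#'   training, in `[0, 1)`; ignored by `linear`.
#' @param learning_rate initial per-step learning rate (> 0).
#' @param lr_decay per-epoch decay argument.
#' @param optimizer `"adam"` or `"sgd"` (plain gradient steps; used for the
#'   exact federated/centralized equivalence analyses).
#' @param sex_concat logical; append sex before the final dense layer.
#' @param n_filters convolution filters for `cnn3d_small`.
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(kind = c("linear", "mlp", "cnn3d_small"),
                             hidden_sizes = 16L,
                             dropout_last = 0.5,
                             learning_rate = 1e-3,
                             lr_decay = 1e-2,
                             optimizer = c("adam", "sgd"),
                             sex_concat = TRUE,
                             n_filters = 2L) {
  kind <- match.arg(kind)
  optimizer <- match.arg(optimizer)
  if (!is_proportion(dropout_last) || dropout_last >= 1) {
    stop("`dropout_last` must be in [0, 1)", call. = FALSE)
  }
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-300)
  check_scalar_number(lr_decay, "lr_decay", lower = 0)
  structure(list(kind = kind, hidden_sizes = as.integer(hidden_sizes),
                 dropout_last = dropout_last, learning_rate = learning_rate,
                 lr_decay = lr_decay, optimizer = optimizer,
                 sex_concat = isTRUE(sex_concat),
                 n_filters = as.integer(n_filters)),
            class = "predictor_config")
}

xavier_uniform <- function(fan_in, fan_out, n = fan_in * fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

relu <- function(x) pmax(x, 0)

raw_features <- function(table) {
  if (!"brain_features" %in% names(table)) stop("`brain_features` column missing", call. = FALSE)
  table$brain_features
}

#' Preprocessing statistics for predictor training
#'
#' Per-feature mean and SD plus the mean age of one or several training
#' sources, computed from per-cohort sufficient statistics (so the federated
#' model's preprocessing equals pooled-data preprocessing without pooling
#' rows). Predictors train on standardized features and a mean-centred age
#' target; the statistics travel with the trained parameters.
#'
#' @param tables a participant table or list of tables.
#' @return An object of class `preprocess_stats` with `center`, `scale`
#'   (per feature) and `age_center`.
#' @export
preprocess_stats <- function(tables) {
  if (!is.list(tables) || !is.null(tables$brain_features)) tables <- list(tables)
  s <- 0; ss <- 0; n <- 0; sage <- 0
  for (tab in tables) {
    X <- raw_features(tab)
    s <- s + colSums(X); ss <- ss + colSums(X^2)
    n <- n + nrow(X); sage <- sage + sum(tab$age)
  }
  center <- s / n
  sd_ <- sqrt(pmax((ss - n * center^2) / (n - 1), 0))
  sd_[sd_ < 1e-12] <- 1
  structure(list(center = center, scale = sd_, age_center = sage / n),
            class = "preprocess_stats")
}

neutral_preprocess <- function(p) {
  structure(list(center = rep(0, p), scale = rep(1, p), age_center = 0),
            class = "preprocess_stats")
}

make_layout <- function(sizes) {
  idx <- integer(0); layout <- list(); at <- 0L
  for (nm in names(sizes)) {
    layout[[nm]] <- seq.int(at + 1L, at + sizes[[nm]])
    at <- at + sizes[[nm]]
  }
  layout
}

# ---- linear adapter ---------------------------------------------------------

adapter_linear <- function(config, p, feats, tgt, offset) {
  sizes <- c(w = p, if (config$sex_concat) c(w_sex = 1L), b = 1L)
  layout <- make_layout(as.list(sizes))
  fwd <- function(pv, table) {
    X <- feats(table)
    out <- drop(X %*% pv_segment(pv, "w")) + pv_segment(pv, "b")
    if (config$sex_concat) out <- out + table$sex * pv_segment(pv, "w_sex")
    out
  }
  list(
    kind = "linear", config = config, p = p, layout = layout,
    init = function(seed) {
      with_seed(derive_seed(seed, "init", "linear"), {
        fan_in <- p + as.integer(config$sex_concat)
        vals <- numeric(sum(unlist(lapply(layout, length))))
        vals[layout$w] <- xavier_uniform(fan_in, 1, p)
        if (config$sex_concat) vals[layout$w_sex] <- xavier_uniform(fan_in, 1, 1)
        vals[layout$b] <- 0
        param_vector(vals, layout)
      })
    },
    predict = function(pv, table) fwd(pv, table) + offset,
    loss = function(pv, table) mean((fwd(pv, table) - tgt(table))^2),
    grad = function(pv, table, training = TRUE) {
      X <- feats(table)
      n <- nrow(X)
      r <- (2 / n) * (fwd(pv, table) - tgt(table))
      g <- numeric(length(pv))
      g[layout$w] <- drop(crossprod(X, r))
      if (config$sex_concat) g[layout$w_sex] <- sum(r * table$sex)
      g[layout$b] <- sum(r)
      g
    }
  )
}

# ---- mlp adapter ------------------------------------------------------------

adapter_mlp <- function(config, p, feats, tgt, offset) {
  hs <- config$hidden_sizes
  if (length(hs) < 1 || any(hs < 1)) stop("mlp needs at least one hidden layer", call. = FALSE)
  dims <- c(p, hs)
  sizes <- list()
  for (l in seq_along(hs)) {
    sizes[[paste0("W", l)]] <- dims[l] * dims[l + 1]
    sizes[[paste0("b", l)]] <- dims[l + 1]
  }
  sizes$w_out <- hs[length(hs)] + as.integer(config$sex_concat)
  sizes$b_out <- 1L
  layout <- make_layout(sizes)

  forward <- function(pv, table, training = FALSE) {
    H <- feats(table)
    Zs <- list(); Hs <- list(H)
    for (l in seq_along(hs)) {
      W <- matrix(pv_segment(pv, paste0("W", l)), dims[l], dims[l + 1])
      Z <- H %*% W + matrix(pv_segment(pv, paste0("b", l)), nrow(H), dims[l + 1], byrow = TRUE)
      H <- relu(Z)
      Zs[[l]] <- Z; Hs[[l + 1]] <- H
    }
    mask <- NULL
    if (training && config$dropout_last > 0) {
      keep <- 1 - config$dropout_last
      mask <- matrix(stats::rbinom(length(H), 1, keep) / keep, nrow(H), ncol(H))
      H <- H * mask
      Hs[[length(Hs)]] <- H
    }
    w_out <- pv_segment(pv, "w_out")
    k <- length(hs)
    yhat <- drop(H %*% w_out[seq_len(hs[k])]) + pv_segment(pv, "b_out")
    if (config$sex_concat) yhat <- yhat + table$sex * w_out[hs[k] + 1]
    list(yhat = yhat, Zs = Zs, Hs = Hs, mask = mask)
  }

  list(
    kind = "mlp", config = config, p = p, layout = layout,
    init = function(seed) {
      with_seed(derive_seed(seed, "init", "mlp"), {
        vals <- numeric(sum(lengths(layout)))
        for (l in seq_along(hs)) {
          vals[layout[[paste0("W", l)]]] <- xavier_uniform(dims[l], dims[l + 1])
          vals[layout[[paste0("b", l)]]] <- 0
        }
        fan_in <- hs[length(hs)] + as.integer(config$sex_concat)
        vals[layout$w_out] <- xavier_uniform(fan_in, 1, length(layout$w_out))
        vals[layout$b_out] <- 0
        param_vector(vals, layout)
      })
    },
    predict = function(pv, table) forward(pv, table, training = FALSE)$yhat + offset,
    loss = function(pv, table) mean((forward(pv, table, FALSE)$yhat - tgt(table))^2),
    grad = function(pv, table, training = TRUE) {
      fw <- forward(pv, table, training = training)
      n <- nrow(table)
      r <- (2 / n) * (fw$yhat - tgt(table))
      g <- numeric(length(pv))
      k <- length(hs)
      w_out <- pv_segment(pv, "w_out")
      Hlast <- fw$Hs[[k + 1]]
      g[layout$w_out] <- c(drop(crossprod(Hlast, r)),
                           if (config$sex_concat) sum(r * table$sex))
      g[layout$b_out] <- sum(r)
      dH <- outer(r, w_out[seq_len(hs[k])])
      if (!is.null(fw$mask)) dH <- dH * fw$mask
      for (l in rev(seq_len(k))) {
        dZ <- dH * (fw$Zs[[l]] > 0)
        g[layout[[paste0("W", l)]]] <- as.numeric(crossprod(fw$Hs[[l]], dZ))
        g[layout[[paste0("b", l)]]] <- colSums(dZ)
        if (l > 1) {
          W <- matrix(pv_segment(pv, paste0("W", l)), dims[l], dims[l + 1])
          dH <- dZ %*% t(W)
        }
      }
      g
    }
  )
}

# ---- small 3-D convolutional adapter ---------------------------------------

# Index map: rows = output voxels of the valid convolution, cols = the 27
# kernel taps, entries = flat input-voxel indices.
conv3d_index_map <- function(dim) {
  out_dim <- dim - 2L
  off <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
  pos <- as.matrix(expand.grid(x = seq_len(out_dim[1]), y = seq_len(out_dim[2]),
                               z = seq_len(out_dim[3])))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (k in seq_len(nrow(off))) {
    x <- pos[, 1] + off[k, 1]; y <- pos[, 2] + off[k, 2]; z <- pos[, 3] + off[k, 3]
    idx[, k] <- x + (y - 1L) * dim[1] + (z - 1L) * dim[1] * dim[2]
  }
  idx
}

adapter_cnn3d <- function(config, p, vol_dim, feats, tgt, offset) {
  if (length(vol_dim) != 3 || prod(vol_dim) != p) {
    stop("cnn3d_small requires volumetric features (prod(volume_dim) == p)", call. = FALSE)
  }
  Fk <- config$n_filters
  inmap <- conv3d_index_map(vol_dim)
  V <- nrow(inmap)
  sizes <- list(conv_w = 27L * Fk, conv_b = Fk,
                w_out = Fk + as.integer(config$sex_concat), b_out = 1L)
  layout <- make_layout(sizes)

  conv_forward <- function(pv, X) {
    W <- matrix(pv_segment(pv, "conv_w"), 27, Fk)
    bb <- pv_segment(pv, "conv_b")
    Z <- vector("list", Fk)
    for (f in seq_len(Fk)) {
      acc <- matrix(bb[f], nrow(X), V)
      for (k in 1:27) acc <- acc + X[, inmap[, k], drop = FALSE] * W[k, f]
      Z[[f]] <- acc
    }
    Z
  }

  forward <- function(pv, table) {
    X <- feats(table)
    Z <- conv_forward(pv, X)
    pooled <- vapply(Z, function(z) rowMeans(relu(z)), numeric(nrow(X)))
    pooled <- matrix(pooled, nrow(X), Fk)
    w_out <- pv_segment(pv, "w_out")
    yhat <- drop(pooled %*% w_out[seq_len(Fk)]) + pv_segment(pv, "b_out")
    if (config$sex_concat) yhat <- yhat + table$sex * w_out[Fk + 1]
    list(yhat = yhat, Z = Z, pooled = pooled, X = X)
  }

  list(
    kind = "cnn3d_small", config = config, p = p, layout = layout,
    init = function(seed) {
      with_seed(derive_seed(seed, "init", "cnn3d"), {
        vals <- numeric(sum(lengths(layout)))
        vals[layout$conv_w] <- xavier_uniform(27, 1, 27 * Fk)
        vals[layout$conv_b] <- 0
        fan_in <- Fk + as.integer(config$sex_concat)
        vals[layout$w_out] <- xavier_uniform(fan_in, 1, length(layout$w_out))
        vals[layout$b_out] <- 0
        param_vector(vals, layout)
      })
    },
    predict = function(pv, table) forward(pv, table)$yhat + offset,
    loss = function(pv, table) mean((forward(pv, table)$yhat - tgt(table))^2),
    grad = function(pv, table, training = TRUE) {
      fw <- forward(pv, table)
      n <- nrow(table)
      r <- (2 / n) * (fw$yhat - tgt(table))
      g <- numeric(length(pv))
      w_out <- pv_segment(pv, "w_out")
      g[layout$w_out] <- c(drop(crossprod(fw$pooled, r)),
                           if (config$sex_concat) sum(r * table$sex))
      g[layout$b_out] <- sum(r)
      gW <- matrix(0, 27, Fk); gb <- numeric(Fk)
      for (f in seq_len(Fk)) {
        dZ <- (r * w_out[f] / V) * (fw$Z[[f]] > 0)  # n x V (recycled rowwise)
        gb[f] <- sum(dZ)
        for (k in 1:27) gW[k, f] <- sum(dZ * fw$X[, inmap[, k], drop = FALSE])
      }
      g[layout$conv_w] <- as.numeric(gW)
      g[layout$conv_b] <- gb
      g
    }
  )
}

#' Build a model adapter for a participant table
#'
#' An adapter bundles initialization, prediction, MSE loss and its gradient
#' for one predictor architecture, against a fixed feature dimensionality.
#' The federation engine and [train_predictor()] are written against this
#' interface only.
#'
#' @param config a [predictor_config()].
#' @param table a participant table supplying the feature dimensionality
#'   (and, for `cnn3d_small`, the volume dimensions).
#' @param preprocess optional [preprocess_stats()]; when supplied, the
#'   adapter standardizes features and centres the age target with these
#'   statistics (training-source statistics; pooled federated statistics
#'   for the federated model). `NULL` means raw features.
#' @return A `model_adapter` list with elements `init(seed)`,
#'   `predict(params, table)`, `loss(params, table)`,
#'   `grad(params, table, training)`, `layout`, `kind`, `preprocess`.
#' @export
make_model_adapter <- function(config, table, preprocess = NULL) {
  p <- ncol(raw_features(table))
  pp <- preprocess %||% neutral_preprocess(p)
  if (length(pp$center) != p) stop("preprocess stats do not match feature dimension",
                                   call. = FALSE)
  feats <- function(tab) {
    X <- raw_features(tab)
    sweep(sweep(X, 2, pp$center), 2, pp$scale, "/")
  }
  tgt <- function(tab) tab$age - pp$age_center
  offset <- pp$age_center
  ad <- switch(config$kind,
    linear = adapter_linear(config, p, feats, tgt, offset),
    mlp = adapter_mlp(config, p, feats, tgt, offset),
    cnn3d_small = adapter_cnn3d(config, p,
      attr(table, "volume_dim") %||% stop("table lacks a volume_dim attribute",
                                          call. = FALSE),
      feats, tgt, offset))
  ad$preprocess <- pp
  structure(ad, class = "model_adapter")
}

# One optimizer step; `state` carries Adam moments across minibatches.
optimizer_step <- function(values, grad, lr, config, state) {
  if (config$optimizer == "sgd") {
    return(list(values = values - lr * grad, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  list(values = values - lr * mhat / (sqrt(vhat) + eps), state = state)
}
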