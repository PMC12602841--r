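test_that("the trained linear predictor matches the closed-form least-squares fit", {
  # noise-free y = 2 x + 1; OLS is exact, so the trained model must match it
  set.seed(10)
  n <- 64
  x <- runif(n, 0, 10)
  tab <- tibble::tibble(participant_id = as.character(1:n), age = 2 * x + 1,
                        sex = rep(0L, n),
                        brain_features = matrix(x, n, 1,
                                                dimnames = list(NULL, "bf_001")))
  cfg <- predictor_config("linear", optimizer = "sgd", learning_rate = 0.3,
                          lr_decay = 0, sex_concat = FALSE)
  fit <- train_predictor(tab, NULL, cfg, epochs = 80, batch_size = 1000, seed = 1)
  pred <- predict_age(fit, tab, cfg)
  ols <- unname(fitted(lm(age ~ x, data.frame(age = tab$age, x = x))))
  expect_lt(max(abs(pred - ols)), 1e-3)
  # recovered slope on the original scale
  tab2 <- tab[1:2, ]
  tab2$brain_features <- matrix(c(0, 10), 2, 1, dimnames = list(NULL, "bf_001"))
  slope <- diff(predict_age(fit, tab2, cfg)) / 10
  expect_equal(unname(slope), 2, tolerance = 1e-3)
})

test_that("zero epochs returns the initialization and training loss never increases", {
  tab <- generate_cohort(tiny_cohort(n = 50), tiny_truth())
  cfg <- predictor_config("linear", optimizer = "sgd", learning_rate = 0.05,
                          lr_decay = 0)
  init <- train_predictor(tab, NULL, cfg, epochs = 0, seed = 3)
  ad <- make_model_adapter(cfg, tab, preprocess = attr(init, "preprocess"))
  expect_identical(init$values, ad$init(3)$values)
  fit <- train_predictor(tab, NULL, cfg, epochs = 40, batch_size = 1000, seed = 3)
  losses <- attr(fit, "history")$train_loss
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("mlp with dropout trains stochastically but predicts deterministically", {
  tab <- generate_cohort(tiny_cohort(n = 60), tiny_truth())
  cfg <- predictor_config("mlp", hidden_sizes = 8, dropout_last = 0.5,
                          learning_rate = 5e-3)
  fit <- train_predictor(tab, NULL, cfg, epochs = 3, seed = 2)
  p1 <- predict_age(fit, tab, cfg)
  p2 <- predict_age(fit, tab, cfg)
  expect_identical(p1, p2)
  fit2 <- train_predictor(tab, NULL, cfg, epochs = 3, seed = 2)
  expect_identical(fit$values, fit2$values)
})

test_that("the small 3-D convolutional predictor trains on volumetric features", {
  truth <- generator_truth(feature_mode = "volume", volume_dim = c(6L, 6L, 6L),
                           noise_sd_brain = 0.5, seed = 31)
  tab <- generate_cohort(tiny_cohort(n = 40), truth)
  cfg <- predictor_config("cnn3d_small", n_filters = 2, learning_rate = 5e-3)
  fit <- train_predictor(tab, NULL, cfg, epochs = 4, batch_size = 8, seed = 1)
  pred <- predict_age(fit, tab, cfg)
  expect_length(pred, 40)
  expect_true(all(is.finite(pred)))
  # gradient check against finite differences on a few coordinates
  ad <- make_model_adapter(cfg, tab, preprocess = attr(fit, "preprocess"))
  g <- ad$grad(fit, tab[1:8, ], training = FALSE)
  eps <- 1e-6
  for (i in c(1, 30, length(fit$values))) {
    vp <- fit$values; vp[i] <- vp[i] + eps
    vm <- fit$values; vm[i] <- vm[i] - eps
    fd <- (ad$loss(param_vector(vp, fit$layout), tab[1:8, ]) -
             ad$loss(param_vector(vm, fit$layout), tab[1:8, ])) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("predictions are row-independent and duplicate rows get duplicate predictions", {
  tab <- generate_cohort(tiny_cohort(n = 30), tiny_truth())
  cfg <- predictor_config("linear")
  fit <- train_predictor(tab, NULL, cfg, epochs = 5, seed = 4)
  pred <- predict_age(fit, tab, cfg)
  perm <- sample(30)
  expect_equal(predict_age(fit, tab[perm, ], cfg), pred[perm], tolerance = 1e-14)
  dup <- tab[c(1, 1), ]
  pd <- predict_age(fit, dup, cfg)
  expect_equal(pd[1], pd[2])
  # layout mismatch is caught
  expect_error(predict_age(fit, tab, predictor_config("mlp")), "layout")
})

test_that("mae is the mean absolute deviation and validates inputs", {
  expect_equal(mae(c(60, 70), c(62, 66)), 3)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(1:5 + 3, 1:5), 3)
  expect_error(mae(1:3, 1:2), "length")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap CI behaves at the degenerate and single-resample edges", {
  age <- 1:20
  expect_equal(unname(bootstrap_ci_mae(age + 3, age, resamples = 50)), c(3, 3))
  one <- bootstrap_ci_mae(age + rnorm(20), age, resamples = 1, seed = 2)
  expect_equal(one[["low"]], one[["high"]])
  expect_error(bootstrap_ci_mae(age, age, level = 1.5), "level")
})

test_that("the 95% bootstrap interval almost always contains the point MAE", {
  set.seed(77)
  pred <- rnorm(60, 50, 8); age <- rnorm(60, 50, 8)
  m <- mae(pred, age)
  hits <- vapply(1:100, function(s) {
    ci <- bootstrap_ci_mae(pred, age, resamples = 1000, seed = s)
    ci[["low"]] <= m && m <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("bootstrap CI width shrinks approximately as 1/sqrt(n)", {
  set.seed(5)
  n <- 400
  err <- rnorm(4 * n, 0, 3)
  age <- rnorm(4 * n, 60, 8)
  w_small <- diff(bootstrap_ci_mae(age[1:n] + err[1:n], age[1:n],
                                   resamples = 2000, seed = 1))
  w_large <- diff(bootstrap_ci_mae(age + err, age, resamples = 2000, seed = 1))
  expect_equal(unname(w_small / w_large), 2, tolerance = 0.2)
})

test_that("k-fold CV partitions participants and honors a perfect oracle", {
  tab <- generate_cohort(tiny_cohort(n = 9), tiny_truth())
  seen <- new.env()
  oracle <- function(train) {
    assign(paste(sort(train$participant_id), collapse = ","), TRUE, envir = seen)
    function(test) test$age
  }
  maes <- kfold_cv(tab, k = 3, trainer = oracle, seed = 1)
  expect_equal(maes, c(0, 0, 0))
  expect_length(ls(seen), 3)  # three distinct training sets of size 6
  maes2 <- kfold_cv(tab, k = 3, trainer = oracle, seed = 1)
  expect_identical(maes, maes2)
  expect_error(kfold_cv(tab, k = 10, trainer = oracle), "exceeds")
})
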