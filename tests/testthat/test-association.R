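test_that("federated standardization equals centralized statistics exactly", {
  tabs <- scored_world(n_per = c(200, 150, 100), seed = 3)
  vars <- c("MetaboAge", "BrainAge", "Age", "BMI", "EC1")
  st <- federated_standardize(tabs, vars)
  pooled <- do.call(rbind, tabs)
  for (v in vars) {
    x <- fedbioage:::assoc_variable(pooled, v)
    i <- match(v, st$variable)
    expect_equal(st$mean[i], mean(x), tolerance = 1e-12)
    expect_equal(st$sd[i], sd(x), tolerance = 1e-12)
    expect_equal(st$n[i], length(x))
  }
  one <- federated_standardize(tabs[1], "Age")
  expect_equal(one$mean, mean(tabs[[1]]$age), tolerance = 1e-14)
  # two tiny cohorts, hand-computed pooled values
  t1 <- tabs[[1]][1:2, ]; t1$age <- c(0, 0)
  t2 <- tabs[[2]][1:2, ]; t2$age <- c(2, 2)
  st2 <- federated_standardize(list(t1, t2), "Age")
  expect_equal(st2$mean, 1)
  expect_equal(st2$sd, sqrt(4 / 3))  # sum sq dev 4, n - 1 = 3
  expect_error(federated_standardize(list(t1), "Age"), "zero pooled variance")
})

test_that("federated gradient descent reproduces centralized GD round by round", {
  tabs <- scored_world(n_per = c(120, 80, 100), seed = 5)
  spec <- association_spec("metaboage", "M2", eta = 0.1, max_rounds = 150,
                           tol = 0, restarts = 1, seed = 9)
  stats <- fedbioage:::assoc_stats_for(tabs, "metaboage", "M2")
  designs <- lapply(tabs, fedbioage:::assoc_design, response = "metaboage",
                    covariate_set = "M2", stats = stats)
  X <- do.call(rbind, lapply(designs, `[[`, "X"))
  y <- do.call(c, lapply(designs, `[[`, "y"))
  # oracle: plain centralized gradient descent from the same initialization
  beta <- fedbioage:::with_seed(fedbioage:::derive_seed(9, "restart", 1),
                                0.01 * rnorm(ncol(X)))
  for (t in 1:150) beta <- beta - 0.1 * (2 / nrow(X)) * drop(crossprod(X, X %*% beta - y))
  fit <- federated_linreg(tabs, spec)
  expect_lt(max(abs(fit$betas - beta)), 1e-12)
})

test_that("noise-free standardized regression converges to the known coefficient", {
  tabs <- scored_world(n_per = c(150, 150), seed = 7)
  for (tab in seq_along(tabs)) {
    tabs[[tab]]$metaboage <- 0  # overwritten below
  }
  st <- federated_standardize(tabs, "BrainAge")
  for (i in seq_along(tabs)) {
    z <- (tabs[[i]]$brainage - st$mean) / st$sd
    tabs[[i]]$metaboage <- 0.4 * z  # exact standardized slope 0.4
  }
  spec <- association_spec("metaboage", "M1", max_rounds = 4000, tol = 1e-13,
                           restarts = 2, seed = 1)
  fit <- federated_linreg(tabs, spec)
  # response is re-standardized internally, so the slope rescales by sd(y)
  ols <- closed_form_pooled_ols(tabs, spec)
  expect_equal(fit$betas[["BrainAge"]], ols$betas[["BrainAge"]], tolerance = 1e-6)
  expect_equal(unname(abs(fit$betas[["BrainAge"]])), 1, tolerance = 1e-3)
})

test_that("federated estimates agree with the pooled closed form across covariate sets", {
  tabs <- scored_world(n_per = c(300, 250, 200), seed = 11)
  for (set in c("M1", "M4", "M6")) {
    spec <- association_spec("metaboage", set, max_rounds = 8000, tol = 1e-12,
                             restarts = 3, seed = 2)
    fed <- federated_linreg(tabs, spec)
    ols <- closed_form_pooled_ols(tabs, spec)
    expect_lt(max(abs(fed$betas - ols$betas)), 1e-4)
    expect_equal(fed$ses, ols$ses, tolerance = 1e-6)
  }
})

test_that("pooled OLS from sufficient statistics equals concatenated-table OLS", {
  tabs <- scored_world(n_per = c(120, 90, 60), seed = 13)
  spec <- association_spec("metabohealth", "M6")
  part <- closed_form_pooled_ols(tabs, spec)
  pooled_tab <- do.call(rbind, tabs)
  conc <- closed_form_pooled_ols(list(pooled_tab), spec)
  expect_lt(max(abs(part$betas - conc$betas)), 1e-12)
  expect_lt(max(abs(part$ses - conc$ses)), 1e-12)
  # and against lm() on the standardized design as an independent oracle
  stats <- fedbioage:::assoc_stats_for(tabs, "metabohealth", "M6")
  d <- fedbioage:::assoc_design(pooled_tab, "metabohealth", "M6", stats)
  lmfit <- lm(d$y ~ d$X - 1)
  expect_equal(unname(part$betas), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(part$ses), unname(coef(summary(lmfit))[, 2]),
               tolerance = 1e-8)
})

test_that("collinear designs raise an error naming the offending columns", {
  tabs <- scored_world(n_per = c(80, 80), seed = 15)
  for (i in seq_along(tabs)) tabs[[i]]$bmi <- tabs[[i]]$age  # BMI duplicates Age
  spec <- association_spec("metaboage", "M6")
  expect_error(closed_form_pooled_ols(tabs, spec), "collinear")
})

test_that("results are invariant to cohort order and within-cohort shuffling", {
  tabs <- scored_world(n_per = c(100, 140), seed = 17)
  spec <- association_spec("metaboage", "M2", restarts = 1, max_rounds = 2000,
                           tol = 1e-12, seed = 3)
  base <- federated_linreg(tabs, spec)
  rev_fit <- federated_linreg(rev(tabs), spec)
  expect_equal(base$betas, rev_fit$betas, tolerance = 1e-10)
  shuffled <- lapply(tabs, function(tab) tab[sample(nrow(tab)), ])
  shuf_fit <- federated_linreg(shuffled, spec)
  expect_equal(base$betas, shuf_fit$betas, tolerance = 1e-10)
})

test_that("the covariate ladder has the published six-model structure", {
  tabs <- scored_world(n_per = c(150, 150), seed = 19)
  ladder <- run_covariate_ladder(tabs, "metaboage", method = "closed_form")
  expect_setequal(unique(ladder$model_id), paste0("M", 1:6))
  m1 <- ladder[ladder$model_id == "M1", ]
  expect_setequal(m1$term, c("(Intercept)", "BrainAge"))
  m4 <- ladder[ladder$model_id == "M4", ]
  expect_setequal(m4$term,
                  c("(Intercept)", "BrainAge", "Age", "Sex", "DM", "LagTime"))
  # intercepts are 0 after standardization (self-check)
  expect_lt(max(abs(ladder$beta[ladder$term == "(Intercept)"])), 1e-8)
  fmt <- format_association_table(ladder)
  expect_equal(nrow(fmt), 6)
  expect_true(all(c("BrainAge", "Age", "mae") %in% names(fmt)))
  expect_true(all(fmt$Age[fmt$model_id %in% c("M1", "M3", "M5")] == "-"))
})

test_that("age confounding attenuates the score association once age is adjusted", {
  # both scores share only the age signal, so M1 is strongly positive and
  # the age-adjusted M2 coefficient collapses toward 0
  tabs <- scored_world(n_per = c(400, 400), seed = 23,
                       truth = tiny_truth(rho_gaps = 0))
  lad <- run_covariate_ladder(tabs, "metaboage", method = "closed_form")
  b1 <- lad[lad$model_id == "M1" & lad$term == "BrainAge", ]
  b2 <- lad[lad$model_id == "M2" & lad$term == "BrainAge", ]
  expect_lt(b1$p, 1e-10)
  expect_gt(b1$beta, 0)
  expect_lt(abs(b2$beta), 0.5 * abs(b1$beta))
})
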