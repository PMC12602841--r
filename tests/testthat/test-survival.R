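surv_table <- function(time, event, x1, x2 = NULL) {
  tab <- tibble::tibble(time_mort = time, event_mort = as.integer(event),
                        bag = x1)
  if (!is.null(x2)) tab$mag <- x2
  tab
}

test_that("gap computation is elementwise and permutation-equivariant", {
  tabs <- scored_world(n_per = c(50), seed = 1)
  tab <- tabs[[1]]
  g <- compute_gaps(tab)
  expect_equal(g$bag, g$brainage - g$age)
  expect_equal(g$mag, g$metaboage - g$age)
  perm <- sample(nrow(tab))
  gp <- compute_gaps(tab[perm, ])
  expect_equal(gp$bag, g$bag[perm])
  tab$metaboage <- tab$age
  expect_equal(compute_gaps(tab)$mag, rep(0, nrow(tab)))
  tab$brainage <- NULL
  expect_error(compute_gaps(tab), "brainage")
})

test_that("the Newton fit matches dense grid maximization of the partial likelihood", {
  # 1-D toy instance with a finite maximizer
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0)
  x <- c(0.5, -0.2, 0.4, -0.7, 0.1)
  fit <- fit_cox(surv_table(time, event, x), "mortality", "bag", "none")
  grid <- seq(-4, 4, by = 1e-3)
  ll <- vapply(grid, function(b) naive_cox_loglik(b, time, event, cbind(x)),
               numeric(1))
  expect_lt(abs(fit$coefficients[["bag"]] - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  # 2-D instance against a coarse grid
  x2 <- c(-0.3, 0.8, 0.1, 0.4, -0.6)
  fit2 <- fit_cox(surv_table(time, event, x, x2), "mortality", c("bag", "mag"),
                  "none")
  g2 <- as.matrix(expand.grid(b1 = seq(-3, 3, by = 0.01),
                              b2 = seq(-3, 3, by = 0.01)))
  ll2 <- apply(g2, 1, function(b) naive_cox_loglik(b, time, event, cbind(x, x2)))
  best <- g2[which.max(ll2), ]
  # the toy likelihood has a flat valley, so certify via the objective value
  # (Newton's optimum must dominate every grid point) and locate the argmax
  # within grid resolution scaled by the valley's conditioning
  expect_gte(fit2$loglik, max(ll2) - 1e-12)
  expect_lt(max(ll2) - fit2$loglik, 1e-3)
  expect_lt(abs(fit2$coefficients[["bag"]] - best[["b1"]]), 0.05)
  expect_lt(abs(fit2$coefficients[["mag"]] - best[["b2"]]), 0.05)
})

test_that("the fit agrees with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  tabs <- scored_world(n_per = c(600), seed = 3, lag_sd = 0)
  tab <- tabs[[1]]
  fit <- suppressMessages(fit_cox(tab, "mortality", c("bag", "mag"), "full"))
  X <- cbind(bag = tab$bag, mag = tab$mag, Age = tab$age, Sex = tab$sex,
             DM = tab$dm, BMI = tab$bmi,
             EC1 = as.numeric(tab$ec == "low"), EC3 = as.numeric(tab$ec == "high"))
  # lag time is constant in this fixture cohort and must have been dropped
  expect_false("LagTime" %in% names(fit$coefficients))
  ref <- survival::coxph(survival::Surv(tab$time_mort, tab$event_mort) ~ X,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$ses), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  bh <- survival::basehaz(ref, centered = FALSE)
  # basehaz reports all follow-up times; compare at the event times
  bh_events <- bh$hazard[match(fit$basehaz$time, bh$time)]
  expect_equal(fit$basehaz$hazard, bh_events, tolerance = 1e-4)
})

test_that("the partial-likelihood gradient vanishes at the optimum", {
  tabs <- scored_world(n_per = c(400), seed = 5)
  fit <- fit_cox(tabs[[1]], "mortality", c("bag", "mag"), "age_only")
  expect_lt(fit$score_norm, 1e-8)
})

test_that("duplicating every row leaves the coefficients unchanged", {
  tabs <- scored_world(n_per = c(200), seed = 7)
  tab <- tabs[[1]]
  fit1 <- fit_cox(tab, "mortality", c("bag", "mag"), "age_only")
  fit2 <- fit_cox(tab[rep(seq_len(nrow(tab)), each = 2), ], "mortality",
                  c("bag", "mag"), "age_only")
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
})

test_that("a covariate independent of the outcome stays within 2 SE of zero", {
  set.seed(31)
  n <- 3000
  x <- rnorm(n)
  noise <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.3 * noise))
  event <- as.integer(time <= 10); time <- pmin(time, 10)
  fit <- fit_cox(surv_table(time, event, x), "mortality", "bag", "none")
  expect_lt(abs(fit$coefficients[["bag"]]), 2 * fit$ses[["bag"]])
})

test_that("errors: no events, nonpositive times, missing outcome", {
  tabs <- scored_world(n_per = c(30), seed = 9)
  tab <- tabs[[1]]
  tab$event_mort <- 0L
  expect_error(fit_cox(tab, "mortality", "bag", "none"), "no events")
  tab2 <- tabs[[1]]
  tab2$time_mort[1] <- 0
  expect_error(fit_cox(tab2, "mortality", "bag", "none"), "> 0")
  expect_error(fit_cox(tab2[, setdiff(names(tab2), "time_dem")], "dementia",
                       "bag", "none"), "outcome")
})

test_that("predicted survival curves respect the linear-predictor ordering", {
  truth <- tiny_truth(loghr_mort_bag = 0.08, loghr_mort_mag = 0.08)
  tabs <- scored_world(n_per = c(1500), seed = 11, truth = truth)
  tab <- tabs[[1]]
  fit <- fit_cox(tab, "mortality", c("bag", "mag"), "age_only")
  expect_true(all(fit$coefficients[c("bag", "mag")] > 0))
  profiles <- list(
    qq = quartile_profile(fit, tab, "Q1", "Q1"),
    qh = quartile_profile(fit, tab, "Q1", "Q3"),
    hq = quartile_profile(fit, tab, "Q3", "Q1"),
    hh = quartile_profile(fit, tab, "Q3", "Q3"))
  expect_lt(profiles$qq$values[["bag"]], profiles$hh$values[["bag"]])
  curves <- lapply(profiles, function(p) predicted_survival(fit, p))
  for (cv in curves) {
    expect_equal(cv$surv[1], 1)
    expect_true(all(diff(cv$surv) <= 1e-12))
  }
  # concordant-profile ordering with mixed profiles in between
  expect_true(all(curves$hh$surv <= curves$qq$surv))
  expect_true(all(curves$qh$surv <= curves$qq$surv & curves$qh$surv >= curves$hh$surv))
  expect_true(all(curves$hq$surv <= curves$qq$surv & curves$hq$surv >= curves$hh$surv))
  # zero linear predictor reduces to baseline survival
  zero <- profiles$qq
  zero$values[] <- 0
  expect_equal(predicted_survival(fit, zero)$surv[-1],
               exp(-fit$basehaz$hazard), tolerance = 1e-12)
  bad <- profiles$qq
  names(bad$values)[1] <- "nope"
  expect_error(predicted_survival(fit, bad), "match")
})

test_that("the survival suite emits separate, pairwise and four-profile outputs", {
  truth <- tiny_truth(loghr_mort_bag = 0.08, loghr_mort_mag = 0.08)
  tabs <- scored_world(n_per = c(800), seed = 13, truth = truth)
  tab <- tabs[[1]]
  suite <- run_survival_suite(tab, outcomes = "mortality")
  cf <- suite$coefficients
  expect_setequal(unique(cf$model_type),
                  c("separate_bag", "separate_mag", "separate_metabohealth",
                    "pairwise"))
  # four quartile profiles per pairwise fit
  cv <- suite$curves
  per_fit <- unique(cv[, c("scores", "covariate_set")])
  for (i in seq_len(nrow(per_fit))) {
    sub <- cv[cv$scores == per_fit$scores[i] &
                cv$covariate_set == per_fit$covariate_set[i], ]
    expect_length(unique(sub$profile), 4)
  }
  # an outcome with no events is skipped with a warning
  tab$event_dem <- 0L
  expect_warning(run_survival_suite(tab, outcomes = c("mortality", "dementia")),
                 "dementia")
})
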