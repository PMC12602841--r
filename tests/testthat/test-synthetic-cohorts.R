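test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec("x", 0, 40, 80), ">= 1")
  expect_error(cohort_spec("x", 10, 80, 40), "age_low")
  expect_error(cohort_spec("x", 10, 40, 80, sex_frac_female = 1.2), "proportion")
  expect_error(cohort_spec("x", 10, 40, 80, followup_years = 0), "followup_years")
  expect_error(generator_truth(rho_gaps = 1.5), "rho_gaps")
})

test_that("degenerate noise-free generation reproduces the linear feature map", {
  truth <- generator_truth(p = 5, sigma_brain_gap = 1e-12, noise_sd_brain = 0,
                           seed = 7)
  tab <- generate_cohort(tiny_cohort(n = 20, site_offset_scale = 0), truth)
  expected <- outer(tab$age, truth$w_brain)
  expect_equal(unname(tab$brain_features), unname(expected), tolerance = 1e-9)
})

test_that("generation is deterministic per seed and varies across seeds", {
  truth <- tiny_truth()
  s <- tiny_cohort(n = 40, seed = 3)
  t1 <- generate_cohort(s, truth)
  t2 <- generate_cohort(s, truth)
  expect_identical(t1$age, t2$age)
  expect_identical(t1$brain_features, t2$brain_features)
  t3 <- generate_cohort(tiny_cohort(n = 40, seed = 4), truth)
  expect_false(identical(t1$age, t3$age))
})

test_that("event fraction matches the closed-form exponential-censoring probability", {
  # with zero log-HRs and zero covariate effects the event probability is
  # 1 - exp(-rate * followup)
  truth <- generator_truth(
    p = 4, loghr_mort_bag = 0, loghr_mort_mag = 0,
    baseline_hazard_mort = 0.05,
    covariate_effects = c(sex = 0, dm = 0, bmi = 0, ec_low = 0, ec_high = 0),
    seed = 11)
  tab <- generate_cohort(tiny_cohort(n = 5000, followup_years = 10, seed = 5), truth)
  p_true <- 1 - exp(-0.05 * 10)
  se <- sqrt(p_true * (1 - p_true) / 5000)
  expect_lt(abs(mean(tab$event_mort) - p_true), 3 * se)
  expect_true(all(tab$time_mort > 0 & tab$time_mort <= 10))
})

test_that("independent gaps are empirically uncorrelated and SDs match truth", {
  truth <- generator_truth(p = 4, rho_gaps = 0, seed = 13)
  tab <- generate_cohort(tiny_cohort(n = 4000, seed = 9), truth)
  expect_lt(abs(cor(tab$true_brain_gap, tab$true_metab_gap)), 3 / sqrt(4000))
  expect_equal(sd(tab$true_brain_gap), truth$sigma_brain_gap, tolerance = 0.1)
  # and a nonzero correlation is reproduced
  truth2 <- generator_truth(p = 4, rho_gaps = 0.6, seed = 13)
  tab2 <- generate_cohort(tiny_cohort(n = 4000, seed = 9), truth2)
  expect_equal(cor(tab2$true_brain_gap, tab2$true_metab_gap), 0.6, tolerance = 0.05)
})

test_that("regression of a feature on age recovers its loading when noise is small", {
  truth <- generator_truth(p = 3, sigma_brain_gap = 0.2, noise_sd_brain = 0.05,
                           seed = 21)
  tab <- generate_cohort(tiny_cohort(n = 2000, seed = 2), truth)
  for (j in 1:3) {
    fit <- summary(lm(tab$brain_features[, j] ~ tab$age))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    expect_lt(abs(est - truth$w_brain[j]), 2 * se + 1e-6)
  }
})

test_that("federation generation validates names and respects age bounds", {
  truth <- tiny_truth()
  expect_error(generate_federation(list(tiny_cohort("a"), tiny_cohort("a")), truth),
               "duplicate")
  specs <- list(tiny_cohort("tms", 300, 40, 75, seed = 1),
                tiny_cohort("rs", 300, 45, 100, seed = 2),
                tiny_cohort("lls", 300, 45, 84, seed = 3))
  tabs <- generate_federation(specs, truth)
  expect_named(tabs, c("tms", "rs", "lls"))
  for (i in seq_along(specs)) {
    expect_true(all(tabs[[i]]$age >= specs[[i]]$age_low &
                      tabs[[i]]$age <= specs[[i]]$age_high))
  }
  one <- generate_federation(list(tiny_cohort("solo")), truth)
  expect_length(one, 1)
})

test_that("same spec under different seeds matches in distribution (KS on age)", {
  truth <- tiny_truth()
  t1 <- generate_cohort(cohort_spec("a", 2000, 45, 85, seed = 1), truth)
  t2 <- generate_cohort(cohort_spec("a", 2000, 45, 85, seed = 2), truth)
  expect_false(identical(t1$age, t2$age))
  ks <- suppressWarnings(ks.test(t1$age, t2$age))
  expect_gt(ks$p.value, 0.001)
})

test_that("lag-time filtering is strict and preserves order; zero-lag cohorts pass through", {
  tab <- generate_cohort(tiny_cohort(n = 5), tiny_truth())
  tab$lag_time <- c(-8, -6.9, 0, 6.9, 7.0)
  kept <- select_analysis_set(tab, max_abs_lag = 7)
  expect_equal(kept$lag_time, c(-6.9, 0, 6.9))
  lls_like <- generate_cohort(tiny_cohort("lls", 30, lag_mean = 0, lag_sd = 0), tiny_truth())
  expect_identical(select_analysis_set(lls_like, 7), lls_like)
  expect_identical(select_analysis_set(tab, Inf)$participant_id, tab$participant_id)
})

test_that("train/validation split sizes, disjointness and determinism", {
  tab <- generate_cohort(tiny_cohort(n = 100), tiny_truth())
  sp <- split_train_val(tab, 0.8, seed = 5)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$val), 20)
  expect_length(intersect(sp$train$participant_id, sp$val$participant_id), 0)
  sp2 <- split_train_val(tab, 0.8, seed = 5)
  expect_identical(sp$train$participant_id, sp2$train$participant_id)
  tiny <- tab[1:5, ]
  sp5 <- split_train_val(tiny, 0.8, seed = 1)
  expect_equal(c(nrow(sp5$train), nrow(sp5$val)), c(4, 1))
  expect_error(split_train_val(tab[1, ], 0.8), "at least 2")
})

test_that("participant tables round-trip losslessly through CSV", {
  tab <- generate_cohort(tiny_cohort(n = 15), tiny_truth())
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_participant_table(tab, path)
  back <- read_participant_table(path)
  expect_identical(back$age, tab$age)
  expect_identical(unname(back$brain_features), unname(tab$brain_features))
  expect_identical(unname(back$metabolites), unname(tab$metabolites))
  expect_identical(back$ec, tab$ec)
  expect_identical(back$time_mort, tab$time_mort)
})

test_that("longitudinal augmentation duplicates rows with perturbed features only", {
  tab <- generate_cohort(tiny_cohort(n = 10), tiny_truth())
  aug <- augment_longitudinal(tab, repeats = 3, feature_noise_sd = 0.1, seed = 2)
  expect_equal(nrow(aug), 30)
  expect_equal(aug$age, rep(tab$age, each = 3))
  # originals kept intact once per participant
  expect_identical(aug$brain_features[seq(1, 30, by = 3), ], tab$brain_features)
  expect_false(identical(aug$brain_features[2, ], tab$brain_features[1, ]))
  expect_identical(augment_longitudinal(tab, 1), tab)
})
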