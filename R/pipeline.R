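#' Default three-cohort study design
#'
#' Cohort specs mirroring the published characteristics of the three
#' participating studies at desk scale: a younger cohort (ages 40-75, high
#' diabetes prevalence, positive lag times), an older general-population
#' cohort (46-96, negative mean lag), and a smaller external cohort (45-84)
#' in which every lag time is exactly 0 and all participants have blood
#' samples. Sizes default to hundreds rather than thousands so analyses run
#' in seconds; scale with `n_scale`.
#'
#' @param n_scale multiplier on the default cohort sizes.
#' @param seed master seed; each cohort derives its own stream.
#' @return Named list of [cohort_spec()] objects (`tms`, `rs`, `lls`).
#' @export
default_cohort_specs <- function(n_scale = 1, seed = 20260101L) {
  list(
    tms = cohort_spec("tms", n = round(600 * n_scale), age_low = 40, age_high = 75,
                      age_shape = "truncnorm", age_mean = 60.3, age_sd = 8.4,
                      sex_frac_female = 0.49, dm_prevalence = 0.222,
                      lag_mean = 2.2, lag_sd = 1.3, site_offset_scale = 1,
                      blood_frac = 0.48,
                      ec_probs = c(low = 0.304, medium = 0.289, high = 0.407),
                      followup_years = 8, seed = derive_seed(seed, "tms")),
    rs = cohort_spec("rs", n = round(600 * n_scale), age_low = 46, age_high = 96,
                     age_shape = "truncnorm", age_mean = 67.5, age_sd = 9.5,
                     sex_frac_female = 0.571, dm_prevalence = 0.088,
                     lag_mean = -1.39, lag_sd = 3.22, site_offset_scale = 1,
                     blood_frac = 0.30,
                     ec_probs = c(low = 0.463, medium = 0.297, high = 0.240),
                     followup_years = 10, seed = derive_seed(seed, "rs")),
    lls = cohort_spec("lls", n = round(200 * n_scale), age_low = 45, age_high = 84,
                      age_shape = "truncnorm", age_mean = 65.5, age_sd = 6.6,
                      sex_frac_female = 0.522, dm_prevalence = 0.058,
                      lag_mean = 0, lag_sd = 0, site_offset_scale = 1,
                      blood_frac = 1,
                      ec_probs = c(low = 0.552, medium = 0.086, high = 0.362),
                      followup_years = 13, seed = derive_seed(seed, "lls"))
  )
}

#' Default end-to-end scenario
#'
#' Bundles cohort specs, generator truth and all stage configurations into
#' one `scenario_config`. The first two cohorts train the predictor (locally
#' and federatedly); remaining cohorts serve as external test sites.
#'
#' @param n_scale multiplier on cohort sizes.
#' @param seed master seed; every stage derives its own stream from it.
#' @param predictor a [predictor_config()].
#' @param federation a [federation_config()].
#' @return An object of class `scenario_config`.
#' @export
default_scenario <- function(n_scale = 1, seed = 20260101L,
                             predictor = predictor_config("linear"),
                             federation = federation_config(seed = seed)) {
  structure(list(
    cohorts = default_cohort_specs(n_scale, seed),
    truth = generator_truth(seed = derive_seed(seed, "truth")),
    predictor = predictor,
    federation = federation,
    training_cohorts = c("tms", "rs"),
    max_abs_lag = 7,
    train_frac = 0.8,
    local_epochs_total = federation$rounds * federation$local_epochs,
    association = list(responses = c("metaboage", "metabohealth"),
                       eta = 0.1, max_rounds = 5000L, tol = 1e-9,
                       restarts = 10L),
    survival = list(cohorts = c("rs", "lls"),
                    outcomes = c("mortality", "dementia")),
    bootstrap_resamples = 1000L,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Read a scenario from a YAML file
#'
#' The file may override any subset of the default scenario: top-level keys
#' `seed`, `n_scale`, `training_cohorts`, `max_abs_lag`, `train_frac`,
#' nested `truth`, `predictor`, `federation`, `association` and `survival`
#' blocks (passed to the respective constructors), and a `cohorts` list of
#' cohort-spec fields.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 20260101L)
  sc <- default_scenario(n_scale = y$n_scale %||% 1, seed = seed)
  if (!is.null(y$truth)) sc$truth <- do.call(generator_truth, y$truth)
  if (!is.null(y$predictor)) sc$predictor <- do.call(predictor_config, y$predictor)
  if (!is.null(y$federation)) sc$federation <- do.call(federation_config, y$federation)
  if (!is.null(y$cohorts)) {
    sc$cohorts <- lapply(y$cohorts, function(cs) do.call(cohort_spec, cs))
    names(sc$cohorts) <- vapply(sc$cohorts, function(s) s$name, character(1))
  }
  for (k in c("training_cohorts", "max_abs_lag", "train_frac")) {
    if (!is.null(y[[k]])) sc[[k]] <- y[[k]]
  }
  if (!is.null(y$association)) sc$association <- utils::modifyList(sc$association, y$association)
  if (!is.null(y$survival)) sc$survival <- utils::modifyList(sc$survival, y$survival)
  sc
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full simulated federated study
#'
#' Sequences all stages end-to-end: cohort simulation; analysis-set
#' selection (blood sample available, absolute lag below the cap, complete
#' covariates) with the remaining participants split 80/20 into
#' train/validation; local predictor training per training cohort and
#' federated training across them; linear age-bias correction per training
#' source with a before/after report; scoring of the analysis sets
#' (brain-based predictor plus the two metabolomic scorers); the six-model
#' association ladder per response via the federated regression; and the
#' Cox survival suite on the cohorts with follow-up. Rerunning with the
#' same config reproduces all outputs bit-identically.
#'
#' @param config a [default_scenario()] / [read_scenario()] object.
#' @param output_dir optional directory; when given, all result tables are
#'   written as CSV together with a manifest (file, md5, seed).
#' @return List of class `pipeline_result` with elements `tables`
#'   (analysis sets, scored), `splits`, `local_fits`, `federated_fit`,
#'   `mae_grid`, `bias_report`, `association`, `survival`, `manifest`.
#' @export
run_pipeline <- function(config = default_scenario(), output_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed

  pipeline_log("simulate", "generating %d cohorts", length(config$cohorts))
  tables <- generate_federation(config$cohorts, config$truth)

  pipeline_log("select", "analysis sets: |lag| < %g y, blood sample, complete covariates",
               config$max_abs_lag)
  analysis <- lapply(tables, select_analysis_set, max_abs_lag = config$max_abs_lag)
  pool <- lapply(tables, function(tab) {
    tab[!(tab$participant_id %in%
            do.call(c, lapply(analysis, function(a) a$participant_id))), , drop = FALSE]
  })

  training <- config$training_cohorts
  splits <- lapply(training, function(ch) {
    split_train_val(pool[[ch]], config$train_frac, seed = derive_seed(seed, "split", ch))
  })
  names(splits) <- training
  for (ch in training) {
    pipeline_log("split", "%s: train %d / val %d / test %d", ch,
                 nrow(splits[[ch]]$train), nrow(splits[[ch]]$val), nrow(analysis[[ch]]))
  }

  pipeline_log("train", "local models (%d epochs each)", config$local_epochs_total)
  local_fits <- lapply(training, function(ch) {
    train_predictor(splits[[ch]]$train, splits[[ch]]$val, config$predictor,
                    epochs = config$local_epochs_total,
                    batch_size = config$federation$batch_size,
                    seed = derive_seed(seed, "local", ch))
  })
  names(local_fits) <- training

  pipeline_log("train", "federated model (%d rounds x %d epochs)",
               config$federation$rounds, config$federation$local_epochs)
  fed_pp <- preprocess_stats(lapply(splits, function(s) s$train))
  fed <- run_federated(splits,
                       model_factory = function() make_model_adapter(config$predictor,
                                                                     splits[[1]]$train,
                                                                     preprocess = fed_pp),
                       config = config$federation)
  best_round <- select_best_round(fed$log, "global_val_mae")
  fed_params <- fed$history[[best_round]]
  pipeline_log("train", "selected round %d (lowest size-weighted validation MAE)",
               best_round)

  # Table-3-shaped MAE grid: cohorts x splits x models, with bootstrap CIs
  models <- c(stats::setNames(local_fits, paste0("local_", training)),
              list(federated = fed_params))
  eval_sets <- list()
  for (ch in training) {
    eval_sets[[paste0(ch, "_training")]] <- splits[[ch]]$train
    eval_sets[[paste0(ch, "_validation")]] <- splits[[ch]]$val
  }
  for (ch in names(tables)) eval_sets[[paste0(ch, "_testing")]] <- analysis[[ch]]
  grid_rows <- list()
  for (mn in names(models)) for (en in names(eval_sets)) {
    tab <- eval_sets[[en]]
    if (nrow(tab) == 0) next
    pred <- predict_age(models[[mn]], tab, config$predictor)
    ci <- bootstrap_ci_mae(pred, tab$age, resamples = config$bootstrap_resamples,
                           seed = derive_seed(seed, "boot", mn, en))
    grid_rows[[length(grid_rows) + 1L]] <- tibble::tibble(
      model = mn, eval_set = en, n = nrow(tab),
      mae = mae(pred, tab$age), ci_low = ci["low"], ci_high = ci["high"])
  }
  mae_grid <- do.call(rbind, grid_rows)

  pipeline_log("correct", "age-bias correction per training source")
  corrections <- list()
  for (ch in training) {
    tr <- splits[[ch]]$train
    corrections[[ch]] <- fit_bias_correction(
      predict_age(local_fits[[ch]], tr, config$predictor), tr$age, source = ch)
  }
  fed_train <- do.call(rbind, lapply(splits, function(s) s$train))
  corrections$federated <- fit_bias_correction(
    predict_age(fed_params, fed_train, config$predictor), fed_train$age,
    source = "federated")
  test_preds <- lapply(names(tables), function(ch) {
    tab <- analysis[[ch]]
    list(pred = predict_age(fed_params, tab, config$predictor), age = tab$age)
  })
  names(test_preds) <- names(tables)
  bias_report <- do.call(rbind, lapply(corrections, correction_report,
                                       predictions = test_preds))

  pipeline_log("score", "attaching brainage/metaboage/metabohealth scores")
  ma_coeffs <- synthetic_metaboage_scorer(config$truth)
  mh_coeffs <- synthetic_metabohealth_scorer(config$truth)
  scored <- lapply(analysis, function(tab) {
    if (nrow(tab) == 0) return(tab)
    compute_gaps(score_participants(tab, fed_params, config$predictor,
                                    ma_coeffs, mh_coeffs))
  })

  pipeline_log("associate", "six-model covariate ladder per response (federated)")
  assoc <- lapply(config$association$responses, function(resp) {
    run_covariate_ladder(scored, response = resp, method = "federated",
                         eta = config$association$eta,
                         max_rounds = config$association$max_rounds,
                         tol = config$association$tol,
                         restarts = config$association$restarts,
                         seed = derive_seed(seed, "assoc", resp))
  })
  names(assoc) <- config$association$responses

  pipeline_log("survive", "Cox suite on cohorts: %s",
               paste(config$survival$cohorts, collapse = ", "))
  surv_tab <- do.call(rbind, scored[intersect(config$survival$cohorts, names(scored))])
  survival <- run_survival_suite(surv_tab, outcomes = config$survival$outcomes)

  result <- structure(list(
    tables = scored, splits = splits, local_fits = local_fits,
    federated_fit = fed, federated_params = fed_params, best_round = best_round,
    mae_grid = mae_grid, corrections = corrections, bias_report = bias_report,
    association = assoc, survival = survival, config = config,
    manifest = NULL
  ), class = "pipeline_result")

  if (!is.null(output_dir)) {
    result$manifest <- write_pipeline_outputs(result, output_dir)
  }
  result
}

# Write all result tables as CSV plus a manifest of md5 hashes and seeds.
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (ch in names(result$tables)) {
    path <- file.path(output_dir, sprintf("analysis_%s.csv", ch))
    write_participant_table(result$tables[[ch]], path)
    files <- c(files, path)
  }
  wr(result$mae_grid, "mae_grid.csv")
  wr(result$bias_report, "bias_correction_report.csv")
  for (resp in names(result$association)) {
    wr(result$association[[resp]], sprintf("association_%s.csv", resp))
    wr(format_association_table(result$association[[resp]]),
       sprintf("association_%s_formatted.csv", resp))
  }
  if (!is.null(result$survival$coefficients)) {
    wr(result$survival$coefficients, "survival_coefficients.csv")
  }
  if (!is.null(result$survival$curves)) {
    wr(result$survival$curves, "survival_curves.csv")
  }
  wr(result$federated_fit$log, "federation_round_log.csv")
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)),
                             master_seed = result$config$seed)
  utils::write.csv(as.data.frame(manifest), file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  cohorts: %s\n", paste(names(x$tables), collapse = ", ")))
  cat(sprintf("  federated best round: %d\n", x$best_round))
  cat("  MAE grid:\n")
  print(x$mae_grid, n = 6)
  invisible(x)
}
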