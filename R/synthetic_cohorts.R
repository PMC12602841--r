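#' Specify one synthetic cohort
#'
#' A `cohort_spec` describes a single recruitment site: its size, age
#' distribution, covariate mix, the lag-time distribution between blood
#' sampling and brain imaging, a site-effect magnitude in feature space, and
#' the administrative censoring horizon for follow-up.
#'
#' @param name cohort label (unique within a federation).
#' @param n number of participants (>= 1).
#' @param age_low,age_high age range in years, `age_low < age_high`.
#' @param age_shape `"uniform"` or `"truncnorm"`; the latter draws from a
#'   normal with `age_mean`/`age_sd` truncated to the range.
#' @param age_mean,age_sd truncated-normal parameters (years), required when
#'   `age_shape = "truncnorm"`.
#' @param sex_frac_female proportion of female participants in `[0, 1]`
#'   (sex coded 1 = female, 0 = male).
#' @param dm_prevalence diabetes prevalence in `[0, 1]`.
#' @param lag_mean,lag_sd mean and SD (years) of the signed interval between
#'   blood draw and scan; `lag_sd = 0` forces `lag = lag_mean` exactly (the
#'   all-zero-lag cohort uses `lag_mean = 0, lag_sd = 0`).
#' @param site_offset_scale SD of the cohort-specific additive offset applied
#'   to every brain feature (site effect); 0 disables it.
#' @param blood_frac proportion of participants with a blood sample (only
#'   these are eligible for the metabolomic analysis set).
#' @param ec_probs length-3 probability vector for education category
#'   low/medium/high.
#' @param followup_years administrative censoring horizon (> 0).
#' @param seed integer RNG seed for this cohort's stream.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [default_cohort_specs()]
#' @export
cohort_spec <- function(name, n, age_low, age_high,
                        age_shape = c("uniform", "truncnorm"),
                        age_mean = NULL, age_sd = NULL,
                        sex_frac_female = 0.5,
                        dm_prevalence = 0.1,
                        lag_mean = 0, lag_sd = 1,
                        site_offset_scale = 0,
                        blood_frac = 1,
                        ec_probs = c(low = 0.44, medium = 0.224, high = 0.336),
                        followup_years = 10,
                        seed = 1L) {
  age_shape <- match.arg(age_shape)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("cohort `name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1", call. = FALSE)
  }
  check_scalar_number(age_low, "age_low")
  check_scalar_number(age_high, "age_high")
  if (age_low >= age_high) stop("age_low must be < age_high", call. = FALSE)
  if (age_shape == "truncnorm") {
    check_scalar_number(age_mean %||% NA_real_, "age_mean")
    check_scalar_number(age_sd %||% NA_real_, "age_sd", lower = 1e-12)
  }
  for (p in c("sex_frac_female", "dm_prevalence", "blood_frac")) {
    if (!is_proportion(get(p))) stop(sprintf("`%s` must be a proportion in [0, 1]", p), call. = FALSE)
  }
  check_scalar_number(lag_sd, "lag_sd", lower = 0)
  check_scalar_number(site_offset_scale, "site_offset_scale", lower = 0)
  check_scalar_number(followup_years, "followup_years", lower = 1e-12)
  ec_probs <- as.numeric(ec_probs)
  if (length(ec_probs) != 3 || any(ec_probs < 0) || abs(sum(ec_probs) - 1) > 1e-8) {
    stop("`ec_probs` must be 3 non-negative probabilities summing to 1", call. = FALSE)
  }
  structure(list(
    name = name, n = as.integer(n),
    age_low = age_low, age_high = age_high, age_shape = age_shape,
    age_mean = age_mean, age_sd = age_sd,
    sex_frac_female = sex_frac_female, dm_prevalence = dm_prevalence,
    lag_mean = lag_mean, lag_sd = lag_sd,
    site_offset_scale = site_offset_scale, blood_frac = blood_frac,
    ec_probs = stats::setNames(ec_probs, c("low", "medium", "high")),
    followup_years = followup_years, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Ground truth of the synthetic world
#'
#' Holds everything the generator knows and the analyses must recover: the
#' SDs and correlation of the latent brain-aging and metabolic-aging gaps
#' (years of apparent acceleration relative to chronological age), the linear
#' loadings mapping `age + gap` to brain features and to the 56-metabolite
#' panel, feature noise levels, per-year log hazard ratios of the gaps on
#' mortality and dementia, baseline hazard rates, and covariate log-HRs.
#'
#' Defaults: dementia is driven by the brain gap only
#' (`loghr_dem_mag = 0`), and the two gaps are independent (`rho_gaps = 0`),
#' so the only information the two age scores share is chronological age.
#'
#' @param p number of brain features in vector mode.
#' @param n_metabolites metabolite panel size (fixed at 56 downstream).
#' @param sigma_brain_gap,sigma_metab_gap SDs of the latent gaps (years, > 0).
#' @param rho_gaps correlation between the gaps in `[-1, 1]`.
#' @param noise_sd_brain,noise_sd_metab additive feature noise SDs.
#' @param loghr_mort_bag,loghr_mort_mag per-year log hazard ratios of the
#'   brain and metabolic gaps on all-cause mortality.
#' @param loghr_dem_bag,loghr_dem_mag per-year log hazard ratios on dementia.
#' @param baseline_hazard_mort,baseline_hazard_dem constant baseline hazards
#'   (events/year) of the exponential survival model.
#' @param covariate_effects named log-HRs for `sex`, `dm`, `bmi` (per kg/m2,
#'   centred at 26.5), `ec_low`, `ec_high` (relative to medium education);
#'   applied to both outcomes.
#' @param feature_mode `"vector"` (length-`p` feature vector) or `"volume"`
#'   (a 16 x 16 x 16 array per participant, stored flat; its voxel sum scales
#'   with `age + brain_gap`).
#' @param volume_dim integer dimensions of the volumetric mode.
#' @param w_brain,w_metab optional explicit loading vectors; drawn from the
#'   truth seed when `NULL`.
#' @param seed RNG seed used to draw the loadings.
#' @return An object of class `generator_truth`.
#' @export
generator_truth <- function(p = 64, n_metabolites = 56,
                            sigma_brain_gap = 5, sigma_metab_gap = 6,
                            rho_gaps = 0,
                            noise_sd_brain = 2, noise_sd_metab = 1,
                            loghr_mort_bag = 0.05, loghr_mort_mag = 0.05,
                            loghr_dem_bag = 0.08, loghr_dem_mag = 0,
                            baseline_hazard_mort = 0.032,
                            baseline_hazard_dem = 0.009,
                            covariate_effects = c(sex = -0.3, dm = 0.5,
                                                  bmi = 0.03, ec_low = 0.1,
                                                  ec_high = -0.1),
                            feature_mode = c("vector", "volume"),
                            volume_dim = c(16L, 16L, 16L),
                            w_brain = NULL, w_metab = NULL,
                            seed = 2026L) {
  feature_mode <- match.arg(feature_mode)
  check_scalar_number(sigma_brain_gap, "sigma_brain_gap", lower = 0)
  check_scalar_number(sigma_metab_gap, "sigma_metab_gap", lower = 0)
  check_scalar_number(rho_gaps, "rho_gaps", lower = -1, upper = 1)
  check_scalar_number(noise_sd_brain, "noise_sd_brain", lower = 0)
  check_scalar_number(noise_sd_metab, "noise_sd_metab", lower = 0)
  check_scalar_number(baseline_hazard_mort, "baseline_hazard_mort", lower = 1e-12)
  check_scalar_number(baseline_hazard_dem, "baseline_hazard_dem", lower = 1e-12)
  need <- c("sex", "dm", "bmi", "ec_low", "ec_high")
  if (!all(need %in% names(covariate_effects))) {
    stop("covariate_effects must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (feature_mode == "volume") p <- prod(volume_dim)
  if (is.null(w_brain)) {
    w_brain <- with_seed(derive_seed(seed, "w_brain"), {
      if (feature_mode == "volume") abs(stats::rnorm(p, 0, 0.02)) else stats::rnorm(p, 0, 0.15)
    })
  }
  if (is.null(w_metab)) {
    w_metab <- with_seed(derive_seed(seed, "w_metab"), stats::rnorm(n_metabolites, 0, 0.1))
  }
  if (length(w_brain) != p) stop("w_brain must have length p", call. = FALSE)
  if (length(w_metab) != n_metabolites) stop("w_metab must have length n_metabolites", call. = FALSE)
  structure(list(
    p = as.integer(p), n_metabolites = as.integer(n_metabolites),
    sigma_brain_gap = sigma_brain_gap, sigma_metab_gap = sigma_metab_gap,
    rho_gaps = rho_gaps,
    noise_sd_brain = noise_sd_brain, noise_sd_metab = noise_sd_metab,
    loghr_mort_bag = loghr_mort_bag, loghr_mort_mag = loghr_mort_mag,
    loghr_dem_bag = loghr_dem_bag, loghr_dem_mag = loghr_dem_mag,
    baseline_hazard_mort = baseline_hazard_mort,
    baseline_hazard_dem = baseline_hazard_dem,
    covariate_effects = covariate_effects,
    feature_mode = feature_mode, volume_dim = as.integer(volume_dim),
    bmi_center = 26.5,
    w_brain = as.numeric(w_brain), w_metab = as.numeric(w_metab),
    seed = as.integer(seed)
  ), class = "generator_truth")
}

draw_ages <- function(spec) {
  if (spec$age_shape == "uniform") {
    stats::runif(spec$n, spec$age_low, spec$age_high)
  } else {
    rtruncnorm(spec$n, spec$age_mean, spec$age_sd, spec$age_low, spec$age_high)
  }
}

# Exponential event times with administrative censoring; returns time/event.
draw_survival <- function(n, baseline, loghr, followup) {
  rate <- baseline * exp(loghr)
  t <- stats::rexp(n, rate)
  event <- as.integer(t <= followup)
  time <- pmin(t, followup)
  time[time <= 0] <- .Machine$double.eps
  list(time = time, event = event)
}

#' Generate one synthetic cohort
#'
#' Draws a participant table with the structure the downstream analyses
#' assume. Ages follow the cohort spec; the latent brain and metabolic aging
#' gaps are bivariate normal with the truth's SDs and correlation; brain
#' features are `w_brain * (age + brain_gap) + site_offset + noise` and
#' metabolites `w_metab * (age + metab_gap) + noise`; mortality and dementia
#' times come from exponential baselines multiplied by
#' `exp(loghr * gap + covariate effects)`, censored administratively at the
#' follow-up horizon. The true gaps are kept as ground-truth columns
#' (`true_brain_gap`, `true_metab_gap`) for parameter-recovery testing and
#' must not be fed to the analyses.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [generator_truth()].
#' @return A tibble (`participant_table`) with one row per participant;
#'   `brain_features` and `metabolites` are matrix columns.
#' @examples
#' tab <- generate_cohort(cohort_spec("demo", 50, 45, 85, seed = 7),
#'                        generator_truth(p = 8))
#' dim(tab$metabolites)
#' @export
generate_cohort <- function(spec, truth) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  if (!inherits(truth, "generator_truth")) stop("`truth` must be a generator_truth", call. = FALSE)
  n <- spec$n
  with_seed(derive_seed(spec$seed, "cohort", spec$name), {
    age <- draw_ages(spec)
    # bivariate normal gaps via explicit Cholesky factor
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    bg <- truth$sigma_brain_gap * z1
    mg <- truth$sigma_metab_gap * (truth$rho_gaps * z1 +
                                     sqrt(max(0, 1 - truth$rho_gaps^2)) * z2)
    site_offset <- stats::rnorm(truth$p, 0, spec$site_offset_scale)
    brain <- outer(age + bg, truth$w_brain) +
      matrix(site_offset, n, truth$p, byrow = TRUE) +
      matrix(stats::rnorm(n * truth$p, 0, truth$noise_sd_brain), n, truth$p)
    colnames(brain) <- sprintf("bf_%03d", seq_len(truth$p))
    mets <- outer(age + mg, truth$w_metab) +
      matrix(stats::rnorm(n * truth$n_metabolites, 0, truth$noise_sd_metab),
             n, truth$n_metabolites)
    colnames(mets) <- sprintf("met_%02d", seq_len(truth$n_metabolites))
    sex <- stats::rbinom(n, 1, spec$sex_frac_female)
    dm <- stats::rbinom(n, 1, spec$dm_prevalence)
    bmi <- rtruncnorm(n, 26.5, 3.8, 15, 50)
    ec <- sample(c("low", "medium", "high"), n, replace = TRUE, prob = spec$ec_probs)
    lag <- if (spec$lag_sd == 0) rep(spec$lag_mean, n) else
      stats::rnorm(n, spec$lag_mean, spec$lag_sd)
    has_blood <- stats::rbinom(n, 1, spec$blood_frac)
    ce <- truth$covariate_effects
    lp_cov <- ce["sex"] * sex + ce["dm"] * dm + ce["bmi"] * (bmi - truth$bmi_center) +
      ce["ec_low"] * (ec == "low") + ce["ec_high"] * (ec == "high")
    mort <- draw_survival(n, truth$baseline_hazard_mort,
                          truth$loghr_mort_bag * bg + truth$loghr_mort_mag * mg + lp_cov,
                          spec$followup_years)
    dem <- draw_survival(n, truth$baseline_hazard_dem,
                         truth$loghr_dem_bag * bg + truth$loghr_dem_mag * mg + lp_cov,
                         spec$followup_years)
    tab <- tibble::tibble(
      participant_id = sprintf("%s_%05d", spec$name, seq_len(n)),
      cohort = spec$name,
      age = age, sex = sex,
      brain_features = brain, metabolites = mets,
      dm = dm, bmi = bmi, ec = ec, lag_time = lag, has_blood = has_blood,
      time_mort = mort$time, event_mort = mort$event,
      time_dem = dem$time, event_dem = dem$event,
      true_brain_gap = bg, true_metab_gap = mg
    )
    attr(tab, "feature_mode") <- truth$feature_mode
    attr(tab, "volume_dim") <- truth$volume_dim
    class(tab) <- c("participant_table", class(tab))
    tab
  })
}

#' Generate a federation of cohorts
#'
#' One participant table per cohort spec, each from an independent RNG stream
#' keyed by its own seed and name, all sharing one ground truth.
#'
#' @param specs list of [cohort_spec()] with distinct names.
#' @param truth a [generator_truth()].
#' @return Named list of participant tables.
#' @export
generate_federation <- function(specs, truth) {
  if (length(specs) < 1) stop("need at least one cohort spec", call. = FALSE)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate cohort names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "),
                               call. = FALSE)
  stats::setNames(lapply(specs, generate_cohort, truth = truth), nms)
}

#' Filter a cohort to its analysis set
#'
#' Keeps participants with a blood sample, absolute lag time strictly below
#' `max_abs_lag` years, and no missing values in the analysis covariates.
#' Row order is preserved; the result may be empty.
#'
#' @param table a participant table.
#' @param max_abs_lag years; the default mirrors the < 7-year eligibility rule.
#' @param require_blood whether to restrict to rows with a blood sample.
#' @return The filtered table.
#' @export
select_analysis_set <- function(table, max_abs_lag = 7, require_blood = TRUE) {
  if (!"lag_time" %in% names(table)) stop("`lag_time` column missing", call. = FALSE)
  keep <- abs(table$lag_time) < max_abs_lag
  if (require_blood && "has_blood" %in% names(table)) keep <- keep & table$has_blood == 1
  vars <- intersect(c("age", "sex", "dm", "bmi", "ec", "lag_time"), names(table))
  cc <- stats::complete.cases(as.data.frame(table[vars]))
  table[keep & cc, , drop = FALSE]
}

#' Random train/validation split by participant
#'
#' Disjoint partition of rows by `participant_id`; the training part gets
#' `round(n * train_frac)` participants, validation the remainder.
#' Reproducible per seed.
#'
#' @param table a participant table with `n >= 2` rows.
#' @param train_frac proportion in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return List with elements `train` and `val`.
#' @export
split_train_val <- function(table, train_frac = 0.8, seed = 1L) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  ids <- unique(table$participant_id)
  k <- length(ids)
  n_train <- round(k * train_frac)
  n_train <- max(1L, min(k - 1L, n_train))
  train_ids <- with_seed(derive_seed(seed, "split"), sample(ids, n_train))
  list(train = table[table$participant_id %in% train_ids, , drop = FALSE],
       val = table[!table$participant_id %in% train_ids, , drop = FALSE])
}

#' Duplicate rows to mimic repeat scans
#'
#' Optional stand-in for longitudinal imaging: each participant's row is
#' repeated `repeats` times with fresh small feature noise, enlarging the
#' training set without new participants. Ground-truth gaps, covariates and
#' outcomes are copied unchanged.
#'
#' @param table a participant table.
#' @param repeats total copies per row (>= 1; 1 returns the table unchanged).
#' @param feature_noise_sd SD of the extra noise added to brain features of
#'   the duplicated rows.
#' @param seed integer seed.
#' @return The augmented table.
#' @export
augment_longitudinal <- function(table, repeats = 2, feature_noise_sd = 0.5, seed = 1L) {
  if (repeats < 1 || repeats != round(repeats)) stop("`repeats` must be an integer >= 1", call. = FALSE)
  if (repeats == 1) return(table)
  out <- table[rep(seq_len(nrow(table)), each = repeats), , drop = FALSE]
  extra <- which(rep(seq_len(repeats), times = nrow(table)) > 1)
  with_seed(derive_seed(seed, "longitudinal"), {
    bf <- out$brain_features
    bf[extra, ] <- bf[extra, ] +
      matrix(stats::rnorm(length(extra) * ncol(bf), 0, feature_noise_sd),
             length(extra), ncol(bf))
    out$brain_features <- bf
  })
  out
}
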