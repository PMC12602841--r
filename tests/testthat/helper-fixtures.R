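# Shared fixture builders; everything is generated in code at test time.

tiny_truth <- function(p = 8, ...) {
  generator_truth(p = p, seed = 424242, ...)
}

tiny_cohort <- function(name = "a", n = 60, lo = 45, hi = 85, seed = 1, ...) {
  cohort_spec(name, n, lo, hi, seed = seed, blood_frac = 1, ...)
}

# A scored analysis world where the measured scores are the latent truth
# plus independent measurement noise: brainage = age + brain_gap + e,
# metaboage via the synthetic pseudo-inverse scorer. Used by association
# and survival tests that probe the estimators, not the predictor.
scored_world <- function(n_per = c(500, 500), seed = 1, truth = tiny_truth(),
                         score_noise_sd = 1, ...) {
  specs <- lapply(seq_along(n_per), function(i) {
    tiny_cohort(paste0("c", i), n_per[i], 45 + 5 * i, 85 + 5 * i,
                seed = seed * 100 + i, ...)
  })
  tabs <- generate_federation(specs, truth)
  ma <- synthetic_metaboage_scorer(truth)
  mh <- synthetic_metabohealth_scorer(truth)
  lapply(tabs, function(tab) {
    noise <- fedbioage:::with_seed(
      fedbioage:::derive_seed(seed, "score_noise", tab$cohort[1]),
      stats::rnorm(nrow(tab), 0, score_noise_sd))
    tab$brainage <- tab$age + tab$true_brain_gap + noise
    tab$metaboage <- score_metabolite_model(ma, tab)
    tab$metabohealth <- score_metabolite_model(mh, tab)
    compute_gaps(tab)
  })
}

# Independent Breslow partial log-likelihood written out naively (double
# loop over events and risk sets); the oracle for the Cox fitter.
naive_cox_loglik <- function(beta, time, event, X) {
  lp <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}
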