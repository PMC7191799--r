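# full-scale study fixture: 100-patient synthetic cohort simulated under all
# four interval variants x both controller approaches with fivefold
# by-patient cross-validated transition models; computed once and shared
# between the audit, trend and acceptance tests

study_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(cohort_spec())   # 100 patients, default spec
    set <- fit_si_transitions(cohort_profiles(cohort), horizons = 1:6,
                              folds = 5, seed = 202, min_pairs = 100)
    variants <- list(
      "STAR-3H" = star_config(max_interval = 3),
      "STAR-4H" = star_config(max_interval = 4),
      "STAR-5H" = star_config(max_interval = 5),
      "STAR-6H" = star_config(max_interval = 6),
      "STAR-ULC-3H" = star_config(max_interval = 3, ulc = TRUE),
      "STAR-ULC-4H" = star_config(max_interval = 4, ulc = TRUE),
      "STAR-ULC-5H" = star_config(max_interval = 5, ulc = TRUE),
      "STAR-ULC-6H" = star_config(max_interval = 6, ulc = TRUE))
    arms <- run_cohort(cohort, variants, set)
    cache <<- list(cohort = cohort, set = set, variants = variants,
                   arms = arms, metrics = lapply(arms, compute_metrics))
    cache
  }
})
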