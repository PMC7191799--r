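# shared fixtures and independent oracles for the test suite

fx_params <- icing_params()

# plasma/interstitial insulin equilibrium for a continuous infusion (U/h),
# solved independently of the integrator
eq_insulin <- function(rate_U_h, p = fx_params) {
  q_of <- function(I) stats::uniroot(function(Q)
    p[["n_I"]] * (I - Q) - p[["n_C"]] * Q / (1 + p[["alpha_G"]] * Q),
    c(0, I + 1))$root
  res <- function(I) {
    Q <- q_of(I)
    p[["n_K"]] * I + p[["n_L"]] * I / (1 + p[["alpha_I"]] * I) +
      p[["n_I"]] * (I - Q) - rate_U_h * 1000 / 60 / p[["V_I"]]
  }
  I <- stats::uniroot(res, c(1e-9, 1e5))$root
  c(I = I, Q = q_of(I))
}

# noise-free synthetic episode with hourly BG measurements
synth_episode <- function(si, insulin_units = 3, bg0 = 9, gf = 65,
                          id = "S1", params = fx_params) {
  hours <- length(si)
  sched <- input_schedule(
    insulin_boluses = if (insulin_units > 0)
      data.frame(time_h = 0:(hours - 1), units = insulin_units) else NULL,
    enteral = data.frame(time_h = 0, pct_gf = 100),
    goal_feed = gf)
  st <- init_state(bg0, gf, params)
  sim <- simulate_icing(st, params, si, sched, hours)
  meas <- data.frame(time_h = 0:hours,
                     bg_mmol_L = as.numeric(bg_at_hours(sim, 0:hours)))
  list(episode = episode_record(id, meas, sched), sim = sim, inputs = sched)
}

# synthetic transition pairs: log-normal current SI with a log-normal step
synth_pairs <- function(n, seed = 1, horizon = 1, mu = log(6.5e-4),
                        sd = 0.3, step_sd = 0.15) {
  set.seed(seed)
  x <- exp(rnorm(n, mu, sd))
  y <- x * exp(rnorm(n, 0, step_sd))
  data.frame(si_now = x, si_future = y, horizon = horizon,
             patient_id = "syn", stringsAsFactors = FALSE)
}

# direct double-loop evaluation of the kernel sum: joint probability as the
# average of per-point product Gaussians with positive-domain normalisers,
# conditioned by dividing by the marginal in the current-SI slot
kde_oracle_conditional <- function(model, si_now, si_future) {
  x <- log(si_now)
  wnum <- vapply(seq_len(model$n), function(i)
    stats::dnorm(x, model$cx[i], model$sx[i]) / model$px[i], 0)
  den <- sum(wnum)
  vapply(log(si_future), function(yy) {
    s <- 0
    for (i in seq_len(model$n))
      s <- s + wnum[i] * stats::dnorm(yy, model$cy[i], model$sy[i]) / model$py[i]
    s / den
  }, 0)
}

# trapezoid integral of the conditional density over a wide log-SI grid
kde_cond_integral <- function(model, si_now) {
  gl <- seq(min(model$cy) - 10 * max(model$sy),
            max(model$cy) + 10 * max(model$sy),
            by = min(model$sy) / 2)
  d <- conditional_density(model, si_now, exp(gl))
  sum((d[-1] + d[-length(d)]) / 2 * diff(gl))
}

# near-deterministic identity transition models (future SI = current SI)
identity_models <- function(horizons = 1:6, n = 400, lo = 2e-4, hi = 2e-3) {
  x <- exp(seq(log(lo), log(hi), length.out = n))
  ms <- lapply(horizons, function(h)
    fit_si_transition(data.frame(si_now = x, si_future = x, horizon = h,
                                 patient_id = "id"),
                      min_pairs = n, k = 2))
  names(ms) <- as.character(horizons)
  ms
}

# small fitted cohort + models reused by controller/trial unit tests
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(cohort_spec(n_patients = 12, seed = 4L))
    set <- fit_si_transitions(cohort_profiles(cohort), folds = 1,
                              seed = 1, min_pairs = 30)
    cache <<- list(cohort = cohort, models = set$folds[[1]]$models,
                   set = set)
    cache
  }
})
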