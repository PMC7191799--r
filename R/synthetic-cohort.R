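## Synthetic virtual-patient cohorts: hourly SI traces with heavy-tailed
## hour-to-hour variability (AR(1) in log space plus occasional abrupt
## multiplicative shifts), hyperglycaemic starting BG, and per-patient goal
## feeds, so the whole toolchain is testable without clinical data.

#' Cohort generation specification
#'
#' Defaults describe an ICU glycaemic-control cohort at desk scale: episode
#' lengths log-normal around a 24 h median (truncated above 10 h per the
#' episode inclusion rule), starting BG log-normal around 9 mmol/L truncated
#' above 7 mmol/L, per-patient goal feeds around 65 mmol glucose/h, and a
#' log-space AR(1) SI process with occasional abrupt sensitivity shifts
#' (jumps) that drive the hypoglycaemic risk of long unobserved intervals.
#'
#' @param n_patients number of virtual patients.
#' @param episode_meanlog,episode_sdlog log-normal episode length (h).
#' @param episode_min,episode_max truncation of episode length (h);
#'   \code{episode_min} must be > 10 (inclusion rule).
#' @param bg0_meanlog,bg0_sdlog log-normal starting BG (mmol/L).
#' @param bg0_min,bg0_max truncation of starting BG; \code{bg0_min} > 7.
#' @param si_mu_log cohort mean of log SI (log L/(mU min)).
#' @param si_sigma_inter inter-patient SD of the per-patient log-SI level.
#' @param si_ar hourly AR(1) coefficient of log SI (< 1 for stationarity).
#' @param si_innovation_sd hourly innovation SD of log SI.
#' @param jump_prob per-hour probability of an abrupt SI shift.
#' @param jump_sd SD of the log-magnitude of a shift.
#' @param gf_mean,gf_sd,gf_min,gf_max per-patient goal feed (mmol/h).
#' @param seed default RNG seed carried by the spec.
#' @return a \code{cohort_spec} object.
#' @export
cohort_spec <- function(n_patients = 100,
                        episode_meanlog = log(24), episode_sdlog = 0.35,
                        episode_min = 11, episode_max = 72,
                        bg0_meanlog = log(9.2), bg0_sdlog = 0.2,
                        bg0_min = 7.05, bg0_max = 18,
                        si_mu_log = log(6.5e-4), si_sigma_inter = 0.3,
                        si_ar = 0.97, si_innovation_sd = 0.15,
                        jump_prob = 0.007, jump_sd = 0.7,
                        gf_mean = 65, gf_sd = 10, gf_min = 40, gf_max = 90,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               episode_meanlog = episode_meanlog, episode_sdlog = episode_sdlog,
               episode_min = episode_min, episode_max = episode_max,
               bg0_meanlog = bg0_meanlog, bg0_sdlog = bg0_sdlog,
               bg0_min = bg0_min, bg0_max = bg0_max,
               si_mu_log = si_mu_log, si_sigma_inter = si_sigma_inter,
               si_ar = si_ar, si_innovation_sd = si_innovation_sd,
               jump_prob = jump_prob, jump_sd = jump_sd,
               gf_mean = gf_mean, gf_sd = gf_sd, gf_min = gf_min,
               gf_max = gf_max, seed = as.integer(seed))
  if (spec$n_patients < 1) stopf("n_patients must be >= 1")
  if (spec$episode_min <= 10 || spec$episode_max < spec$episode_min)
    stopf("episode lengths must satisfy 10 < episode_min <= episode_max")
  if (spec$bg0_min <= 7) stopf("bg0_min must exceed 7 mmol/L (inclusion rule)")
  if (spec$si_innovation_sd < 0 || spec$jump_sd < 0 || spec$si_sigma_inter < 0)
    stopf("standard deviations must be >= 0")
  if (spec$jump_prob < 0 || spec$jump_prob > 1)
    stopf("jump_prob must be in [0, 1]")
  if (abs(spec$si_ar) >= 1) stopf("si_ar must satisfy |si_ar| < 1")
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic virtual-patient cohort
#'
#' Each patient carries a strictly positive hourly true-SI trace (the
#' digital-twin identity) extended 6 h past the episode end so the last
#' treatment interval may overrun, a starting BG > 7 mmol/L, an episode
#' length > 10 h, and a goal feed. Reproducible for a fixed seed.
#'
#' @param spec \code{\link{cohort_spec}}.
#' @param seed RNG seed; defaults to the spec's seed.
#' @return a \code{star_cohort}: list of \code{virtual_patient} objects,
#'   each with fields \code{patient_id}, \code{si_trace}, \code{bg0},
#'   \code{goal_feed}, \code{episode_hours}.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    len <- round(rtrunc(1, function(n) rlnorm(n, spec$episode_meanlog,
                                              spec$episode_sdlog),
                        spec$episode_min, spec$episode_max))
    bg0 <- rtrunc(1, function(n) rlnorm(n, spec$bg0_meanlog, spec$bg0_sdlog),
                  spec$bg0_min, spec$bg0_max)
    gf <- rtrunc(1, function(n) rnorm(n, spec$gf_mean, spec$gf_sd),
                 spec$gf_min, spec$gf_max)
    n_h <- len + 6L
    mu_p <- spec$si_mu_log + rnorm(1, 0, spec$si_sigma_inter)
    sd_stat <- spec$si_innovation_sd / sqrt(1 - spec$si_ar^2)
    z <- numeric(n_h)
    z[1] <- mu_p + rnorm(1, 0, sd_stat)
    if (n_h > 1) for (t in 2:n_h) {
      jump <- if (runif(1) < spec$jump_prob) rnorm(1, 0, spec$jump_sd) else 0
      z[t] <- mu_p + spec$si_ar * (z[t - 1] - mu_p) +
        rnorm(1, 0, spec$si_innovation_sd) + jump
    }
    structure(list(patient_id = sprintf("P%03d", i), si_trace = exp(z),
                   bg0 = bg0, goal_feed = gf, episode_hours = len),
              class = "virtual_patient")
  })
  structure(patients, class = "star_cohort", spec = spec, seed = seed)
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf(
    "virtual patient %s: %d h episode, BG0 %.1f mmol/L, goal feed %.0f mmol/h, median SI %.2e\n",
    x$patient_id, x$episode_hours, x$bg0, x$goal_feed,
    stats::median(x$si_trace)))
  invisible(x)
}

#' @export
print.star_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d virtual patients, %d total episode hours\n",
              length(x), sum(vapply(x, `[[`, 0, "episode_hours"))))
  invisible(x)
}

#' Apply the episode inclusion rule
#'
#' Keeps episodes strictly longer than 10 h with starting BG strictly above
#' 7.0 mmol/L; counts of exclusions by reason are attached.
#'
#' @param episodes a \code{star_cohort} or list of objects with
#'   \code{episode_hours} and \code{bg0} fields.
#' @return the kept episodes (class preserved), with attribute
#'   \code{excluded} = named counts \code{short}, \code{low_bg0}.
#' @export
filter_episodes <- function(episodes) {
  len <- vapply(episodes, `[[`, 0, "episode_hours")
  bg0 <- vapply(episodes, `[[`, 0, "bg0")
  keep <- len > 10 & bg0 > 7.0
  out <- episodes[keep]
  attributes(out) <- c(attributes(out),
                       list(excluded = c(short = sum(len <= 10),
                                         low_bg0 = sum(len > 10 & bg0 <= 7.0))))
  class(out) <- class(episodes)
  out
}

#' True SI profiles of a cohort
#'
#' Extracts each patient's hourly SI trace over its episode as an
#' \code{si_profile}, the training material for transition-model fitting in
#' fully synthetic studies.
#'
#' @param cohort \code{star_cohort}.
#' @return list of \code{\link{si_profile}} objects.
#' @export
cohort_profiles <- function(cohort) {
  lapply(cohort, function(p)
    si_profile(p$si_trace[seq_len(p$episode_hours)], p$patient_id))
}
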