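## Closed-loop virtual trials: replay a virtual patient's true SI trace
## against a controller configuration under ideal protocol compliance,
## selecting the longest offered treatment interval at every measurement.

# controller-side identification of a constant SI over the elapsed interval:
# one-dimensional least squares of the model-predicted BG at the next
# measurement against the measured value, from the controller's propagated
# state. Returns NA when the interval carries no insulin information.
fit_interval_si <- function(state, params, inputs, L, bg_next,
                            si_bounds = c(1e-6, 1e-2), q_tol = 0.5,
                            step_min = 0.5) {
  endg <- function(si) {
    sim <- simulate_icing(state, params, rep(si, L), inputs, L,
                          step_min = step_min)
    c(sim$G[nrow(sim)], max(sim$Q))
  }
  probe <- endg(4.5e-4)
  if (probe[2] < q_tol) return(NA_real_)
  obj <- function(ls) (endg(exp(ls))[1] - bg_next)^2
  opt <- stats::optimize(obj, log(si_bounds), tol = 1e-9)
  si <- exp(opt$minimum)
  if ((endg(0)[1] - bg_next)^2 <= opt$objective) si <- 0
  si
}

#' Run one closed-loop virtual-trial episode
#'
#' Replays the patient's true hourly SI trace against the controller: at
#' each measurement the (noise-free) model BG is read, the controller
#' re-identifies SI from the data it has seen, selects a treatment and the
#' longest offered interval, and the true state is advanced with the true SI
#' trace until the next measurement. The final interval may overrun the
#' nominal episode end, so arms can differ slightly in glycaemic-control
#' hours.
#'
#' @param patient a \code{virtual_patient}.
#' @param config \code{\link{star_config}}.
#' @param models per-horizon \code{si_transition} list for this patient
#'   (from a fold excluding the patient), or an \code{si_transition_set}.
#' @param params \code{\link{icing_params}}.
#' @param step_min integration step (minutes).
#' @param noise_sd measurement-noise SD (mmol/L); default 0, the ideal-
#'   compliance condition.
#' @return a \code{trial_record}: list with the per-measurement \code{rows}
#'   (time, measured BG, treatment, prediction band, fallback flag), the
#'   continuous \code{trajectory}, hourly-resampled BG, and totals
#'   \code{gc_hours}, \code{n_measures}.
#' @export
run_episode <- function(patient, config, models, params = icing_params(),
                        step_min = 0.5, noise_sd = 0) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(config, "star_config"))
  if (inherits(models, "si_transition_set"))
    models <- models_for_patient(models, patient$patient_id)
  gf <- patient$goal_feed
  ep_h <- patient$episode_hours
  if (length(patient$si_trace) < ep_h + config$max_interval - 1)
    stopf("SI trace does not cover the episode (plus possible overrun)")

  true_state <- init_state(patient$bg0, gf, params)
  ctrl_state <- true_state
  prev <- neutral_treatment()
  m1 <- models[["1"]] %||% models[[1]]
  si_now <- exp(stats::median(m1$cx))   # population prior before any data
  traj <- NULL
  rows <- list()
  t <- 0L

  while (t < ep_h) {
    bg_meas <- true_state$y[["G"]]
    if (noise_sd > 0) bg_meas <- max(1, bg_meas + rnorm(1, 0, noise_sd))
    ctrl_state$y[["G"]] <- bg_meas
    sel <- select_treatment(si_now, ctrl_state, prev, models, config,
                            params, gf, step_min)
    trt <- sel$treatment
    L <- trt$interval
    inputs <- input_schedule(
      insulin_boluses = if (trt$insulin > 0)
        data.frame(time_h = t + 0:(L - 1), units = trt$insulin) else NULL,
      enteral = data.frame(time_h = t, pct_gf = trt$nutrition),
      goal_feed = gf)
    si_true <- patient$si_trace[(t + 1):(t + L)]
    sim <- simulate_icing(true_state, params, si_true, inputs, L,
                          step_min = step_min)
    rows[[length(rows) + 1]] <- data.frame(
      time_h = t, bg = bg_meas, insulin = trt$insulin,
      nutrition = trt$nutrition, interval = L,
      bg_low_pred = sel$band$bg_low, bg_high_pred = sel$band$bg_high,
      si_used = si_now, fallback = sel$fallback, relaxed = sel$relaxed)
    traj <- if (is.null(traj)) sim else rbind(traj, sim[-1, ])
    n <- nrow(sim)
    new_true <- icing_state(sim$G[n], sim$I[n], sim$Q[n], sim$P1[n],
                            sim$P2[n], t = t + L)
    bg_next <- new_true$y[["G"]]
    if (noise_sd > 0) bg_next <- max(1, bg_next + rnorm(1, 0, noise_sd))
    si_hat <- fit_interval_si(ctrl_state, params, inputs, L, bg_next,
                              step_min = step_min)
    si_prop <- if (is.na(si_hat)) si_now else si_hat
    csim <- simulate_icing(ctrl_state, params, rep(si_prop, L), inputs, L,
                           step_min = step_min)
    cn <- nrow(csim)
    ctrl_state <- icing_state(csim$G[cn], csim$I[cn], csim$Q[cn],
                              csim$P1[cn], csim$P2[cn], t = t + L)
    if (!is.na(si_hat)) si_now <- max(si_hat, 1e-6)
    true_state <- new_true
    prev <- trt
    t <- t + L
  }
  rows <- do.call(rbind, rows)
  hourly <- bg_at_hours(traj, 0:t)
  structure(list(patient_id = patient$patient_id, rows = rows,
                 trajectory = traj, hourly_bg = hourly,
                 gc_hours = t, n_measures = nrow(rows),
                 episode_hours = ep_h,
                 n_fallback = sum(rows$fallback)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "virtual trial of %s: %d GC hours, %d measurements, median BG %.1f mmol/L\n",
    x$patient_id, x$gc_hours, x$n_measures, stats::median(x$hourly_bg)))
  invisible(x)
}

#' Run a cohort of virtual trials under several controller variants
#'
#' Simulates every patient under every controller configuration with the
#' same true SI trace (paired design). Per-episode failures are collected,
#' not fatal to the cohort.
#'
#' @param cohort \code{star_cohort}.
#' @param configs named list of \code{star_config} variants.
#' @param models an \code{si_transition_set} (per-patient fold models) or a
#'   plain per-horizon model list applied to all patients.
#' @param params \code{\link{icing_params}}.
#' @param step_min integration step (minutes).
#' @param progress print progress lines.
#' @return named list (one element per variant) of \code{trial_record}
#'   lists; attribute \code{failures} holds any per-episode error messages.
#' @export
run_cohort <- function(cohort, configs, models, params = icing_params(),
                       step_min = 0.5, progress = FALSE) {
  stopifnot(inherits(cohort, "star_cohort"))
  if (inherits(configs, "star_config")) configs <- list(variant = configs)
  failures <- list()
  out <- lapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    recs <- lapply(cohort, function(pat) {
      r <- tryCatch(run_episode(pat, cfg, models, params, step_min),
                    error = function(e) {
                      failures[[length(failures) + 1]] <<- sprintf(
                        "%s / %s: %s", names(configs)[ci], pat$patient_id,
                        conditionMessage(e))
                      NULL
                    })
      r
    })
    if (progress)
      message(sprintf("variant %s: %d/%d episodes completed",
                      names(configs)[ci],
                      sum(!vapply(recs, is.null, TRUE)), length(recs)))
    Filter(Negate(is.null), recs)
  })
  names(out) <- names(configs)
  attr(out, "failures") <- failures
  out
}
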