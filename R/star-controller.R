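## STAR risk-based dosing: candidate treatment enumeration, 5th-95th
## percentile BG band prediction, and treatment/interval selection under the
## Standard and Upper-Limit-Controlled (ULC) rules.

#' Controller configuration
#'
#' All printed protocol constants of the STAR framework, exposed as named
#' defaults: the 4.4-8.0 mmol/L target band, 5\% hypoglycaemic risk level,
#' insulin cap (6 U/h default, configurable to 8) with a maximum +2 U/h step
#' between successive interventions, nutrition floor of 30 \%GF with a
#' maximum -30 \%GF step, and the treatment-interval ceiling. The ULC
#' variant additionally requires the predicted 95th-percentile BG at interval
#' end to stay below 8.5 mmol/L for a treatment to be considered.
#'
#' @param band_lo,band_hi target band limits (mmol/L).
#' @param risk_level predicted probability allowed below \code{band_lo}
#'   (fraction; the 5th percentile of predicted BG is held at or above the
#'   band floor).
#' @param insulin_max maximum insulin rate (U/h).
#' @param insulin_step_up_max maximum increase over the previous insulin
#'   rate (U/h).
#' @param insulin_grid_step insulin grid increment (U/h).
#' @param nutrition_min nutrition floor (\%GF).
#' @param nutrition_step_down_max maximum decrease over the previous
#'   nutrition rate (\%GF).
#' @param nutrition_grid_step nutrition grid increment (\%GF).
#' @param max_interval longest treatment interval offered (h, 1-6).
#' @param ulc enable the Upper-Limit-Controlled rule.
#' @param ulc_limit 95th-percentile BG ceiling under ULC (mmol/L).
#' @param avail_slack Standard-mode slack above \code{band_hi} (mmol/L) on
#'   the predicted 95th-percentile BG for a longer-than-1 h interval to be
#'   offered; ULC uses no slack (its own ceiling applies).
#' @return a \code{star_config} object.
#' @export
star_config <- function(band_lo = 4.4, band_hi = 8.0, risk_level = 0.05,
                        insulin_max = 6, insulin_step_up_max = 2,
                        insulin_grid_step = 0.5,
                        nutrition_min = 30, nutrition_step_down_max = 30,
                        nutrition_grid_step = 5,
                        max_interval = 3, ulc = FALSE, ulc_limit = 8.5,
                        avail_slack = 2.0) {
  cfg <- list(band_lo = band_lo, band_hi = band_hi, risk_level = risk_level,
              insulin_max = insulin_max,
              insulin_step_up_max = insulin_step_up_max,
              insulin_grid_step = insulin_grid_step,
              nutrition_min = nutrition_min,
              nutrition_step_down_max = nutrition_step_down_max,
              nutrition_grid_step = nutrition_grid_step,
              max_interval = as.integer(max_interval), ulc = isTRUE(ulc),
              ulc_limit = ulc_limit, avail_slack = avail_slack)
  if (!(band_lo < band_hi && band_hi < ulc_limit))
    stopf("config must satisfy band_lo < band_hi < ulc_limit")
  if (!(max_interval %in% 1:6)) stopf("max_interval must be in 1..6")
  if (insulin_grid_step <= 0 || nutrition_grid_step <= 0)
    stopf("grid steps must be positive")
  if (risk_level <= 0 || risk_level >= 0.5) stopf("risk_level must be in (0, 0.5)")
  structure(cfg, class = "star_config")
}

#' @export
print.star_config <- function(x, ...) {
  cat(sprintf(
    "STAR config (%s): band %.1f-%.1f mmol/L, insulin <= %g U/h (+%g max step),\n  nutrition %g-100 %%GF (-%g max step), intervals 1-%d h%s\n",
    if (x$ulc) "Upper Limit Controlled" else "Standard",
    x$band_lo, x$band_hi, x$insulin_max, x$insulin_step_up_max,
    x$nutrition_min, x$nutrition_step_down_max, x$max_interval,
    if (x$ulc) sprintf(", 95th pct BG < %.1f mmol/L", x$ulc_limit) else ""))
  invisible(x)
}

#' Treatment constructor
#'
#' @param insulin insulin rate (U/h), administered as an hourly bolus of the
#'   same number of units at the top of each hour of the interval.
#' @param nutrition enteral nutrition (\%GF).
#' @param interval treatment interval (h).
#' @return a \code{star_treatment} object.
#' @export
star_treatment <- function(insulin, nutrition, interval = 1L) {
  stopifnot(insulin >= 0, nutrition >= 0, nutrition <= 100,
            interval >= 1)
  structure(list(insulin = insulin, nutrition = nutrition,
                 interval = as.integer(interval)),
            class = "star_treatment")
}

# neutral prior used at episode start
neutral_treatment <- function() star_treatment(0, 100, 1L)

#' Enumerate admissible candidate treatments
#'
#' All (insulin, nutrition, interval) combinations on the configured grids
#' that satisfy the step constraints relative to the previous treatment:
#' insulin at most \code{previous + insulin_step_up_max} and at most
#' \code{insulin_max}; nutrition between
#' \code{max(nutrition_min, previous - nutrition_step_down_max)} and 100
#' \%GF. Repeating the previous insulin rate is always admissible, so the
#' list is never empty.
#'
#' @param previous previous \code{star_treatment} (use
#'   \code{star_treatment(0, 100)} at episode start).
#' @param config \code{star_config}.
#' @return data.frame with columns \code{insulin}, \code{nutrition},
#'   \code{interval}.
#' @export
candidate_treatments <- function(previous, config) {
  stopifnot(inherits(previous, "star_treatment"),
            inherits(config, "star_config"))
  ins_hi <- min(config$insulin_max,
                previous$insulin + config$insulin_step_up_max)
  ins <- seq(0, ins_hi, by = config$insulin_grid_step)
  nut_lo <- max(config$nutrition_min,
                previous$nutrition - config$nutrition_step_down_max)
  nut <- rev(seq(100, nut_lo, by = -config$nutrition_grid_step))
  out <- expand.grid(insulin = ins, nutrition = nut,
                     interval = seq_len(config$max_interval),
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$interval, out$insulin, out$nutrition), , drop = FALSE]
}

# Dosing objective: fraction of the predicted interval-end BG band
# [bg_lo, bg_hi] lying inside the target band (intersection length divided
# by prediction-band width; a collapsed band counts 1 when inside the
# target, 0 otherwise), plus the distance from the prediction band to the
# target band as a secondary criterion for fully out-of-band candidates.
band_overlap <- function(bg_lo, bg_hi, band_lo, band_hi) {
  w <- bg_hi - bg_lo
  inter <- pmax(0, pmin(bg_hi, band_hi) - pmax(bg_lo, band_lo))
  mid <- (bg_lo + bg_hi) / 2
  point_in <- mid >= band_lo & mid <= band_hi
  overlap <- ifelse(w > 1e-9, inter / w, as.numeric(point_in))
  dist <- pmax(0, band_lo - bg_hi) + pmax(0, bg_lo - band_hi)
  list(overlap = overlap, dist = dist)
}

# hour-wise 5th/95th percentile SI paths for horizons 1..L, conditional on
# si_now at the matching horizon
si_percentile_paths <- function(si_now, models, L, probs = c(5, 95)) {
  lo <- numeric(L); hi <- numeric(L); extra <- FALSE
  for (h in seq_len(L)) {
    m <- if (!is.null(names(models))) models[[as.character(h)]]
         else if (h <= length(models)) models[[h]]
    if (is.null(m)) stopf("no transition model available for horizon %d h", h)
    q <- conditional_percentiles(m, si_now, probs)
    lo[h] <- q[[1]]; hi[h] <- q[[2]]
    extra <- extra || isTRUE(attr(q, "extrapolation"))
  }
  list(lo = lo, hi = hi, extrapolation = extra)
}

#' Predict the 5th-95th percentile BG band for a treatment
#'
#' The hour-wise 5th and 95th percentile SI trajectories (each conditional
#' on \code{si_now} at the matching horizon) are fed through the ICING model
#' under the candidate treatment: the lower-percentile SI path yields the
#' upper BG bound and vice versa (BG is monotonically non-increasing in SI).
#' Insulin is administered as hourly boluses; nutrition is constant over the
#' interval.
#'
#' @param si_now current identified SI (L/(mU min)).
#' @param treatment \code{star_treatment}.
#' @param state current \code{icing_state}.
#' @param models list of \code{si_transition} models indexed by horizon
#'   ("1".."6").
#' @param params \code{icing_params}.
#' @param goal_feed goal feed (mmol/h) defining 100 \%GF.
#' @param step_min integration step (minutes).
#' @return a \code{prediction_band}: list with the SI percentile paths,
#'   hourly BG bounds (\code{bg_hourly_lo}, \code{bg_hourly_hi}) and the
#'   interval-end bounds \code{bg_low}, \code{bg_high}.
#' @export
predict_band <- function(si_now, treatment, state, models, params,
                         goal_feed, step_min = 0.5) {
  stopifnot(inherits(treatment, "star_treatment"),
            inherits(state, "icing_state"))
  if (!is_number(si_now) || si_now <= 0) stopf("si_now must be > 0")
  L <- treatment$interval
  paths <- si_percentile_paths(si_now, models, L)
  feed <- treatment$nutrition / 100 * goal_feed
  bb <- band_batch_cpp(state$y, as.numeric(params),
                       si_path_a = paths$lo, si_path_b = paths$hi,
                       insulin_U_h = treatment$insulin, feed_mmol_h = feed,
                       step_min = step_min)
  bg_hi <- as.numeric(bb$bg_a)   # low SI path -> high BG
  bg_lo <- as.numeric(bb$bg_b)   # high SI path -> low BG
  structure(list(interval = L,
                 si_low_path = paths$lo, si_high_path = paths$hi,
                 bg_hourly_lo = bg_lo, bg_hourly_hi = bg_hi,
                 bg_low = bg_lo[L], bg_high = bg_hi[L],
                 extrapolation = paths$extrapolation),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf("predicted BG band over %d h: [%.2f, %.2f] mmol/L at interval end\n",
              x$interval, x$bg_low, x$bg_high))
  invisible(x)
}

#' Select the treatment and interval per the STAR risk-based rules
#'
#' Enumerates candidate treatments, predicts the 5th-95th percentile BG band
#' for each, and selects per protocol: the predicted 5th-percentile BG must
#' stay at or above the band floor at every intermediate hour and at
#' interval end (the pre-set hypoglycaemic risk level); under ULC the
#' predicted 95th-percentile BG at interval end must additionally stay below
#' \code{ulc_limit}. Intervals are considered from the longest down and the
#' longest interval with an admissible candidate is taken (the virtual-trial
#' convention); a longer-than-1 h interval is only offered if an admissible
#' candidate keeps the predicted 95th-percentile BG within
#' \code{band_hi + avail_slack} (Standard) or \code{ulc_limit} (ULC). Among
#' admissible candidates, nutrition is only reduced if insulin alone is not
#' sufficient: the highest admissible feed level is taken first, and at that
#' level the objective maximises the overlap of the predicted interval-end
#' band with the target band (intersection length divided by the
#' prediction-band width, i.e. the fraction of likely BG outcomes falling in
#' band), tie-broken by smaller distance to the target band, then lower
#' insulin, then grid order.
#'
#' When the ULC ceiling is unattainable from the current state (e.g. entry
#' hyperglycaemia, where even maximal insulin and minimal feed cannot bring
#' the predicted 95th percentile under 8.5 mmol/L within one hour), the
#' interval shortens to 1 h and dosing follows the Standard rule until the
#' ceiling becomes attainable again.
#'
#' If no candidate is admissible at any interval (imminent predicted
#' hypoglycaemia), a safety fallback is returned: 1 h interval, insulin 0 or
#' the previous rate (whichever predicts the higher 5th-percentile BG), and
#' nutrition raised toward 100 \%GF; the result is flagged.
#'
#' @inheritParams predict_band
#' @param previous previous \code{star_treatment}.
#' @param config \code{star_config}.
#' @return list with elements \code{treatment} (\code{star_treatment}),
#'   \code{band} (\code{prediction_band}), \code{fallback} (logical),
#'   \code{relaxed} (logical; TRUE when a ULC decision had to revert to the
#'   Standard 1 h rule), and \code{overlap} (objective value of the
#'   selected candidate, NA for fallback).
#' @export
select_treatment <- function(si_now, state, previous, models, config,
                             params, goal_feed, step_min = 0.5) {
  stopifnot(inherits(config, "star_config"))
  L_max <- config$max_interval
  paths <- si_percentile_paths(si_now, models, L_max)
  cand1 <- candidate_treatments(previous, config)
  cand1 <- cand1[cand1$interval == 1L, c("insulin", "nutrition")]
  feed_of <- function(nut) nut / 100 * goal_feed

  attempt <- function(intervals, ulc_mode) {
    for (L in intervals) {
      bb <- band_batch_cpp(state$y, as.numeric(params),
                           si_path_a = paths$lo[seq_len(L)],
                           si_path_b = paths$hi[seq_len(L)],
                           insulin_U_h = cand1$insulin,
                           feed_mmol_h = feed_of(cand1$nutrition),
                           step_min = step_min)
      bg_hi <- bb$bg_a   # matrix candidates x hours, upper BG bound
      bg_lo <- bb$bg_b   # lower BG bound
      safe_lo <- apply(bg_lo >= config$band_lo - 1e-12, 1, all)
      end_hi <- bg_hi[, L]
      admissible <- if (ulc_mode) {
        safe_lo & (end_hi < config$ulc_limit)
      } else if (L > 1L) {
        safe_lo & (end_hi <= config$band_hi + config$avail_slack)
      } else {
        safe_lo
      }
      if (!any(admissible)) next
      # nutrition is reduced only if insulin alone is not sufficient: take
      # the highest feed level with an admissible candidate, then the best
      # band overlap over insulin at that level
      nut_best <- max(cand1$nutrition[admissible])
      idx <- which(admissible & cand1$nutrition == nut_best)
      end_lo <- bg_lo[idx, L]
      sc <- band_overlap(end_lo, end_hi[idx], config$band_lo, config$band_hi)
      # objective, then distance to band, then lower insulin / grid order
      best <- idx[order(-sc$overlap, sc$dist, cand1$insulin[idx])][1]
      j <- match(best, idx)
      trt <- star_treatment(cand1$insulin[best], cand1$nutrition[best], L)
      band <- structure(list(interval = L,
                             si_low_path = paths$lo[seq_len(L)],
                             si_high_path = paths$hi[seq_len(L)],
                             bg_hourly_lo = as.numeric(bg_lo[best, ]),
                             bg_hourly_hi = as.numeric(bg_hi[best, ]),
                             bg_low = bg_lo[best, L], bg_high = bg_hi[best, L],
                             extrapolation = paths$extrapolation),
                        class = "prediction_band")
      return(list(treatment = trt, band = band, fallback = FALSE,
                  relaxed = FALSE, overlap = sc$overlap[j]))
    }
    NULL
  }

  sel <- attempt(rev(seq_len(L_max)), config$ulc)
  # ULC ceiling unattainable from the current state (e.g. entry
  # hyperglycaemia): shorten to 1 h and dose per the Standard rule; the
  # ceiling re-engages once it becomes attainable
  if (is.null(sel) && config$ulc) {
    sel <- attempt(1L, FALSE)
    if (!is.null(sel)) sel$relaxed <- TRUE
  }
  if (!is.null(sel)) return(sel)

  # safety fallback: no admissible candidate at any interval
  nut_fb <- min(100, previous$nutrition + config$nutrition_step_down_max)
  ins_opts <- unique(c(0, previous$insulin))
  bands <- lapply(ins_opts, function(i)
    predict_band(si_now, star_treatment(i, nut_fb, 1L), state, models,
                 params, goal_feed, step_min))
  pick <- which.max(vapply(bands, function(b) b$bg_low, 0))
  list(treatment = star_treatment(ins_opts[pick], nut_fb, 1L),
       band = bands[[pick]], fallback = TRUE, relaxed = FALSE,
       overlap = NA_real_)
}
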