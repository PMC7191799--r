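## ICING glucose-insulin-nutrition physiological model: parameter handling,
## state and input-schedule constructors, and the simulation front-end over
## the compiled RK4 core.

# fixed parameter order shared with the C++ core
.icing_par_names <- c("p_G", "alpha_G", "EGP", "CNS", "V_G",
                      "n_I", "n_C", "n_K", "n_L", "alpha_I",
                      "x_L", "V_I", "d1", "d2", "P_max", "u_en")

#' ICING model parameters
#'
#' Builds the parameter set of the ICING (Intensive Control Insulin-Nutrition-
#' Glucose) physiological model. The shipped default set
#' (\code{"icing-default-1"}, see
#' \code{system.file("extdata", "icing_default.txt", package = "stargc")})
#' is a literature-standard reconstruction of the clinically used model for
#' critically ill adults with endogenous insulin secretion suppressed
#' (\code{u_en = 0}). Any parameter can be overridden, either from a
#' \code{key: value} text file or by named arguments.
#'
#' @param file optional path to a \code{key: value} parameter file
#'   (\code{#} starts a comment); values not listed fall back to the default
#'   set.
#' @param ... named numeric overrides, e.g. \code{EGP = 1.2}.
#' @return an object of class \code{icing_params}: a named numeric vector
#'   with attribute \code{set} naming the base set.
#' @examples
#' p <- icing_params()
#' p2 <- icing_params(EGP = 1.2)
#' @export
icing_params <- function(file = NULL, ...) {
  defaults <- read_params_file(system.file("extdata", "icing_default.txt",
                                           package = "stargc"))
  p <- defaults
  set_name <- "icing-default-1"
  if (!is.null(file)) {
    if (!file.exists(file)) stopf("parameter file not found: %s", file)
    over <- read_params_file(file)
    p[names(over)] <- over
    set_name <- basename(file)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .icing_par_names)
    if (length(bad)) stopf("unknown ICING parameter(s): %s",
                           paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(dots)
  }
  p <- p[.icing_par_names]
  if (anyNA(p)) stopf("missing ICING parameter(s): %s",
                      paste(.icing_par_names[is.na(p)], collapse = ", "))
  strict_pos <- setdiff(.icing_par_names, c("alpha_G", "alpha_I", "u_en"))
  if (any(p[strict_pos] <= 0))
    stopf("ICING parameters must be strictly positive: %s",
          paste(strict_pos[p[strict_pos] <= 0], collapse = ", "))
  if (any(p[c("alpha_G", "alpha_I", "u_en")] < 0))
    stopf("saturation and secretion parameters must be >= 0")
  structure(p, class = "icing_params", set = set_name)
}

read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stopf("malformed parameter line: '%s'", lines[bad][1])
  vals <- vapply(kv, function(x) suppressWarnings(as.numeric(trimws(x[2]))), 0)
  nms <- vapply(kv, function(x) trimws(x[1]), "")
  if (anyNA(vals)) stopf("non-numeric parameter value for '%s'", nms[is.na(vals)][1])
  names(vals) <- nms
  vals
}

#' Write an ICING parameter file
#'
#' @param params an \code{icing_params} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_icing_params <- function(params, path) {
  stopifnot(inherits(params, "icing_params"))
  units <- c(p_G = "1/min", alpha_G = "L/mU", EGP = "mmol/min",
             CNS = "mmol/min", V_G = "L", n_I = "1/min", n_C = "1/min",
             n_K = "1/min", n_L = "1/min", alpha_I = "L/mU", x_L = "-",
             V_I = "L", d1 = "1/min", d2 = "1/min", P_max = "mmol/min",
             u_en = "mU/min")
  lines <- sprintf("%s: %.17g  # %s", names(params), as.numeric(params),
                   units[names(params)])
  writeLines(c("# ICING model parameters", lines), path)
  invisible(path)
}

#' @export
print.icing_params <- function(x, ...) {
  cat("ICING model parameters (set:", attr(x, "set"), ")\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Model state constructor
#'
#' @param G blood glucose (mmol/L).
#' @param I plasma insulin (mU/L).
#' @param Q interstitial insulin (mU/L).
#' @param P1,P2 stomach and gut glucose compartments (mmol).
#' @param t time (h).
#' @return an \code{icing_state} object.
#' @export
icing_state <- function(G, I = 0, Q = 0, P1 = 0, P2 = 0, t = 0) {
  v <- c(G = G, I = I, Q = Q, P1 = P1, P2 = P2)
  if (!all(is.finite(v)) || any(v < 0))
    stopf("all state compartments must be finite and >= 0")
  structure(list(y = v, t = t), class = "icing_state")
}

#' Initial state with gut compartments at feed equilibrium
#'
#' Sets stomach/gut glucose to the steady state of the given enteral rate and
#' zero insulin compartments, the standard starting condition of an episode
#' with an established feed and no prior insulin.
#'
#' @param bg starting blood glucose (mmol/L).
#' @param feed_mmol_h enteral glucose rate (mmol/h).
#' @param params \code{icing_params}.
#' @return an \code{icing_state}.
#' @export
init_state <- function(bg, feed_mmol_h, params = icing_params()) {
  rate_min <- feed_mmol_h / 60
  icing_state(G = bg, I = 0, Q = 0,
              P1 = rate_min / params[["d1"]],
              P2 = rate_min / params[["d2"]])
}

#' Treatment input schedule
#'
#' Collects the exogenous inputs of a simulated episode. Insulin may be given
#' as boluses (the default mode of care simulated here) and/or continuous
#' rates; enteral nutrition is a piecewise-constant fraction of the
#' patient-specific goal feed; dextrose boluses add glucose to the stomach
#' compartment.
#'
#' @param insulin_boluses data.frame with columns \code{time_h}, \code{units}
#'   (U).
#' @param insulin_rates data.frame with columns \code{time_h},
#'   \code{rate_U_h}; each rate holds from its time until the next entry.
#' @param enteral data.frame with columns \code{time_h}, \code{pct_gf}
#'   (percent of goal feed, 0-100); piecewise constant.
#' @param dextrose data.frame with columns \code{time_h}, \code{mmol}.
#' @param goal_feed goal feed rate (mmol glucose/h) defining 100 \%GF.
#' @return an \code{input_schedule} object.
#' @export
input_schedule <- function(insulin_boluses = NULL, insulin_rates = NULL,
                           enteral = NULL, dextrose = NULL, goal_feed = 65) {
  chk <- function(df, cols, what) {
    if (is.null(df) || nrow(df) == 0)
      return(stats::setNames(as.data.frame(rep(list(numeric(0)), length(cols))), cols))
    if (!all(cols %in% names(df)))
      stopf("%s needs columns: %s", what, paste(cols, collapse = ", "))
    df <- df[order(df$time_h), cols, drop = FALSE]
    if (any(!is.finite(as.matrix(df)))) stopf("%s has non-finite entries", what)
    if (any(df[[2]] < 0)) stopf("%s has negative values", what)
    df
  }
  if (!is_number(goal_feed) || goal_feed <= 0)
    stopf("goal_feed must be a positive number (mmol/h)")
  en <- chk(enteral, c("time_h", "pct_gf"), "enteral")
  if (nrow(en) && any(en$pct_gf > 100))
    stopf("enteral nutrition cannot exceed 100 %%GF")
  structure(list(
    insulin_boluses = chk(insulin_boluses, c("time_h", "units"), "insulin_boluses"),
    insulin_rates = chk(insulin_rates, c("time_h", "rate_U_h"), "insulin_rates"),
    enteral = en,
    dextrose = chk(dextrose, c("time_h", "mmol"), "dextrose"),
    goal_feed = goal_feed
  ), class = "input_schedule")
}

#' Simulate the ICING model
#'
#' Integrates the glucose-insulin-nutrition ODE system under an hourly
#' piecewise-constant insulin-sensitivity trace and an input schedule, using
#' a fixed-step fourth-order Runge-Kutta scheme (0.5 min default step) with
#' exact hour-boundary SI switching and exact bolus event handling. The
#' trajectory is returned on a fixed fine grid.
#'
#' @param state initial \code{icing_state}.
#' @param params \code{icing_params}.
#' @param si hourly SI values (L/(mU min)); \code{si[k]} applies on
#'   \code{[t0 + k - 1, t0 + k)}. Must cover \code{duration_h}.
#' @param inputs \code{input_schedule}.
#' @param duration_h simulation length (h), at least 1.
#' @param step_min integration step (minutes).
#' @param out_dt_h output grid spacing (h); must be a multiple of the step.
#' @return an \code{icing_sim}: data.frame with columns \code{time_h, G, I,
#'   Q, P1, P2}.
#' @examples
#' p <- icing_params()
#' st <- init_state(8, 65, p)
#' sched <- input_schedule(
#'   insulin_boluses = data.frame(time_h = 0:5, units = 3),
#'   enteral = data.frame(time_h = 0, pct_gf = 100), goal_feed = 65)
#' sim <- simulate_icing(st, p, rep(4.5e-4, 6), sched, 6)
#' bg_at_hours(sim, 0:6)
#' @export
simulate_icing <- function(state, params, si, inputs, duration_h,
                           step_min = 0.5, out_dt_h = 1 / 12) {
  stopifnot(inherits(state, "icing_state"), inherits(inputs, "input_schedule"))
  if (!is_number(duration_h) || duration_h < 1)
    stopf("duration_h must be >= 1 h")
  if (!is.numeric(si) || any(!is.finite(si)) || any(si < 0))
    stopf("si must be a non-negative numeric vector")
  if (length(si) < ceiling(duration_h - 1e-9))
    stopf("si trace (%d h) does not cover duration (%g h)",
          length(si), duration_h)
  t0 <- state$t
  en <- inputs$enteral
  feed_t <- if (nrow(en)) en$time_h else t0
  feed_v <- if (nrow(en)) en$pct_gf / 100 * inputs$goal_feed else 0
  ir <- inputs$insulin_rates
  ins_t <- if (nrow(ir)) ir$time_h else t0
  ins_v <- if (nrow(ir)) ir$rate_U_h else 0
  traj <- icing_simulate_cpp(
    state$y, t0, duration_h, step_min,
    si_t = t0 + seq_along(si) - 1, si_v = si,
    ins_t = ins_t, ins_v = ins_v,
    feed_t = feed_t, feed_v = feed_v,
    bol_t = inputs$insulin_boluses$time_h,
    bol_mU = inputs$insulin_boluses$units * 1000,
    dex_t = inputs$dextrose$time_h,
    dex_mmol = inputs$dextrose$mmol,
    p = as.numeric(params), out_dt_h = out_dt_h)
  out <- as.data.frame(traj)
  attr(out, "params_set") <- attr(params, "set")
  attr(out, "step_min") <- step_min
  class(out) <- c("icing_sim", "data.frame")
  out
}

#' Blood glucose at integer hours
#'
#' Extracts BG at integer hours directly from the simulated solution grid
#' (no interpolation), the hourly resampling used for protocol comparison.
#'
#' @param trajectory an \code{icing_sim} (or any data.frame with
#'   \code{time_h} and \code{G} columns on a grid containing integer hours).
#' @param hours integer hours to extract; default all covered hours.
#' @return named numeric vector of BG values (mmol/L).
#' @export
bg_at_hours <- function(trajectory, hours = NULL) {
  tt <- trajectory$time_h
  if (is.null(hours)) hours <- seq(ceiling(min(tt) - 1e-9), floor(max(tt) + 1e-9))
  pick <- vapply(hours, function(h) {
    i <- which(abs(tt - h) < 1e-9)
    if (!length(i)) stopf("hour %g is outside the simulated trajectory", h)
    i[1]
  }, 1L)
  stats::setNames(trajectory$G[pick], hours)
}

#' Export a simulated trajectory as CSV
#'
#' @param sim an \code{icing_sim}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  df <- data.frame(time_h = sim$time_h, BG_mmol_per_L = sim$G,
                   I = sim$I, Q = sim$Q, P1 = sim$P1, P2 = sim$P2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
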