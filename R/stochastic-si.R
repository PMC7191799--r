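## Kernel-density conditional transition models of insulin sensitivity:
## P(SI_{n+i} | SI_n) for horizons i = 1..6 h. SI is modelled as a first-order
## Markov process; the joint density is a sum of per-point Gaussian kernels in
## log-SI space with adaptive (local-data-density) bandwidths, and the
## conditional follows by normalising over the current-SI axis.

#' Build (SI_n, SI_{n+i}) transition pairs from hourly SI profiles
#'
#' Pairs are formed strictly within one profile (never across episodes), and
#' any hour flagged non-identifiable or clamped is excluded from both slots.
#'
#' @param profiles a single \code{si_profile} or a list of them.
#' @param horizon prediction horizon i in hours (1-6).
#' @return data.frame with columns \code{si_now}, \code{si_future},
#'   \code{horizon}, \code{patient_id}.
#' @export
make_si_pairs <- function(profiles, horizon) {
  if (inherits(profiles, "si_profile")) profiles <- list(profiles)
  if (!is_number(horizon) || horizon < 1 || horizon > 6 ||
      horizon != round(horizon))
    stopf("horizon must be an integer in 1..6")
  out <- lapply(profiles, function(pr) {
    ok <- pr$flag == "ok" & pr$si > 0
    n <- nrow(pr)
    if (n <= horizon) return(NULL)
    i <- seq_len(n - horizon)
    keep <- ok[i] & ok[i + horizon]
    if (!any(keep)) return(NULL)
    data.frame(si_now = pr$si[i][keep], si_future = pr$si[i + horizon][keep],
               horizon = horizon,
               patient_id = rep(attr(pr, "patient_id") %||% NA, sum(keep)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0)
    stopf("no SI pairs could be formed at horizon %d h", horizon)
  rownames(out) <- NULL
  out
}

# distance to the k-th nearest neighbour for every element of x
# (O(n*k) via a sorted window)
knn_distance <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  d <- numeric(n)
  for (ii in seq_len(n)) {
    lo <- max(1L, ii - k)
    hi <- min(n, ii + k)
    cand <- sort(abs(xs[lo:hi] - xs[ii]))
    d[ord[ii]] <- cand[min(k + 1L, length(cand))]  # cand[1] is self (0)
  }
  d
}

#' Fit a kernel-density SI transition model
#'
#' Fits the conditional model \eqn{P(SI_{n+i} | SI_n)} from transition pairs.
#' The joint density is the average of per-pair product Gaussian kernels
#' \eqn{\phi(x; x_i, \sigma^2_{x_i})\,\phi(y; y_i, \sigma^2_{y_i}) /
#' (p_{x_i} p_{y_i})}
#' placed at the data points, with per-point bandwidths weighted according to
#' local data density: \eqn{\sigma_{x_i}} is the distance to the k-th nearest
#' neighbour of \eqn{x_i} (default \eqn{k = n/20}, floor 10), and likewise on
#' y. SI values are log-transformed before kernel placement so the data are
#' approximately Gaussian and the positive-SI constraint is honoured
#' automatically; the per-kernel positive-domain normalisers \eqn{p_{x_i},
#' p_{y_i}} (kernel mass on the valid domain) are carried explicitly in the
#' model and equal 1 in the log coordinate. The conditional density
#' integrates to 1 over the future-SI axis for every current-SI value.
#'
#' @param pairs data.frame from \code{\link{make_si_pairs}}.
#' @param min_pairs minimum training size (default 500).
#' @param k nearest-neighbour count for the adaptive bandwidth; default
#'   \code{max(10, floor(n/20))}.
#' @param sigma_min bandwidth floor in log-SI units.
#' @param grid_n number of log-spaced grid points used for conditional CDF
#'   inversion.
#' @return an object of class \code{si_transition}.
#' @seealso \code{\link{conditional_percentiles}},
#'   \code{\link{conditional_density}}, \code{\link{predict.si_transition}}
#' @export
fit_si_transition <- function(pairs, min_pairs = 500, k = NULL,
                              sigma_min = 1e-3, grid_n = 300) {
  need <- c("si_now", "si_future")
  if (!all(need %in% names(pairs))) stopf("pairs must have si_now/si_future")
  n <- nrow(pairs)
  if (n < min_pairs)
    stopf("only %d SI pairs; at least %d required to fit a transition model",
          n, min_pairs)
  if (any(pairs$si_now <= 0) || any(pairs$si_future <= 0))
    stopf("SI pairs must be strictly positive for the log transform")
  cx <- log(pairs$si_now)
  cy <- log(pairs$si_future)
  k <- as.integer(k %||% max(10L, floor(n / 20)))
  sx <- pmax(knn_distance(cx, k), sigma_min)
  sy <- pmax(knn_distance(cy, k), sigma_min)
  si_all <- c(pairs$si_now, pairs$si_future)
  grid <- exp(seq(log(min(si_all) / 3), log(3 * max(si_all)),
                  length.out = grid_n))
  structure(list(
    horizon = as.numeric(pairs$horizon[1] %||% NA),
    n = n, k = k, sigma_min = sigma_min,
    cx = cx, cy = cy, sx = sx, sy = sy,
    px = rep(1, n), py = rep(1, n),
    grid = grid,
    si_range = range(pairs$si_now),
    train_patients = unique(pairs$patient_id),
    version = as.character(utils::packageVersion("stargc"))
  ), class = "si_transition")
}

#' @export
print.si_transition <- function(x, ...) {
  cat(sprintf(
    "SI transition model, horizon %s h: %d kernel centres (k = %d, log-SI space)\n",
    x$horizon, x$n, x$k))
  cat(sprintf("  training SI range: [%.3g, %.3g] L/(mU min)\n",
              x$si_range[1], x$si_range[2]))
  invisible(x)
}

#' Conditional density of future SI
#'
#' Evaluates \eqn{P(SI_{n+i} = y | SI_n = x)}. With \code{scale = "log"}
#' (default) the density is per unit log-SI, the model's working coordinate,
#' and integrates to 1 over a wide log-SI grid; \code{scale = "si"} applies
#' the Jacobian to express it per unit SI.
#'
#' @param model \code{si_transition}.
#' @param si_now current SI (scalar, > 0).
#' @param si_future vector of future SI values.
#' @param scale \code{"log"} or \code{"si"}.
#' @return numeric vector of density values.
#' @export
conditional_density <- function(model, si_now, si_future,
                                scale = c("log", "si")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "si_transition"), si_now > 0)
  d <- kde_cond_density_cpp(log(si_now), log(si_future),
                            model$cx, model$cy, model$sx, model$sy,
                            model$px, model$py)
  if (scale == "si") d <- d / si_future
  d
}

#' Conditional percentiles of future SI
#'
#' Inverts the conditional CDF of \eqn{P(SI_{n+i} | SI_n = si\_now)} on the
#' model's log-SI grid (monotone linear interpolation of the gridded CDF).
#' Queries outside the training SI support are still answered using the
#' nearest-edge kernels but are flagged as extrapolation.
#'
#' @param model \code{si_transition}.
#' @param si_now current SI (> 0).
#' @param probs percentiles in (0, 100), e.g. \code{c(5, 95)}.
#' @return named numeric vector of SI values, strictly increasing with
#'   \code{probs}; attribute \code{extrapolation} TRUE if \code{si_now} lies
#'   outside the training support.
#' @export
conditional_percentiles <- function(model, si_now, probs = c(5, 95)) {
  stopifnot(inherits(model, "si_transition"))
  if (!is_number(si_now) || si_now <= 0) stopf("si_now must be > 0")
  if (any(probs <= 0 | probs >= 100)) stopf("probs must lie in (0, 100)")
  lg <- log(model$grid)
  cdf <- kde_cond_cdf_cpp(log(si_now), lg, model$cx, model$cy,
                          model$sx, model$sy, model$px, model$py,
                          lo = -Inf)
  p <- probs / 100
  # monotone inversion; deduplicate flat CDF stretches for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  q <- stats::approx(cdf[keep], lg[keep], xout = p, rule = 2)$y
  # refine within the bracketing grid cell on the analytic CDF, so the
  # inversion error is not limited by the grid spacing (matters when the
  # bandwidth floor is finer than the grid)
  h <- diff(range(lg)) / (length(lg) - 1)
  cdf_at <- function(y) kde_cond_cdf_cpp(log(si_now), y, model$cx, model$cy,
                                         model$sx, model$sy, model$px,
                                         model$py, lo = -Inf)
  q <- vapply(seq_along(q), function(i) {
    br <- c(q[i] - h, q[i] + h)
    f <- function(y) cdf_at(y) - p[i]
    if (f(br[1]) > 0 || f(br[2]) < 0) return(q[i])
    stats::uniroot(f, br, tol = 1e-10)$root
  }, 0)
  out <- stats::setNames(exp(q), paste0("p", probs))
  extra <- si_now < model$si_range[1] || si_now > model$si_range[2]
  if (extra)
    attr(out, "extrapolation") <- TRUE
  out
}

#' @rdname conditional_percentiles
#' @param object \code{si_transition}.
#' @param ... passed on.
#' @export
predict.si_transition <- function(object, si_now, probs = c(5, 95), ...) {
  if (length(si_now) == 1L)
    return(conditional_percentiles(object, si_now, probs))
  t(vapply(si_now, function(x)
    as.numeric(conditional_percentiles(object, x, probs)),
    numeric(length(probs))))
}

#' Sample future SI from the conditional model
#'
#' Draws from \eqn{P(SI_{n+i} | SI_n = si\_now)} by sampling a kernel with
#' probability proportional to its local weight at \code{si_now}, then
#' drawing from that kernel's Gaussian in log-SI space.
#'
#' @param object \code{si_transition}.
#' @param nsim number of draws.
#' @param seed optional seed.
#' @param si_now current SI (> 0).
#' @param ... unused.
#' @return numeric vector of SI draws.
#' @export
simulate.si_transition <- function(object, nsim = 1, seed = NULL,
                                   si_now, ...) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(si_now > 0)
  w <- kde_cond_weights_cpp(log(si_now), object$cx, object$sx, object$px)
  idx <- sample.int(object$n, nsim, replace = TRUE, prob = w)
  exp(stats::rnorm(nsim, object$cy[idx], object$sy[idx]))
}

#' Plot percentile bands of a transition model
#'
#' Draws the conditional percentile curves of future SI against current SI
#' (the classic stochastic-model band picture).
#'
#' @param x \code{si_transition}.
#' @param probs percentiles to draw.
#' @param n_x number of current-SI values.
#' @param ... passed to \code{matplot}.
#' @return invisibly, the matrix of percentile curves.
#' @export
plot.si_transition <- function(x, probs = c(5, 50, 95), n_x = 60, ...) {
  sx <- exp(seq(log(x$si_range[1]), log(x$si_range[2]), length.out = n_x))
  m <- predict(x, sx, probs = probs)
  graphics::matplot(sx * 1e4, m * 1e4, type = "l", lty = c(2, 1, 2),
                    col = "black",
                    xlab = "current SI (1e-4 L/(mU min))",
                    ylab = "future SI (1e-4 L/(mU min))",
                    main = sprintf("SI transition percentiles, %s h horizon",
                                   x$horizon), ...)
  graphics::abline(0, 1, col = "grey60")
  invisible(m)
}

#' Fit transition models for all horizons with by-patient cross-validation
#'
#' Splits patients (never episodes or hours) into folds, then fits one
#' transition model per horizon per fold on the training patients. With
#' \code{folds = 1} a single model set is fitted on all patients (no
#' held-out set).
#'
#' @param profiles list of \code{si_profile} objects (one per episode);
#'   \code{patient_id} attributes drive the fold assignment.
#' @param horizons integer horizons, default 1:6.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param ... passed to \code{\link{fit_si_transition}} (e.g.
#'   \code{min_pairs}).
#' @return an \code{si_transition_set}: list with \code{folds} (each holding
#'   \code{train_patients}, \code{test_patients} and \code{models}, a list
#'   indexed by horizon) and the fold \code{assignment}.
#' @export
fit_si_transitions <- function(profiles, horizons = 1:6, folds = 5,
                               seed = 1, ...) {
  ids <- unique(vapply(profiles, function(p) as.character(attr(p, "patient_id")), ""))
  if (folds > 1 && length(ids) < folds)
    stopf("%d folds requested but only %d distinct patients", folds, length(ids))
  set.seed(seed)
  fold_of <- if (folds == 1) stats::setNames(rep(1L, length(ids)), ids)
             else stats::setNames(sample(rep_len(seq_len(folds), length(ids))), ids)
  fold_list <- lapply(seq_len(folds), function(f) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- if (folds == 1) ids else setdiff(ids, test_ids)
    train_prof <- Filter(function(p)
      as.character(attr(p, "patient_id")) %in% train_ids, profiles)
    models <- lapply(horizons, function(h) {
      pairs <- tryCatch(make_si_pairs(train_prof, h), error = function(e)
        stopf("fold %d, horizon %d h: %s", f, h, conditionMessage(e)))
      tryCatch(fit_si_transition(pairs, ...), error = function(e)
        stopf("fold %d, horizon %d h: %s", f, h, conditionMessage(e)))
    })
    names(models) <- as.character(horizons)
    list(train_patients = train_ids, test_patients = test_ids,
         models = models)
  })
  structure(list(folds = fold_list, horizons = horizons,
                 assignment = data.frame(patient_id = names(fold_of),
                                         fold = as.integer(fold_of),
                                         stringsAsFactors = FALSE),
                 seed = seed),
            class = "si_transition_set")
}

#' @export
print.si_transition_set <- function(x, ...) {
  cat(sprintf("SI transition model set: %d fold(s), horizons %s h, %d patients\n",
              length(x$folds), paste(range(x$horizons), collapse = "-"),
              nrow(x$assignment)))
  invisible(x)
}

#' Models applicable to a given patient
#'
#' Returns the per-horizon models of the fold in which the patient is held
#' out (so the patient never appears in its own training data).
#'
#' @param set \code{si_transition_set}.
#' @param patient_id identifier.
#' @return named list of \code{si_transition} models indexed by horizon.
#' @export
models_for_patient <- function(set, patient_id) {
  stopifnot(inherits(set, "si_transition_set"))
  if (length(set$folds) == 1) return(set$folds[[1]]$models)
  pid <- as.character(patient_id)
  f <- set$assignment$fold[match(pid, set$assignment$patient_id)]
  if (is.na(f)) stopf("patient %s has no fold assignment", pid)
  set$folds[[f]]$models
}
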