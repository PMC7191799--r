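## Outcome statistics of a simulated trial arm: time-in-band on hourly
## resampled BG, per-patient dose statistics, workload, and per-patient band
## attainment / severe-hypoglycaemia counts, in the standard report layout.

#' Hourly-resampled BG of a trial record
#'
#' One BG per glycaemic-control hour, taken directly from the simulated
#' solution grid (the resampling used for fair comparison between
#' protocols).
#'
#' @param record a \code{trial_record}.
#' @return named numeric vector of hourly BG (mmol/L).
#' @export
resample_hourly <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  record$hourly_bg
}

#' Cohort outcome metrics
#'
#' Computes the standard glycaemic-control summary of a trial arm: pooled
#' percentage of hourly BG in the 4.4-8.0 and 4.4-7.0 mmol/L bands and
#' outside them (band edges inclusive; \code{< 4.4} and \code{< 2.2}
#' strict), per-patient median [IQR] of BG, insulin and nutrition, workload
#' (24 x measurements / GC hours, reported rounded to the nearest integer
#' alongside the raw value), and per-patient attainment and severe-
#' hypoglycaemia counts.
#'
#' @param records list of \code{trial_record}s (one trial arm).
#' @return a \code{cohort_metrics} object (list; see fields in the source
#'   or \code{print} output).
#' @export
compute_metrics <- function(records) {
  if (!length(records)) stopf("no trial records supplied")
  hourly <- lapply(records, resample_hourly)
  pooled <- unlist(hourly, use.names = FALSE)
  gc_hours <- sum(vapply(records, `[[`, 0, "gc_hours"))
  n_meas <- sum(vapply(records, `[[`, 0, "n_measures"))
  per_bg <- vapply(hourly, median, 0)
  per_ins <- vapply(records, function(r) median(r$rows$insulin), 0)
  per_nut <- vapply(records, function(r) median(r$rows$nutrition), 0)
  pct <- function(cond) 100 * mean(cond)
  in_44_70 <- vapply(hourly, function(b) mean(b >= 4.4 & b <= 7.0), 0)
  in_44_80 <- vapply(hourly, function(b) mean(b >= 4.4 & b <= 8.0), 0)
  min_bg <- vapply(hourly, min, 0)
  n_ep <- length(records)
  structure(list(
    n_episodes = n_ep,
    gc_hours = gc_hours,
    n_measures = n_meas,
    workload_raw = 24 * n_meas / gc_hours,
    workload = round(24 * n_meas / gc_hours),
    bg_median = median_iqr(per_bg),
    insulin_median = median_iqr(per_ins),
    nutrition_median = median_iqr(per_nut),
    pct_in_44_80 = pct(pooled >= 4.4 & pooled <= 8.0),
    pct_in_44_70 = pct(pooled >= 4.4 & pooled <= 7.0),
    pct_gt_80 = pct(pooled > 8.0),
    pct_lt_44 = pct(pooled < 4.4),
    pct_lt_22 = pct(pooled < 2.2),
    n_pat_50_44_70 = sum(in_44_70 >= 0.5),
    pct_pat_50_44_70 = 100 * mean(in_44_70 >= 0.5),
    n_pat_50_44_80 = sum(in_44_80 >= 0.5),
    pct_pat_50_44_80 = 100 * mean(in_44_80 >= 0.5),
    n_pat_min_lt_22 = sum(min_bg < 2.2),
    pct_pat_min_lt_22 = 100 * mean(min_bg < 2.2),
    n_fallback = sum(vapply(records, `[[`, 0, "n_fallback"))
  ), class = "cohort_metrics")
}

#' @export
print.cohort_metrics <- function(x, ...) {
  mi <- function(v) sprintf("%.1f [%.1f %.1f]", v[1], v[2], v[3])
  cat(sprintf("# Episodes                              %d\n", x$n_episodes))
  cat(sprintf("# GC hours                              %d\n", x$gc_hours))
  cat(sprintf("# BG measures                           %d\n", x$n_measures))
  cat(sprintf("Workload (meas. per day)                %d (%.2f)\n",
              x$workload, x$workload_raw))
  cat(sprintf("Median BG (mmol/L)                      %s\n", mi(x$bg_median)))
  cat(sprintf("Median insulin (U/h)                    %s\n", mi(x$insulin_median)))
  cat(sprintf("Median nutrition (%%GF)                  %s\n", mi(x$nutrition_median)))
  cat(sprintf("%%BG in 4.4-8.0 mmol/L                   %.0f\n", x$pct_in_44_80))
  cat(sprintf("%%BG in 4.4-7.0 mmol/L                   %.0f\n", x$pct_in_44_70))
  cat(sprintf("%%BG > 8.0 mmol/L                        %.0f\n", x$pct_gt_80))
  cat(sprintf("%%BG < 4.4 mmol/L                        %.1f\n", x$pct_lt_44))
  cat(sprintf("%%BG < 2.2 mmol/L                        %.2f\n", x$pct_lt_22))
  cat(sprintf("# Patients >= 50%%BG in 4.4-7.0 (%%)      %d (%.0f%%)\n",
              x$n_pat_50_44_70, x$pct_pat_50_44_70))
  cat(sprintf("# Patients >= 50%%BG in 4.4-8.0 (%%)      %d (%.0f%%)\n",
              x$n_pat_50_44_80, x$pct_pat_50_44_80))
  cat(sprintf("# Patients min BG < 2.2 mmol/L (%%)      %d (%.1f%%)\n",
              x$n_pat_min_lt_22, x$pct_pat_min_lt_22))
  invisible(x)
}

#' Risk-reward trade-off summary across controller variants
#'
#' One row per variant with the workload (reward) and safety/efficacy/
#' nutrition (risk) axes, in input order.
#'
#' @param metrics_list named list of \code{cohort_metrics} (>= 2 variants).
#' @return data.frame with one row per variant.
#' @export
tradeoff_summary <- function(metrics_list) {
  if (length(metrics_list) < 2) stopf("need at least 2 variants to compare")
  rows <- lapply(names(metrics_list), function(nm) {
    m <- metrics_list[[nm]]
    data.frame(variant = nm,
               workload_raw = m$workload_raw, workload = m$workload,
               pct_in_44_80 = m$pct_in_44_80, pct_in_44_70 = m$pct_in_44_70,
               pct_gt_80 = m$pct_gt_80, pct_lt_44 = m$pct_lt_44,
               pct_lt_22 = m$pct_lt_22,
               pct_pat_min_lt_22 = m$pct_pat_min_lt_22,
               median_bg = m$bg_median[["median"]],
               median_insulin = m$insulin_median[["median"]],
               median_nutrition = m$nutrition_median[["median"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the workload versus safety/efficacy trade-off
#'
#' @param summary data.frame from \code{\link{tradeoff_summary}}.
#' @param ... passed to \code{matplot}.
#' @return invisibly, \code{summary}.
#' @export
plot_tradeoff <- function(summary, ...) {
  graphics::matplot(summary$workload_raw,
                    cbind(summary$pct_in_44_80, summary$pct_in_44_70),
                    type = "b", pch = c(1, 2), lty = 1, col = c(1, 2),
                    xlab = "workload (measurements/day)",
                    ylab = "% BG in band", ...)
  graphics::legend("bottomright", c("4.4-8.0 mmol/L", "4.4-7.0 mmol/L"),
                   pch = c(1, 2), col = c(1, 2), bty = "n")
  invisible(summary)
}
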