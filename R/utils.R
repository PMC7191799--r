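stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# median and interquartile range (type-7 quantiles), returned as a named
# vector c(median, q25, q75)
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, na.rm = TRUE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

# truncated draws by rejection; falls back to clamping if the acceptance
# region is extremely unlikely
rtrunc <- function(n, rfun, lo, hi, max_tries = 1000L) {
  out <- rfun(n)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) && tries < max_tries) {
    out[bad] <- rfun(length(bad))
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  pmin(pmax(out, lo), hi)
}
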