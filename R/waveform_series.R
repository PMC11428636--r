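#' Periodic waveform series
#'
#' A sampled physical waveform over one period: driving pressure gradients
#' (Pa/m), flow rates (m3/s), velocities (m/s) or pressures (mmHg). Samples
#' start at t = 0 and must not extend beyond the period; the series is
#' treated as periodic, with the wrap segment from the last sample back to
#' the first closing the cycle.
#'
#' @param times Sample times, s; strictly increasing, `times[1] == 0`,
#'   `times[length(times)] <= period_T`, at least 8 samples.
#' @param values Sample values (same length as `times`), finite.
#' @param period_T Period, s (> 0).
#' @param units Units tag, e.g. `"Pa/m"`, `"m3/s"`, `"m/s"`, `"mmHg"`.
#' @return An object of class `"waveform_series"`.
#' @export
waveform_series <- function(times, values, period_T, units = "") {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (length(times) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (!is.numeric(period_T) || length(period_T) != 1L || period_T <= 0)
    stop("'period_T' must be a single positive number", call. = FALSE)
  if (anyNA(times) || anyNA(values) || any(!is.finite(values)))
    stop("non-finite samples", call. = FALSE)
  if (times[1] != 0) stop("'times' must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (times[length(times)] > period_T * (1 + 1e-12))
    stop("'times' extend beyond the period", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period_T = period_T, units = units),
            class = "waveform_series")
}

#' @export
print.waveform_series <- function(x, ...) {
  cat(sprintf("Waveform series: %d samples over T = %g s [%s], range [%g, %g]\n",
              length(x$times), x$period_T, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

# Periodic linear interpolant of a waveform_series, callable at any t.
waveform_fun <- function(w) {
  stopifnot(inherits(w, "waveform_series"))
  tt <- c(w$times, w$period_T)
  vv <- c(w$values, w$values[1])  # periodic wrap
  force(tt); force(vv)
  function(t) {
    tm <- t %% w$period_T
    stats::approx(tt, vv, xout = tm, rule = 2)$y
  }
}

#' Time average of a periodic waveform
#'
#' Trapezoidal average over one period including the wrap segment from the
#' last sample back to the first.
#'
#' @param w A [waveform_series()] (or [pressure_waveform()]).
#' @return Scalar mean value in the waveform's units.
#' @export
waveform_mean <- function(w) {
  tt <- c(w$times, w$period_T)
  vv <- c(w$values, w$values[1])
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2) / w$period_T
}
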