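#' Pressure conversion constants
#'
#' Convert between mmHg and Pa with the fixed factor 133.322 Pa/mmHg.
#' @param x Pressure values.
#' @return Converted values.
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' Pressure waveform over one cardiac cycle
#'
#' A sampled arterial pressure waveform (mmHg) at a named location, treated
#' as periodic with period `period_T`.
#'
#' @param times Sample times, s; strictly increasing from 0, at least 16
#'   samples.
#' @param pressures Pressures, mmHg; finite.
#' @param period_T Period, s.
#' @param location Free-text location label (e.g. `"ascending aorta"`).
#' @return Object of class `"pressure_waveform"` (also a
#'   [waveform_series()]).
#' @export
pressure_waveform <- function(times, pressures, period_T,
                              location = "unspecified") {
  if (length(times) < 16L) stop("need at least 16 samples", call. = FALSE)
  w <- waveform_series(times, pressures, period_T, units = "mmHg")
  w$location <- location
  class(w) <- c("pressure_waveform", class(w))
  w
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("Pressure waveform at '%s': %d samples over T = %g s, [%g, %g] mmHg\n",
              x$location, length(x$times), x$period_T,
              min(x$values), max(x$values)))
  invisible(x)
}

local_minima_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n]) + 1L
}

#' Morphological features of an aortic pressure waveform
#'
#' Locates the landmarks of the central aortic waveform: the systolic peak
#' (global maximum), the diastolic minimum, the dicrotic notch (incisura,
#' marking aortic valve closure) as the most prominent local minimum in a
#' post-peak search window, the end-diastolic pressure (value at cycle end),
#' the pulse pressure, the period-weighted mean pressure, and the steepest
#' upstroke slope before the peak.
#'
#' @param w A [pressure_waveform()].
#' @param notch_window Length of the post-peak notch search window as a
#'   fraction of the period. Default 0.4.
#' @param notch_prominence Minimum prominence (mmHg) for a local minimum to
#'   qualify as the notch. Default 0 (any local minimum).
#' @return Object of class `"waveform_features"`: lists `systolic_peak` and
#'   `diastolic_min` (each `value` mmHg + `time` s), `dicrotic_notch` (or
#'   `NULL` when absent), `end_diastolic_pressure`, `pulse_pressure`,
#'   `mean_pressure` (mmHg), `upstroke_slope` (mmHg/s).
#' @export
#' @examples
#' syn <- synth_pressure_waveform(synth_config(seed = 7))
#' extract_features(syn$waveform)
extract_features <- function(w, notch_window = 0.4, notch_prominence = 0) {
  stopifnot(inherits(w, "pressure_waveform"))
  v <- w$values; tt <- w$times
  if (max(v) == min(v)) {
    warning("constant waveform: no landmarks to extract", call. = FALSE)
    i <- 1L
    feat <- list(systolic_peak = list(value = v[i], time = tt[i]),
                 diastolic_min = list(value = v[i], time = tt[i]),
                 dicrotic_notch = NULL,
                 end_diastolic_pressure = v[length(v)],
                 pulse_pressure = 0, mean_pressure = v[i],
                 upstroke_slope = 0)
    class(feat) <- "waveform_features"
    return(feat)
  }
  ipk <- which.max(v)
  imin <- which.min(v)
  t_pk <- tt[ipk]
  # notch: most prominent local minimum in (t_peak, t_peak + window]
  win_end <- t_pk + notch_window * w$period_T
  cand <- local_minima_idx(v)
  cand <- cand[tt[cand] > t_pk & tt[cand] <= win_end]
  notch <- NULL
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      left <- max(v[ipk:i])
      after <- v[i:min(length(v), max(which(tt <= win_end)))]
      min(left, max(after)) - v[i]
    }, numeric(1))
    keep <- prom >= notch_prominence & prom > 0
    if (any(keep)) {
      i <- cand[keep][which.max(prom[keep])]
      notch <- list(value = v[i], time = tt[i])
    }
  }
  upstroke <- if (ipk > 1) max(diff(v[1:ipk]) / diff(tt[1:ipk])) else NA_real_
  feat <- list(systolic_peak = list(value = v[ipk], time = t_pk),
               diastolic_min = list(value = v[imin], time = tt[imin]),
               dicrotic_notch = notch,
               end_diastolic_pressure = v[length(v)],
               pulse_pressure = v[ipk] - v[imin],
               mean_pressure = waveform_mean(w),
               upstroke_slope = upstroke)
  class(feat) <- "waveform_features"
  feat
}

#' @export
print.waveform_features <- function(x, ...) {
  cat("Aortic waveform features\n")
  cat(sprintf("  systolic peak : %.2f mmHg at %.4g s\n",
              x$systolic_peak$value, x$systolic_peak$time))
  cat(sprintf("  diastolic min : %.2f mmHg at %.4g s\n",
              x$diastolic_min$value, x$diastolic_min$time))
  if (is.null(x$dicrotic_notch)) cat("  dicrotic notch: absent\n")
  else cat(sprintf("  dicrotic notch: %.2f mmHg at %.4g s\n",
                   x$dicrotic_notch$value, x$dicrotic_notch$time))
  cat(sprintf("  end-diastolic : %.2f mmHg; pulse pressure %.2f mmHg\n",
              x$end_diastolic_pressure, x$pulse_pressure))
  cat(sprintf("  mean pressure : %.2f mmHg; upstroke %.4g mmHg/s\n",
              x$mean_pressure, x$upstroke_slope))
  invisible(x)
}

# Resample two waveforms onto a common uniform grid over one period.
common_grid <- function(a, b, n = 1000L) {
  if (abs(a$period_T - b$period_T) > 1e-3 * a$period_T)
    stop("waveform periods differ by more than 0.1%", call. = FALSE)
  tg <- seq(0, a$period_T, length.out = n + 1L)[1:n]
  fa <- waveform_fun(a); fb <- waveform_fun(b)
  list(t = tg, a = fa(tg), b = fb(tg))
}

#' Pointwise difference between two pressure waveforms
#'
#' Both waveforms are resampled to a common uniform grid (linear
#' interpolation, 1000 points by default) and the mean and maximum absolute
#' differences are reported — the metric used for mesh-to-mesh waveform
#' comparisons.
#'
#' @param a,b [pressure_waveform()]s with equal periods (to 0.1%).
#' @param n Number of resampling points. Default 1000.
#' @return List `mean_abs_diff`, `max_abs_diff` (mmHg).
#' @export
waveform_difference <- function(a, b, n = 1000L) {
  g <- common_grid(a, b, n)
  d <- abs(g$a - g$b)
  list(mean_abs_diff = mean(d), max_abs_diff = max(d))
}

#' Mean absolute percent error between waveforms
#'
#' Mean over a common uniform grid of `100 * |sim - ref| / ref` — the
#' clinical-validation error metric for simulated versus measured pressure
#' waveforms. The reference must be strictly positive (pressures in mmHg
#' are).
#'
#' @param sim,ref [pressure_waveform()]s with equal periods (to 0.1%).
#' @param n Number of resampling points. Default 1000.
#' @return Mean percent error (scalar, %).
#' @export
percent_error <- function(sim, ref, n = 1000L) {
  g <- common_grid(sim, ref, n)
  if (any(g$b <= 0)) stop("reference waveform must be strictly positive",
                          call. = FALSE)
  mean(100 * abs(g$a - g$b) / g$b)
}

#' Pressure difference between two locations
#'
#' Pointwise upstream minus downstream pressure on a common grid, plus mean
#' and peak summary values — the location-to-location pressure-drop
#' diagnostic.
#'
#' @param upstream,downstream [pressure_waveform()]s with equal periods.
#' @param n Number of resampling points. Default 1000.
#' @return List with `dp_waveform` (a [pressure_waveform()] of the
#'   difference), `mean_dp` and `peak_dp` (mmHg; peak is the largest
#'   magnitude, signed).
#' @export
delta_p <- function(upstream, downstream, n = 1000L) {
  g <- common_grid(upstream, downstream, n)
  d <- g$a - g$b
  wp <- waveform_series(g$t, d, upstream$period_T, units = "mmHg")
  wp$location <- paste0(upstream$location, " - ", downstream$location)
  class(wp) <- c("pressure_waveform", class(wp))
  list(dp_waveform = wp, mean_dp = mean(d), peak_dp = d[which.max(abs(d))])
}

#' Systolic/diastolic table for a set of waveforms
#'
#' @param waveforms Non-empty list of [pressure_waveform()]s.
#' @return `data.frame` with columns `label`, `systolic_mmHg`,
#'   `diastolic_mmHg`.
#' @export
systolic_diastolic_table <- function(waveforms) {
  if (!length(waveforms)) stop("empty waveform list", call. = FALSE)
  rows <- lapply(waveforms, function(w) {
    stopifnot(inherits(w, "pressure_waveform"))
    data.frame(label = w$location, systolic_mmHg = max(w$values),
               diastolic_mmHg = min(w$values), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
plot.pressure_waveform <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time [s]",
                 ylab = "pressure [mmHg]", main = x$location, ...)
  invisible(x)
}
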