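#' Sampled time-effect series
#'
#' A regional rCBF-like signal sampled at frame midpoints, noiseless or
#' noise-corrupted. Constructed by [predict_time_effect()] or [add_noise()];
#' direct construction is mainly useful for ingesting measured data.
#'
#' @param frame_times Frame midpoint times (minutes), strictly increasing.
#' @param values Effect values (ml/hg/min), finite.
#' @param noisy Logical flag: has acquisition noise been added?
#' @param noise_cov Coefficient of variation used, if `noisy`.
#' @param seed Seed used for the noise draw, if any.
#' @param e0 Optional baseline effect carried along for baseline-referenced
#'   noise and identifiability checks.
#' @return An object of class `time_effect_series`.
#' @export
time_effect_series <- function(frame_times, values, noisy = FALSE,
                               noise_cov = NULL, seed = NULL, e0 = NULL) {
  frame_times <- as.numeric(frame_times)
  values <- as.numeric(values)
  if (length(frame_times) != length(values))
    stop_param("'frame_times' and 'values' must have the same length")
  if (length(frame_times) < 1L)
    stop_param("series must contain at least one frame")
  if (any(diff(frame_times) <= 0))
    stop_param("'frame_times' must be strictly increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop_param("'values' must be finite")
  structure(list(frame_times = frame_times, values = values,
                 noisy = isTRUE(noisy), noise_cov = noise_cov,
                 seed = seed, e0 = e0),
            class = "time_effect_series")
}

#' @export
print.time_effect_series <- function(x, ...) {
  cat(sprintf(
    "<time_effect_series> %d frames on [%.3g, %.4g] min, %s%s\n",
    length(x$frame_times), x$frame_times[1],
    x$frame_times[length(x$frame_times)],
    if (x$noisy) sprintf("noisy (CoV %.3g)", x$noise_cov) else "noiseless",
    if (!is.null(x$seed)) sprintf(", seed %d", as.integer(x$seed)) else ""))
  invisible(x)
}

#' Frame-midpoint sampling grid
#'
#' Midpoints of contiguous CBF frames of fixed duration covering
#' `[t_start, t_end]` (a trailing partial frame is dropped). The default
#' 34 s matches pCASL CBF acquisition; durations outside 5-60 s are
#' rejected as outside the plausible perfusion-imaging range.
#'
#' @param t_start,t_end Interval endpoints (minutes), `t_end > t_start`.
#' @param frame_duration_s Frame duration in seconds, in `[5, 60]`.
#' @return Frame midpoint times in minutes.
#' @examples
#' length(frame_grid(0, 544 / 60, 34))  # 16 frames, as in a pCASL run
#' @export
frame_grid <- function(t_start, t_end, frame_duration_s = 34) {
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_end <= t_start)
    stop_param("need t_end > t_start")
  if (!is.numeric(frame_duration_s) || length(frame_duration_s) != 1L ||
      frame_duration_s < 5 || frame_duration_s > 60)
    stop_param("'frame_duration_s' must be in [5, 60] seconds")
  dur_min <- frame_duration_s / 60
  n <- floor((t_end - t_start) / dur_min + 1e-9)
  if (n < 1L) stop_param("interval shorter than one frame: empty grid")
  t_start + (seq_len(n) - 0.5) * dur_min
}

#' Add Gaussian acquisition noise to a time-effect series
#'
#' Adds independent Gaussian noise with a specified coefficient of
#' variation (CoV): frame `i` receives `N(0, (cov * ref_i)^2)` where the
#' reference is the noiseless value itself (`reference = "signal"`, the
#' default) or the series baseline `e0` (`reference = "baseline"`).
#' Negative noisy values are allowed (not clipped), to avoid biasing
#' downstream estimation. Reproducible given `seed`; the caller's RNG
#' state is preserved.
#'
#' @param series A noiseless [time_effect_series()].
#' @param cov Coefficient of variation, >= 0 (e.g. 0.129).
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#' @param reference `"signal"` or `"baseline"`.
#' @param e0 Baseline for `reference = "baseline"`; defaults to the value
#'   stored in the series.
#' @return A noisy `time_effect_series`.
#' @export
add_noise <- function(series, cov, seed = NULL,
                      reference = c("signal", "baseline"), e0 = NULL) {
  stopifnot(inherits(series, "time_effect_series"))
  reference <- match.arg(reference)
  if (!is.numeric(cov) || length(cov) != 1L || !is.finite(cov) || cov < 0)
    stop_param("'cov' must be a single number >= 0")
  if (isTRUE(series$noisy))
    stop_param("series is already noisy")
  ref <- if (reference == "signal") {
    series$values
  } else {
    b <- if (is.null(e0)) series$e0 else e0
    if (is.null(b)) stop_param("baseline reference requires 'e0'")
    rep(b, length(series$values))
  }
  eps <- with_seed(seed, stats::rnorm(length(series$values), 0, 1))
  time_effect_series(series$frame_times, series$values + cov * ref * eps,
                     noisy = cov > 0, noise_cov = cov, seed = seed,
                     e0 = series$e0)
}
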