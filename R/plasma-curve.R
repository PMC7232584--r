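#' Piecewise-linear plasma concentration curve
#'
#' Container for a plasma levodopa concentration time course \eqn{C_p(t)},
#' represented by knots that are linearly interpolated between blood-sample
#' (or simulation) times. All times are in minutes and concentrations in
#' ng/mL throughout the package.
#'
#' @param times Numeric vector of knot times (minutes), strictly increasing,
#'   at least 2 knots.
#' @param concentrations Numeric vector of plasma concentrations (ng/mL),
#'   one per knot, finite and non-negative.
#' @return An object of class `plasma_curve` with elements `times` and
#'   `concentrations`.
#' @examples
#' pc <- plasma_curve(c(0, 10, 150), c(0, 3000, 600))
#' interp_plasma(pc, 5)
#' @export
plasma_curve <- function(times, concentrations) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) < 2L)
    stop_param("a plasma curve needs at least 2 knots")
  if (length(times) != length(concentrations))
    stop_param("'times' and 'concentrations' must have the same length")
  if (anyNA(times) || any(!is.finite(times)))
    stop_param("knot times must be finite")
  if (any(diff(times) <= 0))
    stop_param("knot times must be strictly increasing")
  if (anyNA(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations < 0))
    stop_param("concentrations must be finite and >= 0")
  structure(list(times = times, concentrations = concentrations),
            class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf(
    "<plasma_curve> %d knots on [%g, %g] min, C in [%.4g, %.4g] ng/mL\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

check_in_span <- function(curve, t, what = "evaluation time") {
  lo <- curve$times[1]
  hi <- curve$times[length(curve$times)]
  if (any(t < lo) || any(t > hi))
    stop_param(sprintf(
      "%s outside the plasma curve span [%g, %g] min (no extrapolation)",
      what, lo, hi))
  invisible(TRUE)
}

# segment index for each t: i such that t in [times[i], times[i+1]]
segment_index <- function(times, t) {
  idx <- findInterval(t, times, rightmost.closed = TRUE)
  pmin.int(pmax.int(idx, 1L), length(times) - 1L)
}

#' Interpolate a plasma curve
#'
#' Evaluates \eqn{C_p(t)} by linear interpolation between knots:
#' \eqn{C_p(t) = C_p(t_i) + m_i (t - t_i)} on the segment containing `t`,
#' with slope \eqn{m_i = [C_p(t_{i+1}) - C_p(t_i)] / (t_{i+1} - t_i)}.
#' Extrapolation outside the knot span is an error.
#'
#' @param curve A [plasma_curve()].
#' @param t Numeric vector of times (minutes) within the curve span.
#' @return Concentrations (ng/mL) at `t`.
#' @export
interp_plasma <- function(curve, t) {
  stopifnot(inherits(curve, "plasma_curve"))
  t <- as.numeric(t)
  check_in_span(curve, t)
  i <- segment_index(curve$times, t)
  m <- (curve$concentrations[i + 1L] - curve$concentrations[i]) /
    (curve$times[i + 1L] - curve$times[i])
  curve$concentrations[i] + m * (t - curve$times[i])
}
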