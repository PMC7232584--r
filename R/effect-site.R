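#' Effect-compartment concentration for a piecewise-linear plasma curve
#'
#' Solves the effect-compartment (biophase) equation
#' \deqn{C_e'(t) = k_e (C_p(t) - C_e(t))}
#' in closed form. With \eqn{C_p} piecewise linear,
#' \eqn{C_p(t) = C_p(t_i) + m_i (t - t_i)} on \eqn{[t_i, t_{i+1}]}, the
#' solution on each segment is
#' \deqn{C_e(t) = (C_p(t_i) - m_i/k_e) + m_i (t - t_i)
#'       + (C_e(t_i) - C_p(t_i) + m_i/k_e) e^{-k_e (t - t_i)}.}
#' The value at the right end of each segment seeds the next, so the result
#' is exact (no integration error) and continuous across knots.
#'
#' @param curve A [plasma_curve()].
#' @param ke Effect-site rate constant, per minute, > 0. Equilibration
#'   half-life is `t_half_e(ke) = log(2)/ke`.
#' @param ce0 Initial effect-site concentration (ng/mL) at the first knot.
#'   Defaults to \eqn{C_p(t_0)}, the pre-infusion quasi-equilibrium
#'   assumption.
#' @param eval_times Times (minutes) at which to evaluate \eqn{C_e}; must
#'   lie within the plasma curve span.
#' @return An object of class `effect_site_curve`: list with `times`,
#'   `concentrations`, `ke`, `ce0`.
#' @seealso [effect_site_ode_oracle()] for an independent numerical check.
#' @examples
#' pc <- plasma_curve(c(0, 150), c(600, 600))
#' effect_site(pc, ke = 0.1, eval_times = c(0, 75, 150))$concentrations
#' @export
effect_site <- function(curve, ke, ce0 = NULL, eval_times) {
  stopifnot(inherits(curve, "plasma_curve"))
  check_scalar_pos(ke, "ke")
  if (is.null(ce0)) ce0 <- curve$concentrations[1]
  if (!is.numeric(ce0) || length(ce0) != 1L || !is.finite(ce0) || ce0 < 0)
    stop_param("'ce0' must be a single finite number >= 0")
  eval_times <- as.numeric(eval_times)
  check_in_span(curve, eval_times)
  ce_knots <- effect_site_knots(curve, ke, ce0)
  conc <- effect_site_eval(curve, ke, ce_knots, eval_times)
  structure(list(times = eval_times, concentrations = conc,
                 ke = ke, ce0 = ce0),
            class = "effect_site_curve")
}

# C_e at every plasma knot via the per-segment affine recurrence
# ce[i+1] = A_i + B_i * ce[i]
effect_site_knots <- function(curve, ke, ce0) {
  tt <- curve$times
  cp <- curve$concentrations
  dt <- diff(tt)
  m <- diff(cp) / dt
  B <- exp(-ke * dt)
  A <- (cp[-length(cp)] - m / ke) * (1 - B) + m * dt
  n <- length(dt)
  ce <- numeric(n + 1L)
  ce[1L] <- ce0
  for (i in seq_len(n)) ce[i + 1L] <- A[i] + B[i] * ce[i]
  ce
}

effect_site_eval <- function(curve, ke, ce_knots, eval_times) {
  tt <- curve$times
  cp <- curve$concentrations
  i <- segment_index(tt, eval_times)
  m <- (cp[i + 1L] - cp[i]) / (tt[i + 1L] - tt[i])
  tau <- eval_times - tt[i]
  (cp[i] - m / ke) + m * tau +
    (ce_knots[i] - cp[i] + m / ke) * exp(-ke * tau)
}

#' @export
print.effect_site_curve <- function(x, ...) {
  cat(sprintf(
    "<effect_site_curve> ke = %.5g /min (t1/2e = %.4g min), %d points\n",
    x$ke, log(2) / x$ke, length(x$times)))
  invisible(x)
}

#' Numerical ODE oracle for the effect compartment
#'
#' Integrates \eqn{C_e' = k_e (C_p - C_e)} with a fixed-step classical
#' 4th-order Runge-Kutta scheme, independently of the closed form in
#' [effect_site()]. Intended for verification in tests; the closed form is
#' what the rest of the package uses. Integration proceeds checkpoint to
#' checkpoint (plasma knots plus evaluation times), with the step shortened
#' within each leg so checkpoints are hit exactly and the piecewise-linear
#' kinks of \eqn{C_p} never fall inside a step.
#'
#' @inheritParams effect_site
#' @param step Target RK4 step (minutes), > 0 and small relative to `1/ke`.
#' @return An `effect_site_curve`.
#' @export
effect_site_ode_oracle <- function(curve, ke, ce0 = NULL, eval_times,
                                   step = 1e-3) {
  stopifnot(inherits(curve, "plasma_curve"))
  check_scalar_pos(ke, "ke")
  check_scalar_pos(step, "step")
  if (is.null(ce0)) ce0 <- curve$concentrations[1]
  eval_times <- as.numeric(eval_times)
  check_in_span(curve, eval_times)

  t0 <- curve$times[1]
  checkpoints <- sort(unique(c(curve$times, eval_times)))
  checkpoints <- checkpoints[checkpoints >= t0]
  y <- ce0
  value_at <- c(stats::setNames(ce0, sprintf("%.15g", t0)))
  for (j in seq_len(length(checkpoints) - 1L)) {
    a <- checkpoints[j]; b <- checkpoints[j + 1L]
    nstep <- max(1L, as.integer(ceiling((b - a) / step)))
    h <- (b - a) / nstep
    # Cp on the half-step grid of this leg (linear within the leg)
    cpg <- interp_plasma(curve, a + (0:(2L * nstep)) * (h / 2))
    c1 <- cpg[seq(1L, 2L * nstep - 1L, by = 2L)]
    c2 <- cpg[seq(2L, 2L * nstep, by = 2L)]
    c3 <- cpg[seq(3L, 2L * nstep + 1L, by = 2L)]
    # RK4 for a linear ODE is an affine update y <- Acoef*y + b_i; the
    # recurrence is evaluated exactly by a recursive filter.
    k10 <- ke * c1
    k20 <- ke * (c2 - (h / 2) * k10)
    k30 <- ke * (c2 - (h / 2) * k20)
    k40 <- ke * (c3 - h * k30)
    bvec <- (h / 6) * (k10 + 2 * k20 + 2 * k30 + k40)
    k1y <- -ke
    k2y <- -ke * (1 + (h / 2) * k1y)
    k3y <- -ke * (1 + (h / 2) * k2y)
    k4y <- -ke * (1 + h * k3y)
    acoef <- 1 + (h / 6) * (k1y + 2 * k2y + 2 * k3y + k4y)
    yseq <- stats::filter(bvec, acoef, method = "recursive", init = y)
    y <- yseq[nstep]
    value_at[sprintf("%.15g", b)] <- y
  }
  conc <- unname(value_at[sprintf("%.15g", eval_times)])
  structure(list(times = eval_times, concentrations = conc,
                 ke = ke, ce0 = ce0),
            class = "effect_site_curve")
}
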