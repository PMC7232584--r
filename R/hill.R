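#' Pharmacodynamic parameter set
#'
#' Bundles the sigmoid Emax response parameters with the effect-site rate
#' constant. Units: `e0` and `emax` in ml/hg/min (baseline rCBF and maximal
#' rCBF increment), `ec50` in ng/mL, `n` dimensionless, `ke` per minute.
#'
#' @param e0 Baseline effect (rCBF), >= 0.
#' @param emax Maximal effect increment above baseline, >= 0.
#' @param ec50 Effect-site concentration producing half-maximal effect, > 0.
#' @param n Hill coefficient (sigmoid steepness), > 0.
#' @param ke Effect-site rate constant, per minute, > 0.
#' @return An object of class `pd_params`.
#' @examples
#' pd_params(e0 = 50, emax = 35, ec50 = 600, n = 3, ke = ke_from_t_half(30))
#' @export
pd_params <- function(e0 = 50, emax = 35, ec50, n, ke) {
  for (nm in c("e0", "emax")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_param(sprintf("'%s' must be a single finite number >= 0", nm))
  }
  check_scalar_pos(ec50, "ec50")
  check_scalar_pos(n, "n")
  check_scalar_pos(ke, "ke")
  structure(list(e0 = as.numeric(e0), emax = as.numeric(emax),
                 ec50 = as.numeric(ec50), n = as.numeric(n),
                 ke = as.numeric(ke)),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf(
    paste0("<pd_params> e0 = %g, emax = %g ml/hg/min; ec50 = %g ng/mL; ",
           "n = %g; ke = %.5g /min (t1/2e = %.4g min)\n"),
    x$e0, x$emax, x$ec50, x$n, x$ke, log(2) / x$ke))
  invisible(x)
}

#' Sigmoid Emax (Hill) concentration-effect model
#'
#' \deqn{E(C_e) = E_0 + E_{max} \frac{C_e^n}{EC_{50}^n + C_e^n}}
#' Strictly increasing in \eqn{C_e}, equal to \eqn{E_0} at zero and
#' approaching \eqn{E_0 + E_{max}} asymptotically; exactly the midpoint
#' \eqn{E_0 + E_{max}/2} at \eqn{C_e = EC_{50}} for every Hill coefficient.
#' Computed via \eqn{r = (C_e/EC_{50})^n}, \eqn{E = E_0 + E_{max} r/(1+r)},
#' which is overflow-safe for large concentrations and steep `n`.
#'
#' @param ce Effect-site concentrations (ng/mL), >= 0 (Inf allowed, giving
#'   the asymptote).
#' @param params A [pd_params()].
#' @return Effect values (ml/hg/min).
#' @export
hill_effect <- function(ce, params) {
  stopifnot(inherits(params, "pd_params"))
  ce <- as.numeric(ce)
  if (anyNA(ce) || any(ce < 0))
    stop_param("'ce' must be >= 0")
  r <- (ce / params$ec50)^params$n
  frac <- ifelse(is.infinite(r), 1, r / (1 + r))
  params$e0 + params$emax * frac
}

#' Equilibration half-life and rate constant
#'
#' Converts between the effect-site rate constant \eqn{k_e} (per minute) and
#' the equilibration half-life \eqn{t_{1/2,e} = \ln 2 / k_e} (minutes): the
#' time for the effect-site concentration to close half its gap to a
#' constant plasma level. The two functions are exact inverses.
#'
#' @param ke Rate constant, per minute, > 0.
#' @param t_half Equilibration half-life, minutes, > 0.
#' @return `t_half_e(ke)`: minutes; `ke_from_t_half(t_half)`: per minute.
#' @examples
#' t_half_e(log(2) / 5)      # 5 (severe-PD preset)
#' ke_from_t_half(277)       # mildest preset
#' @export
t_half_e <- function(ke) {
  if (!is.numeric(ke) || anyNA(ke) || any(ke <= 0))
    stop_param("'ke' must be > 0")
  log(2) / ke
}

#' @rdname t_half_e
#' @export
ke_from_t_half <- function(t_half) {
  if (!is.numeric(t_half) || anyNA(t_half) || any(t_half <= 0))
    stop_param("'t_half' must be > 0")
  log(2) / t_half
}

#' Predict a noiseless time-effect series
#'
#' Composes the effect-compartment solution with the sigmoid Emax model:
#' plasma knots are first mapped to effect-site concentrations at the
#' requested times (with \eqn{C_e(t_0) = C_p(t_0)} unless overridden), then
#' through [hill_effect()]. The result is a noiseless
#' [time_effect_series()].
#'
#' @inheritParams effect_site
#' @param params A [pd_params()] supplying `ke` and the response parameters.
#' @param eval_times Sample times (minutes), e.g. from [frame_grid()].
#' @return A noiseless `time_effect_series`.
#' @export
predict_time_effect <- function(curve, params, eval_times, ce0 = NULL) {
  stopifnot(inherits(params, "pd_params"))
  es <- effect_site(curve, params$ke, ce0 = ce0, eval_times = eval_times)
  time_effect_series(eval_times, hill_effect(es$concentrations, params),
                     noisy = FALSE, e0 = params$e0)
}
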