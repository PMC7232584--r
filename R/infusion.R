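#' Intravenous levodopa infusion regimen
#'
#' Encodes the loading + maintenance infusion used to reach and hold a
#' target plasma level quickly: a 10-min loading dose at 0.6426 mg/kg
#' followed by a maintenance infusion at
#' \eqn{2.882\times 10^{-5}} mg/kg/min \eqn{\times (140 - age)} for a
#' default total of 150 min. `duration_scale = s` stretches both phases by
#' `s` and divides both rates by `s`, so the total infused dose is invariant
#' (the doubled-duration, half-rate protocol is `duration_scale = 2`).
#'
#' @param weight_kg Body weight (kg), > 0.
#' @param age_yr Age (years), in (0, 140); the maintenance formula becomes
#'   non-positive at 140.
#' @param duration_scale Dimensionless stretch factor >= 1.
#' @param loading_mg_per_kg Loading dose per kg delivered over the loading
#'   phase (mg/kg).
#' @param maintenance_coef Maintenance coefficient (mg/kg/min per year of
#'   `140 - age`).
#' @param loading_duration_min,total_duration_min Unscaled phase durations
#'   (minutes).
#' @return An object of class `infusion_regimen` with the per-subject rates:
#'   `loading_dose_mg`, `loading_rate_mg_min`, `loading_duration_min`,
#'   `maintenance_rate_mg_min`, `total_duration_min`, `duration_scale`,
#'   plus the inputs.
#' @examples
#' reg <- build_regimen(70, 65)
#' round(reg$loading_dose_mg)            # 45 mg over 10 min
#' round(reg$maintenance_rate_mg_min, 2) # 0.15 mg/min
#' round(total_dose(reg))                # 66 mg over 150 min
#' @export
build_regimen <- function(weight_kg, age_yr, duration_scale = 1,
                          loading_mg_per_kg = 0.6426,
                          maintenance_coef = 2.882e-5,
                          loading_duration_min = 10,
                          total_duration_min = 150) {
  check_scalar_pos(weight_kg, "weight_kg")
  check_scalar_pos(age_yr, "age_yr")
  if (age_yr >= 140)
    stop_param("age_yr must be < 140 (maintenance formula non-positive)")
  if (!is.numeric(duration_scale) || length(duration_scale) != 1L ||
      duration_scale < 1)
    stop_param("'duration_scale' must be >= 1")
  if (loading_duration_min >= total_duration_min)
    stop_param("loading duration must be shorter than total duration")
  s <- as.numeric(duration_scale)
  loading_dose <- loading_mg_per_kg * weight_kg
  maint_rate <- maintenance_coef * weight_kg * (140 - age_yr)
  structure(list(
    weight_kg = as.numeric(weight_kg),
    age_yr = as.numeric(age_yr),
    duration_scale = s,
    loading_dose_mg = loading_dose,
    loading_duration_min = loading_duration_min * s,
    loading_rate_mg_min = loading_dose / (loading_duration_min * s),
    maintenance_rate_mg_min = maint_rate / s,
    total_duration_min = total_duration_min * s
  ), class = "infusion_regimen")
}

#' @export
print.infusion_regimen <- function(x, ...) {
  cat(sprintf(
    paste0("<infusion_regimen> %g kg, %g yr: %.4g mg over %g min, then ",
           "%.4g mg/min to %g min (total %.4g mg%s)\n"),
    x$weight_kg, x$age_yr, x$loading_dose_mg, x$loading_duration_min,
    x$maintenance_rate_mg_min, x$total_duration_min, total_dose(x),
    if (x$duration_scale != 1)
      sprintf(", duration_scale %g", x$duration_scale) else ""))
  invisible(x)
}

#' Total infused dose
#'
#' Loading dose plus maintenance rate times maintenance duration (mg).
#' Invariant under `duration_scale` by construction.
#'
#' @param regimen An [build_regimen()] object.
#' @return Total dose in mg.
#' @export
total_dose <- function(regimen) {
  stopifnot(inherits(regimen, "infusion_regimen"))
  regimen$loading_dose_mg + regimen$maintenance_rate_mg_min *
    (regimen$total_duration_min - regimen$loading_duration_min)
}

#' Plasma pharmacokinetic scenario
#'
#' Named multiplicative scenarios standing in for between-subject
#' variability in plasma levels: the `mean` scenario is the calibrated
#' curve, `high` and `low` scale it (defaults 1.5 and 0.55, emulating the
#' 90th/10th percentile spread of measured infusion data). An explicit
#' `clearance` (L/min) overrides the plateau-derived value.
#'
#' @param label One of `"mean"`, `"high"`, `"low"`.
#' @param scale Multiplier on the mean-scenario curve; defaults 1 / 1.5 /
#'   0.55 by label. Must be > 0, with high > mean = 1 > low.
#' @param clearance Optional elimination clearance override (L/min).
#' @return An object of class `pk_scenario`.
#' @export
pk_scenario <- function(label = c("mean", "high", "low"), scale = NULL,
                        clearance = NULL) {
  label <- match.arg(label)
  if (is.null(scale))
    scale <- c(mean = 1, high = 1.5, low = 0.55)[[label]]
  check_scalar_pos(scale, "scale")
  if (label == "mean" && scale != 1)
    stop_param("mean scenario must have scale 1")
  if (label == "high" && scale <= 1)
    stop_param("high scenario must have scale > 1")
  if (label == "low" && scale >= 1)
    stop_param("low scenario must have scale < 1")
  if (!is.null(clearance)) check_scalar_pos(clearance, "clearance")
  structure(list(label = label, scale = scale, clearance = clearance),
            class = "pk_scenario")
}

# Propagate the two-compartment system through one constant-rate phase.
# State s = (C1 mg/L, C2 mg/L, 1); returns central concentration (mg/L) at
# the requested times plus the end-of-phase state.
propagate_phase <- function(state, times, t0, t_end, rate, cl, v1, v2, q) {
  G <- rbind(c(-(cl + q) / v1, q / v1, rate / v1),
             c(q / v2, -q / v2, 0),
             c(0, 0, 0))
  conc <- numeric(length(times))
  if (length(times)) {
    dts <- diff(c(t0, times))
    expms <- lapply(unique(dts), function(d) {
      unname(as.matrix(Matrix::expm(G * d)))
    })
    names(expms) <- sprintf("%.15g", unique(dts))
    for (i in seq_along(times)) {
      state <- expms[[sprintf("%.15g", dts[i])]] %*% state
      conc[i] <- state[1L]
    }
  }
  if (length(times) == 0L || times[length(times)] < t_end) {
    d <- t_end - if (length(times)) times[length(times)] else t0
    state <- unname(as.matrix(Matrix::expm(G * d))) %*% state
  }
  list(conc = conc, state = state)
}

# Exact simulation of the two-compartment model for a regimen, given PK
# parameters; returns concentrations (ng/mL) at knot_times.
simulate_2cpt <- function(regimen, knot_times, cl, v1, v2, q) {
  ld <- regimen$loading_duration_min
  td <- regimen$total_duration_min
  phases <- rbind(c(0, ld, regimen$loading_rate_mg_min),
                  c(ld, td, regimen$maintenance_rate_mg_min),
                  c(td, Inf, 0))
  conc <- numeric(length(knot_times))
  conc[knot_times == 0] <- 0
  state <- c(0, 0, 1)
  for (p in seq_len(nrow(phases))) {
    a <- phases[p, 1]; b <- phases[p, 2]
    sel <- which(knot_times > a & knot_times <= b)
    b_eff <- min(b, max(knot_times))
    out <- propagate_phase(state, knot_times[sel], a, b_eff,
                           phases[p, 3], cl, v1, v2, q)
    conc[sel] <- out$conc
    state <- out$state
    if (b >= max(knot_times)) break
  }
  list(conc_ng_ml = conc * 1000,
       amounts_mg = c(state[1L] * v1, state[2L] * v2))
}

#' Calibrate subject plasma pharmacokinetics to the printed targets
#'
#' Fixes a two-compartment (central/peripheral) disposition model for a
#' subject so that the standard (scale 1) regimen reproduces the two
#' published constraints of the infusion protocol: a maintenance
#' steady-state plasma level of `target_ss_ng_ml` (clearance
#' `CL = maintenance rate / target`), and an end-of-loading transient peak
#' within `peak_band_ng_ml`. The steady-state volume of distribution is
#' found by a fixed-point iteration that matches the realized 100-150 min
#' plateau to the target; the central fraction `v1_frac` and
#' inter-compartmental clearance `q_l_min` shape the transient peak.
#'
#' @param weight_kg,age_yr Subject covariates passed to [build_regimen()].
#' @param target_ss_ng_ml Steady-state plasma target (ng/mL), default 600.
#' @param peak_band_ng_ml Admissible transient peak range (ng/mL).
#' @param v1_frac Central volume as a fraction of Vss.
#' @param q_l_min Inter-compartmental clearance (L/min).
#' @param clearance Optional clearance override (L/min).
#' @return List of class `pk_params`: `cl`, `v1`, `v2`, `vss` (L),
#'   `q`, plus the calibration targets; errors if the peak constraint
#'   cannot be met.
#' @export
calibrate_pk <- function(weight_kg, age_yr, target_ss_ng_ml = 600,
                         peak_band_ng_ml = c(1500, 3500), v1_frac = 0.2,
                         q_l_min = 0.5, clearance = NULL) {
  reg <- build_regimen(weight_kg, age_yr)
  target_mg_l <- target_ss_ng_ml / 1000
  cl <- if (is.null(clearance))
    reg$maintenance_rate_mg_min / target_mg_l else clearance
  knots <- sort(unique(c(seq(0, reg$total_duration_min, by = 1),
                         reg$loading_duration_min)))
  vss <- reg$loading_dose_mg / target_mg_l
  plateau_sel <- knots >= (2 / 3) * reg$total_duration_min
  for (i in 1:8) {
    sim <- simulate_2cpt(reg, knots, cl, v1_frac * vss,
                         (1 - v1_frac) * vss, q_l_min)
    plateau <- mean(sim$conc_ng_ml[plateau_sel])
    if (plateau <= 0) stop_param("PK calibration failed: zero plateau")
    vss_new <- vss * plateau / target_ss_ng_ml
    if (abs(vss_new - vss) < 1e-8 * vss) { vss <- vss_new; break }
    vss <- vss_new
  }
  sim <- simulate_2cpt(reg, knots, cl, v1_frac * vss,
                       (1 - v1_frac) * vss, q_l_min)
  peak <- max(sim$conc_ng_ml)
  if (peak < peak_band_ng_ml[1] || peak > peak_band_ng_ml[2])
    stop_param(sprintf(
      paste0("PK calibration infeasible: end-of-loading peak %.0f ng/mL ",
             "outside [%g, %g]; adjust v1_frac/q_l_min"),
      peak, peak_band_ng_ml[1], peak_band_ng_ml[2]))
  structure(list(cl = cl, v1 = v1_frac * vss, v2 = (1 - v1_frac) * vss,
                 vss = vss, q = q_l_min,
                 target_ss_ng_ml = target_ss_ng_ml,
                 peak_ng_ml = peak, weight_kg = weight_kg,
                 age_yr = age_yr),
            class = "pk_params")
}

#' Simulate a plasma concentration curve for a regimen
#'
#' Runs the calibrated two-compartment disposition model under the given
#' infusion regimen and samples the central-compartment concentration as a
#' piecewise-linear [plasma_curve()]. High/low scenarios multiply the mean
#' curve by the scenario scale. The curve extends `tail_min` past the end
#' of infusion so late acquisition frames remain within its span.
#'
#' @param regimen An [build_regimen()] object.
#' @param scenario A [pk_scenario()]; default mean.
#' @param knot_times Output knot times (minutes); default every minute from
#'   0 to infusion end + `tail_min`, plus the phase boundaries.
#' @param pk Optional precomputed [calibrate_pk()] result (reused across
#'   calls for speed); default calibrates from the regimen's covariates.
#' @param tail_min Post-infusion tail (minutes), default 30.
#' @return A `plasma_curve` with attributes `pk` (the parameters used) and
#'   `scenario`.
#' @export
simulate_plasma <- function(regimen, scenario = pk_scenario("mean"),
                            knot_times = NULL, pk = NULL, tail_min = 30) {
  stopifnot(inherits(regimen, "infusion_regimen"),
            inherits(scenario, "pk_scenario"))
  if (is.null(knot_times)) {
    knot_times <- sort(unique(c(
      seq(0, regimen$total_duration_min + tail_min, by = 1),
      regimen$loading_duration_min, regimen$total_duration_min)))
  } else {
    knot_times <- sort(unique(as.numeric(knot_times)))
  }
  if (regimen$loading_rate_mg_min == 0 &&
      regimen$maintenance_rate_mg_min == 0) {
    out <- plasma_curve(knot_times, rep(0, length(knot_times)))
    attr(out, "scenario") <- scenario
    return(out)
  }
  if (is.null(pk))
    pk <- calibrate_pk(regimen$weight_kg, regimen$age_yr,
                       clearance = scenario$clearance)
  sim <- simulate_2cpt(regimen, knot_times, pk$cl, pk$v1, pk$v2, pk$q)
  conc <- pmax(sim$conc_ng_ml * scenario$scale, 0)
  out <- plasma_curve(knot_times, conc)
  attr(out, "pk") <- pk
  attr(out, "scenario") <- scenario
  attr(out, "amounts_mg") <- sim$amounts_mg
  out
}
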