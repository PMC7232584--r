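# shared fixtures, all generated in code

# random piecewise-linear plasma curve on [0, span] (uses the current RNG)
random_plasma_curve <- function(span = 180, max_knots = 12,
                                conc_max = 3500) {
  n <- sample(3:max_knots, 1)
  times <- sort(c(0, span, runif(n - 2, 0, span)))
  while (any(diff(times) < 1e-3))
    times <- sort(c(0, span, runif(n - 2, 0, span)))
  plasma_curve(times, runif(n, 0, conc_max))
}

# one shared mean-scenario setup, computed lazily and memoised
.setup_cache <- new.env(parent = emptyenv())
mean_setup <- function() {
  if (is.null(.setup_cache$s)) {
    reg <- build_regimen(70, 65)
    pk <- calibrate_pk(70, 65)
    plasma <- simulate_plasma(reg, pk = pk)
    .setup_cache$s <- list(
      regimen = reg, pk = pk, plasma = plasma,
      frames = frame_grid(0, reg$total_duration_min + 30, 34),
      presets = severity_presets())
  }
  .setup_cache$s
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
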