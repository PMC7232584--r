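#' Read and write two-column time-series files
#'
#' Delimited text (comma-separated, one header line) with a time column in
#' minutes and a value column in the declared units (ng/mL for plasma,
#' ml/hg/min for effect series). Validation errors name the offending data
#' line.
#'
#' @param path File path.
#' @return `read_timeseries()`: list with `times`, `values`, and the
#'   header `names`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_param(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop_param(sprintf("%s: need a header plus at least one data row",
                       path))
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L || any(!is.na(suppressWarnings(
    as.numeric(header[1:2])))))
    stop_param(sprintf("%s: line 1: missing non-numeric header", path))
  times <- numeric(0)
  values <- numeric(0)
  for (ln in seq(2L, length(lines))) {
    if (!nzchar(trimws(lines[ln]))) next
    parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(parts[1:2]))
    if (length(parts) < 2L || anyNA(num))
      stop_param(sprintf("%s: line %d: non-numeric or missing cell",
                         path, ln))
    times <- c(times, num[1L])
    values <- c(values, num[2L])
  }
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop_param(sprintf(
      "%s: line %d: times not strictly increasing", path, bad[1L] + 2L))
  list(times = times, values = values, names = header[1:2])
}

#' @rdname read_timeseries
#' @param times,values Numeric vectors of equal length.
#' @param names Column names for the header.
#' @export
write_timeseries <- function(path, times, values,
                             names = c("time_min", "value")) {
  if (length(times) != length(values))
    stop_param("'times' and 'values' must have the same length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names[1], names[2], sep = ","), con)
  writeLines(sprintf("%.10g,%.10g", times, values), con)
  invisible(path)
}

#' Generate a deterministic fixture bundle
#'
#' Writes a small self-consistent bundle used by integration tests: the
#' mean-scenario plasma curve, the noiseless and noisy (CoV 12.9%)
#' most-severe-preset effect series, a JSON sidecar with the generation
#' metadata, and the [fit_pkpd()] result of a pinned fit of the noisy
#' series. Byte-identical for identical seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving the noise draw and fit.
#' @param preset_index Which severity preset to use (default most severe).
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1L, preset_index = 6L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preset <- severity_presets()[[preset_index]]
  cond <- generate_condition(preset, "mean")
  paths <- c(plasma = file.path(dir, "plasma.csv"),
             noiseless = file.path(dir, "effect_noiseless.csv"),
             noisy = file.path(dir, "effect_noisy.csv"),
             meta = file.path(dir, "meta.json"),
             fit = file.path(dir, "fit_expected.json"))
  write_timeseries(paths["plasma"], cond$plasma$times,
                   cond$plasma$concentrations,
                   names = c("time_min", "conc_ng_ml"))
  write_timeseries(paths["noiseless"], cond$series$frame_times,
                   cond$series$values)
  noisy <- add_noise(cond$series, 0.129, seed = seed)
  write_timeseries(paths["noisy"], noisy$frame_times, noisy$values)
  fit <- fit_pkpd(cond$plasma, noisy, e0 = preset$params$e0,
                  emax = preset$params$emax, seed = seed)
  jsonlite::write_json(list(
    preset = preset$label, cov = 0.129, seed = seed,
    truth = unclass(preset$params)), paths["meta"],
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    ke_hat = fit$ke_hat, ec50_hat = fit$ec50_hat, n_hat = fit$n_hat,
    objective = fit$objective, converged = fit$converged,
    seed = fit$seed), paths["fit"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
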