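#' Disease-severity pharmacodynamic presets
#'
#' Named parameter sets spanning the Parkinson-disease severity range used
#' in the simulations: equilibration half-lives from 277 min (mildest) to
#' 5 min (most severe), with Hoehn & Yahr stage analogs in between
#' (log-spaced t1/2e). Baseline and maximal effect are 50 and 35 ml/hg/min
#' for every preset. The default EC50 (400-1500 ng/mL, log-spaced) and Hill
#' coefficient (2-8, linear), both increasing with severity, are
#' *illustrative placeholders* for literature per-stage values, which are
#' not bundled; override them from a table of published estimates via
#' `overrides` or [read_presets()].
#'
#' @param overrides Optional `data.frame` replacing the default table;
#'   columns `label`, `t_half_e_min`, `ec50`, `n`, and optionally `e0`,
#'   `emax`. Rows must be ordered mildest to most severe with strictly
#'   decreasing `t_half_e_min` (strictly increasing ke) and satisfy the
#'   usual positivity constraints.
#' @return An ordered list of `severity_preset` objects (`label`, `params`
#'   a [pd_params()]), mildest first; class `severity_presets`.
#' @examples
#' ps <- severity_presets()
#' sapply(ps, function(p) t_half_e(p$params$ke))
#' @export
severity_presets <- function(overrides = NULL) {
  if (is.null(overrides)) {
    tab <- data.frame(
      label = c("mildest", "HY-I", "HY-II", "HY-III", "HY-IV",
                "most-severe"),
      t_half_e_min = exp(seq(log(277), log(5), length.out = 6)),
      ec50 = exp(seq(log(400), log(1500), length.out = 6)),
      n = seq(2, 8, length.out = 6),
      e0 = 50, emax = 35,
      stringsAsFactors = FALSE)
    # pin the printed extremes exactly
    tab$t_half_e_min[c(1, 6)] <- c(277, 5)
  } else {
    tab <- as.data.frame(overrides, stringsAsFactors = FALSE)
    need <- c("label", "t_half_e_min", "ec50", "n")
    if (!all(need %in% names(tab)))
      stop_param(sprintf("overrides must have columns: %s",
                         paste(need, collapse = ", ")))
    if (is.null(tab$e0)) tab$e0 <- 50
    if (is.null(tab$emax)) tab$emax <- 35
    if (nrow(tab) < 2L)
      stop_param("need at least two presets")
    if (any(diff(tab$t_half_e_min) >= 0))
      stop_param(paste0("presets must be ordered mildest to most severe: ",
                        "t_half_e_min strictly decreasing"))
  }
  presets <- lapply(seq_len(nrow(tab)), function(i) {
    structure(list(
      label = as.character(tab$label[i]),
      params = pd_params(e0 = tab$e0[i], emax = tab$emax[i],
                         ec50 = tab$ec50[i], n = tab$n[i],
                         ke = ke_from_t_half(tab$t_half_e_min[i]))),
      class = "severity_preset")
  })
  structure(presets, class = c("severity_presets", "list"))
}

#' @export
`[.severity_presets` <- function(x, i) {
  structure(unclass(x)[i], class = c("severity_presets", "list"))
}

#' @export
print.severity_presets <- function(x, ...) {
  cat("<severity_presets>\n")
  for (p in x)
    cat(sprintf("  %-12s t1/2e %7.4g min  ec50 %6.4g ng/mL  n %.3g\n",
                p$label, t_half_e(p$params$ke), p$params$ec50, p$params$n))
  invisible(x)
}

presets_table <- function(presets) {
  stopifnot(inherits(presets, "severity_presets"))
  do.call(rbind, lapply(presets, function(p) {
    data.frame(label = p$label, t_half_e_min = t_half_e(p$params$ke),
               ec50 = p$params$ec50, n = p$params$n,
               e0 = p$params$e0, emax = p$params$emax,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize severity presets to/from a JSON table
#'
#' The on-disk form is a JSON array of rows with fields `label`,
#' `t_half_e_min`, `ec50`, `n`, `e0`, `emax`, suitable for substituting
#' published per-stage parameter values.
#'
#' @param presets A `severity_presets` object.
#' @param path File path.
#' @return `read_presets()` returns a validated `severity_presets` object.
#' @export
write_presets <- function(presets, path) {
  jsonlite::write_json(presets_table(presets), path, digits = NA)
  invisible(path)
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  severity_presets(jsonlite::fromJSON(path))
}
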