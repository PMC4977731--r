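#' Fitting settings
#'
#' Bundles every tunable of the per-pixel pipeline. Defaults follow the
#' reference procedure: a two-pass lookup-table T1 search over 0–4000 ms
#' (coarse 50 ms grid, then 5 ms grid within ±100 ms of the coarse winner),
#' simplex convergence when the relaxation-time spread between consecutive
#' simplexes drops below 0.10 ms, and exclusion of T2 estimates outside the
#' open interval (0, 400) ms.
#'
#' @param t1_grid_max Upper end of the T1 lookup interval, ms.
#' @param t1_coarse_step Coarse lookup-table spacing, ms.
#' @param t1_fine_step Fine lookup-table spacing, ms.
#' @param t1_fine_halfwidth Half-width of the fine search window around the
#'   coarse winner, ms.
#' @param convergence_tol Simplex convergence tolerance on the relaxation
#'   time, ms.
#' @param t2_exclusion Length-2 numeric: open-interval bounds for admissible
#'   initial T2 values, ms.
#' @param max_iterations Simplex iteration cap; pixels hitting it are marked
#'   unrefined.
#' @param objective Refinement objective: `"sum_squared"` (default) or
#'   `"sum_absolute"`.
#' @param background_fraction Pixels whose maximum absolute signal is below
#'   this fraction of the image maximum are skipped as background.
#' @return A `fit_settings` list.
#' @export
fit_settings <- function(t1_grid_max = 4000, t1_coarse_step = 50,
                         t1_fine_step = 5, t1_fine_halfwidth = 100,
                         convergence_tol = 0.10, t2_exclusion = c(0, 400),
                         max_iterations = 1000L,
                         objective = c("sum_squared", "sum_absolute"),
                         background_fraction = 0.01) {
  objective <- match.arg(objective)
  stopifnot(t1_grid_max > 0, t1_coarse_step > 0, t1_fine_step > 0,
            t1_fine_halfwidth > 0, max_iterations >= 1,
            length(t2_exclusion) == 2L,
            background_fraction >= 0, background_fraction < 1)
  if (t1_fine_step >= t1_coarse_step) {
    stop("t1_fine_step must be smaller than t1_coarse_step", call. = FALSE)
  }
  if (convergence_tol <= 0) stop("convergence_tol must be positive", call. = FALSE)
  if (t2_exclusion[1] < 0 || t2_exclusion[2] <= t2_exclusion[1]) {
    stop("t2_exclusion bounds must be non-negative and ordered", call. = FALSE)
  }
  structure(list(
    t1_grid_max = t1_grid_max, t1_coarse_step = t1_coarse_step,
    t1_fine_step = t1_fine_step, t1_fine_halfwidth = t1_fine_halfwidth,
    convergence_tol = convergence_tol, t2_exclusion = as.numeric(t2_exclusion),
    max_iterations = as.integer(max_iterations), objective = objective,
    background_fraction = background_fraction
  ), class = "fit_settings")
}

#' Read fitting settings from a YAML/JSON-style plain-text config
#'
#' Accepts a JSON file whose keys match the arguments of [fit_settings()];
#' unknown keys are rejected.
#'
#' @param path Path to a JSON config file.
#' @return A `fit_settings` list.
#' @export
read_fit_settings <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(fit_settings))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown fit settings key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(fit_settings, cfg)
}

# stable digest of the settings for provenance records
settings_digest <- function(settings) {
  rlang::hash(unclass(settings))
}
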