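# Modified Bland-Altman agreement analysis: differences are plotted against
# the reference (not the pair mean); percentage forms divide each difference
# by its reference value.

#' Modified Bland-Altman agreement statistics
#'
#' Computes `d = measured - reference`, bias (mean of `d`), variability
#' (sample SD of `d`) and 95 % limits of agreement `bias +/- 1.96 SD`, in ms
#' and as percentages of the reference (`mean(d/reference) * 100`).
#'
#' @param measured Numeric vector of candidate values (ms).
#' @param reference Equal-length vector of reference values (ms, positive).
#' @return A one-row tibble of class `agreement_stats` with columns
#'   `bias_ms`, `sd_ms`, `loa_low_ms`, `loa_high_ms`, `bias_pct`, `sd_pct`,
#'   `loa_low_pct`, `loa_high_pct`, `n`; the paired observations are attached
#'   as attribute `"pairs"`.
#' @examples
#' bland_altman(c(105, 195), c(100, 200))
#' @export
bland_altman <- function(measured, reference) {
  measured <- as.numeric(measured)
  reference <- as.numeric(reference)
  if (length(measured) != length(reference)) {
    stop("measured and reference must have equal length", call. = FALSE)
  }
  if (length(measured) < 1L) stop("no paired observations", call. = FALSE)
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference values must be finite and positive", call. = FALSE)
  }
  d <- measured - reference
  p <- d / reference * 100
  n <- length(d)
  bias <- mean(d)
  s <- if (n >= 2) sd(d) else NA_real_
  bias_pct <- mean(p)
  s_pct <- if (n >= 2) sd(p) else NA_real_
  out <- tibble(
    bias_ms = bias, sd_ms = s,
    loa_low_ms = bias - 1.96 * s, loa_high_ms = bias + 1.96 * s,
    bias_pct = bias_pct, sd_pct = s_pct,
    loa_low_pct = bias_pct - 1.96 * s_pct,
    loa_high_pct = bias_pct + 1.96 * s_pct,
    n = n
  )
  attr(out, "pairs") <- tibble(measured = measured, reference = reference,
                               diff = d, diff_pct = p)
  class(out) <- c("agreement_stats", class(out))
  out
}

#' Pair per-vial map means with reference values
#'
#' Averages the map over the refined pixels of each vial mask and pairs the
#' result with the vial's reference value. Vials with no refined pixels are
#' dropped with a warning.
#'
#' @param map A [fit_map()] result.
#' @param reference Numeric vector of reference values, one per vial.
#' @param vial_masks List of logical matrices (one mask per vial), e.g.
#'   `truth$vial_masks` from [simulate_series()].
#' @return Tibble with columns `vial`, `measured`, `reference`,
#'   `n_refined`.
#' @export
per_vial_means <- function(map, reference, vial_masks) {
  stopifnot(inherits(map, "relaxation_map"), is.list(vial_masks))
  if (length(reference) != length(vial_masks)) {
    stop("one reference value per vial mask is required", call. = FALSE)
  }
  rows <- lapply(seq_along(vial_masks), function(v) {
    m <- vial_masks[[v]]
    if (!all(dim(m) == dim(map$tau_map))) {
      stop("vial mask shape does not match the map", call. = FALSE)
    }
    sel <- m & map$refined_mask
    if (!any(sel)) return(NULL)
    tibble(vial = v, measured = mean(map$tau_map[sel]),
           reference = reference[v], n_refined = sum(sel))
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning("vial(s) ", paste(which(dropped), collapse = ", "),
            " had no refined pixels and were dropped", call. = FALSE)
  }
  do.call(rbind, rows[!dropped])
}
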