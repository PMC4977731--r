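# broom-style accessors: tidy() for per-term / per-pixel tables, glance()
# for one-row fit summaries.

#' @export
tidy.relax_fit <- function(x, ...) {
  terms <- tibble(
    term = c("A", "B", "tau"),
    estimate = c(x$A, x$B, x$tau)
  )
  if (!is.null(x$model) && x$model$needs_look_locker) {
    terms <- rbind(terms, tibble(term = "tau_corrected",
                                 estimate = x$tau_corrected))
  }
  terms
}

#' @export
glance.relax_fit <- function(x, ...) {
  tibble(
    tau = x$tau, tau_corrected = x$tau_corrected,
    residual_pct = x$residual_pct, objective = x$objective_value,
    n_iterations = x$n_iterations, converged = x$converged,
    refined = x$refined, excluded = x$excluded
  )
}

#' @export
tidy.relaxation_map <- function(x, ...) {
  d <- dim(x$tau_map)
  tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    tau = as.vector(x$tau_map),
    residual_pct = as.vector(x$residual_map),
    refined = as.vector(x$refined_mask),
    excluded = as.vector(x$excluded_mask)
  )
}

#' @export
glance.relaxation_map <- function(x, ...) {
  ref <- x$refined_mask
  tibble(
    model_id = x$provenance$model_id, variant = x$provenance$variant,
    n_total = x$n_pixels$total, n_refined = x$n_pixels$refined,
    n_excluded = x$n_pixels$excluded,
    tau_median = if (any(ref)) stats::median(x$tau_map[ref]) else NA_real_,
    residual_median = if (any(ref)) stats::median(x$residual_map[ref],
                                                  na.rm = TRUE) else NA_real_
  )
}

#' @export
tidy.agreement_stats <- function(x, ...) {
  attr(x, "pairs")
}

#' @export
glance.agreement_stats <- function(x, ...) {
  out <- x
  attr(out, "pairs") <- NULL
  class(out) <- setdiff(class(out), "agreement_stats")
  out
}
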