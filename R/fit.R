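# Per-pixel estimation pipeline:
#   T1: two-pass lookup-table initialization (normalized signal, ideal
#       efficiency, sum-of-absolute-error score) -> Nelder-Mead refinement.
#   T2: weighted log-linear initialization with stepwise echo truncation ->
#       open-interval (0, 400) ms exclusion -> Nelder-Mead refinement.
# Unrefined or excluded pixels emit 0 in the resulting map.

#' A single pixel's signal time-series
#'
#' @param values Signal samples (magnitude or signed).
#' @param times Matching preparation times in ms. The anchor frame's nominal
#'   time may be `NA`.
#' @param convention `"magnitude"` or `"signed"`.
#' @param anchor_index Optional index of a saturation-recovery anchor sample
#'   (T2-prepared series only).
#' @return A `pixel_series` with samples sorted by time (anchor last).
#' @export
pixel_series <- function(values, times, convention = c("magnitude", "signed"),
                         anchor_index = NULL) {
  convention <- match.arg(convention)
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (length(values) != length(times)) {
    stop("values and times must have equal length", call. = FALSE)
  }
  if (length(values) < 2L) stop("at least two samples are required", call. = FALSE)
  n <- length(values)
  is_anchor <- rep(FALSE, n)
  if (!is.null(anchor_index)) {
    anchor_index <- as.integer(anchor_index)
    stopifnot(length(anchor_index) == 1L, anchor_index >= 1L, anchor_index <= n)
    is_anchor[anchor_index] <- TRUE
  }
  tt <- times[!is_anchor]
  if (any(!is.finite(tt)) || any(tt < 0)) {
    stop("non-anchor preparation times must be finite and non-negative",
         call. = FALSE)
  }
  if (anyDuplicated(tt)) stop("duplicate preparation times", call. = FALSE)
  idx <- seq_len(n)[!is_anchor][order(times[!is_anchor])]
  ord <- c(idx, which(is_anchor))
  structure(list(values = values[ord], times = times[ord],
                 convention = convention, is_anchor = is_anchor[ord]),
            class = "pixel_series")
}

# lookup-table scores for one normalized pixel over a T1 grid; candidates
# assume unit amplitude and ideal efficiency and are themselves normalized
# by their maximum absolute value over the sampled times
.t1_grid_scores <- function(s_norm, t, grid, B, magnitude) {
  inv <- 1 / pmax(grid, .Machine$double.xmin)   # grid entry 0 -> curve limit
  E <- exp(-outer(t, inv))
  C <- 1 - B * E
  if (magnitude) C <- abs(C)
  cmax <- apply(abs(C), 2L, max)
  C <- sweep(C, 2L, pmax(cmax, .Machine$double.xmin), "/")
  colSums(abs(C - s_norm))
}

#' Two-pass lookup-table T1 initialization
#'
#' The pixel time-series is normalized by its maximum absolute value;
#' candidate recovery curves assume unit amplitude and ideal
#' inversion/saturation efficiency and are normalized the same way. A coarse
#' pass scans the full T1 interval (default 0–4000 ms in 50 ms steps); a fine
#' pass scans a 5 ms grid within ±100 ms of the coarse winner. The entry with
#' the minimum sum of absolute error is returned (ties: smallest T1).
#'
#' @param pixel A [pixel_series()].
#' @param model A T1 [signal_model()].
#' @param settings A [fit_settings()].
#' @return Initial T1 estimate in ms.
#' @export
lookup_init_t1 <- function(pixel, model, settings = fit_settings()) {
  stopifnot(inherits(pixel, "pixel_series"), inherits(model, "signal_model"))
  if (model$family != "t1") stop("lookup_init_t1 requires a T1 model", call. = FALSE)
  v <- pixel$values[!pixel$is_anchor]
  t <- pixel$times[!pixel$is_anchor]
  if (length(v) < 2L) stop("at least two samples are required", call. = FALSE)
  m <- max(abs(v))
  if (m == 0) stop("pixel has no signal (all-zero time-series)", call. = FALSE)
  s <- v / m
  magnitude <- model$code == 1L
  B <- model$ideal_B

  coarse <- seq(0, settings$t1_grid_max, by = settings$t1_coarse_step)
  w <- coarse[which.min(.t1_grid_scores(s, t, coarse, B, magnitude))]
  fine <- seq(max(0, w - settings$t1_fine_halfwidth),
              min(settings$t1_grid_max, w + settings$t1_fine_halfwidth),
              by = settings$t1_fine_step)
  fine[which.min(.t1_grid_scores(s, t, fine, B, magnitude))]
}

#' Weighted log-linear T2 initialization with echo truncation
#'
#' Fits `log S = log A - t/T2` by weighted linear regression (weights
#' `S^2`, compensating the variance inflation of the log transform),
#' repeated for stepwise truncation of the maximum echo time down to three
#' data points. Each candidate is scored by the sum of absolute error of the
#' back-transformed curve over all data points; the winning T2 is returned.
#'
#' Non-positive samples are dropped before the logarithm; if fewer than three
#' remain, or no truncation yields a decaying fit, `NA` is returned and the
#' pixel is to be marked unrefined.
#'
#' @param pixel A [pixel_series()] (anchor samples are ignored).
#' @param settings A [fit_settings()].
#' @return Initial T2 estimate in ms, or `NA_real_` on failure.
#' @export
loglinear_init_t2 <- function(pixel, settings = fit_settings()) {
  stopifnot(inherits(pixel, "pixel_series"))
  keep <- !pixel$is_anchor & pixel$values > 0
  S <- pixel$values[keep]
  t <- pixel$times[keep]
  n <- length(S)
  if (n < 3L) return(NA_real_)
  y <- log(S)
  w <- S^2
  best_score <- Inf
  best_t2 <- NA_real_
  for (k in seq(n, 3L)) {
    idx <- seq_len(k)
    wi <- w[idx]; ti <- t[idx]; yi <- y[idx]
    tw <- sum(wi * ti) / sum(wi)
    yw <- sum(wi * yi) / sum(wi)
    sxx <- sum(wi * (ti - tw)^2)
    if (sxx == 0) next
    slope <- sum(wi * (ti - tw) * (yi - yw)) / sxx
    if (slope >= 0) next
    t2 <- -1 / slope
    A <- exp(yw - slope * tw)
    score <- sum(abs(A * exp(-t / t2) - S))
    if (score < best_score) {
      best_score <- score
      best_t2 <- t2
    }
  }
  best_t2
}

#' Normalized mean absolute residual of a fit
#'
#' The average absolute difference between the fitted curve and the pixel
#' values, normalized by the maximum absolute pixel value within the
#' time-series, as a percentage.
#'
#' @param pixel A [pixel_series()].
#' @param fitted A [model_params()] (or list with `A`, `B`, `tau`).
#' @param model The [signal_model()] used for the fit.
#' @return Residual percentage (`>= 0`), or `NA` if the series is all zero
#'   (flagged with a warning).
#' @export
compute_residual <- function(pixel, fitted, model) {
  stopifnot(inherits(pixel, "pixel_series"), inherits(model, "signal_model"))
  m <- max(abs(pixel$values))
  if (m == 0) {
    warning("residual undefined for an all-zero time-series", call. = FALSE)
    return(NA_real_)
  }
  tt <- pixel$times
  tt[pixel$is_anchor] <- 0  # anchor prediction ignores its nominal time
  pred <- predict_signal(model, fitted, tt, anchor = pixel$is_anchor)
  mean(abs(pred - pixel$values)) / m * 100
}

#' Nelder-Mead refinement of an initialized fit
#'
#' Runs a simplex search over the model's 2 or 3 parameters, minimizing the
#' configured objective (sum of squared residuals by default). Convergence is
#' declared when the maximum absolute difference of the relaxation-time
#' coordinate across corresponding vertices of consecutive simplexes falls
#' below `settings$convergence_tol` (default 0.10 ms). For 3-parameter T2
#' models the offset constraint `B >= 0` is enforced by reparameterization;
#' for MOLLI models the Look-Locker correction is applied to the fitted T1*.
#'
#' @param pixel A [pixel_series()].
#' @param model A [signal_model()].
#' @param init A [model_params()] with the initial `A`, `B`, `tau`.
#' @param settings A [fit_settings()].
#' @param keep_trace Keep the per-iteration best objective values (for
#'   convergence diagnostics).
#' @return A `relax_fit` object.
#' @export
refine_fit <- function(pixel, model, init, settings = fit_settings(),
                       keep_trace = TRUE) {
  stopifnot(inherits(pixel, "pixel_series"), inherits(model, "signal_model"))
  if (!all(is.finite(c(init$A, init$B, init$tau)))) {
    stop("initial parameters must be finite", call. = FALSE)
  }
  tt <- pixel$times
  tt[pixel$is_anchor] <- 0
  B0 <- if (model$variant == "2p") model$ideal_B else init$B
  res <- .nm_refine_cpp(
    pixel$values, tt, pixel$is_anchor,
    model$code, model$n_params, init$A, B0, init$tau,
    b_fixed = model$variant == "2p",
    abs_offset = model$offset_constrained,
    sum_abs = settings$objective == "sum_absolute",
    tol = settings$convergence_tol,
    max_iter = settings$max_iterations,
    keep_trace = keep_trace
  )
  diverged <- !is.finite(res$value)
  refined <- isTRUE(res$converged) && !diverged

  tau_corrected <- res$tau
  ll_flagged <- FALSE
  if (model$needs_look_locker) {
    if (is.finite(res$B) && res$B > 1) {
      tau_corrected <- res$tau * (res$B - 1)
    } else {
      tau_corrected <- NA_real_
      ll_flagged <- TRUE
    }
  }

  fitted <- list(A = res$A, B = res$B, tau = res$tau)
  residual <- if (diverged) NA_real_ else compute_residual(pixel, fitted, model)

  new_relax_fit(
    A = res$A, B = res$B, tau = res$tau, tau_corrected = tau_corrected,
    residual_pct = residual, refined = refined,
    excluded = diverged || ll_flagged,
    converged = isTRUE(res$converged), n_iterations = res$n_iterations,
    objective_value = res$value, monotone = isTRUE(res$monotone),
    trace = res$trace, init = init, model = model, settings = settings
  )
}

new_relax_fit <- function(A, B, tau, tau_corrected, residual_pct, refined,
                          excluded, converged, n_iterations, objective_value,
                          monotone, trace = numeric(0), init = NULL,
                          model = NULL, settings = NULL, init_tau = NULL) {
  structure(list(
    A = A, B = B, tau = tau, tau_corrected = tau_corrected,
    residual_pct = residual_pct, refined = refined, excluded = excluded,
    converged = converged, n_iterations = n_iterations,
    objective_value = objective_value, monotone = monotone, trace = trace,
    init = init, init_tau = if (is.null(init_tau)) init$tau else init_tau,
    model = model, settings = settings
  ), class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("<relax_fit> %s %s\n", x$model$model_id, x$model$variant))
  cat(sprintf("  tau = %.2f ms%s, A = %.4g, B = %.4g\n", x$tau,
              if (!is.null(x$model) && x$model$needs_look_locker)
                sprintf(" (corrected T1 = %.2f ms)", x$tau_corrected) else "",
              x$A, x$B))
  cat(sprintf("  residual = %.3f %%, refined = %s, excluded = %s, %d iterations\n",
              x$residual_pct, x$refined, x$excluded, x$n_iterations))
  invisible(x)
}

#' Apply the exclusion rules to a fit result
#'
#' T2 pixels whose initial estimate falls outside the open admissible
#' interval (default 0 < T2 < 400 ms) are excluded; excluded and unrefined
#' pixels emit 0 in the resulting map. T1 results pass through (their lookup
#' initialization is already clamped to the grid interval), except that
#' unrefined pixels likewise emit 0.
#'
#' @param result A `relax_fit`.
#' @param model The [signal_model()] used.
#' @param settings A [fit_settings()].
#' @return The result with `excluded` updated and `map_value` set.
#' @export
apply_exclusion <- function(result, model, settings = fit_settings()) {
  stopifnot(inherits(result, "relax_fit"), inherits(model, "signal_model"))
  if (model$family == "t2" && !is.null(result$init_tau)) {
    it <- result$init_tau
    eps <- 1e-6
    if (is.na(it) || it <= settings$t2_exclusion[1] + eps ||
        it >= settings$t2_exclusion[2] - eps) {
      result$excluded <- TRUE
      result$refined <- FALSE
    }
  }
  emit <- if (model$needs_look_locker) result$tau_corrected else result$tau
  if (result$excluded || !result$refined || !is.finite(emit)) {
    result$map_value <- 0
  } else {
    result$map_value <- emit
  }
  result
}

#' Fit one pixel end-to-end
#'
#' Runs initialization (lookup-table for T1, weighted log-linear for T2),
#' the exclusion rule, Nelder-Mead refinement, the Look-Locker correction
#' where applicable, and the residual calculation.
#'
#' @inheritParams refine_fit
#' @return A `relax_fit` with `map_value` set.
#' @export
fit_pixel <- function(pixel, model, settings = fit_settings(),
                      keep_trace = FALSE) {
  stopifnot(inherits(pixel, "pixel_series"), inherits(model, "signal_model"))
  if (pixel$convention == "signed" && model$signal_convention == "magnitude") {
    stop("signed data cannot be fitted with a magnitude-convention model",
         call. = FALSE)
  }
  A0 <- max(abs(pixel$values))
  if (model$family == "t1") {
    tau0 <- lookup_init_t1(pixel, model, settings)
    # clamp to the lookup interval; floor at the fine-grid step so the
    # simplex never starts at tau = 0
    tau0 <- min(max(tau0, settings$t1_fine_step), settings$t1_grid_max)
    B0 <- model$ideal_B
  } else {
    tau0 <- loglinear_init_t2(pixel, settings)
    if (model$variant == "3p") {
      # seed the offset from the anchor sample when present, else from the
      # latest-echo floor; a zero seed cripples the initial simplex
      B0 <- if (any(pixel$is_anchor)) max(pixel$values[pixel$is_anchor], 0)
            else max(min(pixel$values[!pixel$is_anchor]), 0)
      A0 <- max(A0 - B0, 0.1 * A0)
    } else {
      B0 <- 0
    }
  }

  failed_init <- is.na(tau0)
  excluded_init <- FALSE
  if (!failed_init && model$family == "t2") {
    # open interval, guarded by a micro-ms band against floating-point
    # round-off at the boundaries
    eps <- 1e-6
    excluded_init <- tau0 <= settings$t2_exclusion[1] + eps ||
      tau0 >= settings$t2_exclusion[2] - eps
  }
  if (failed_init || excluded_init) {
    res <- new_relax_fit(
      A = A0, B = B0, tau = if (failed_init) NA_real_ else tau0,
      tau_corrected = NA_real_, residual_pct = NA_real_,
      refined = FALSE, excluded = TRUE, converged = FALSE,
      n_iterations = 0L, objective_value = NA_real_, monotone = TRUE,
      init = NULL, init_tau = tau0, model = model, settings = settings
    )
    return(apply_exclusion(res, model, settings))
  }

  init <- model_params(A = A0, B = B0, tau = tau0)
  res <- refine_fit(pixel, model, init, settings, keep_trace = keep_trace)
  res$init_tau <- tau0
  apply_exclusion(res, model, settings)
}
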