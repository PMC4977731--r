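# Map assembly: runs the per-pixel pipeline over an image stack and packs
# the results into matrix-backed relaxation-map objects.

#' A co-registered multi-timepoint image series
#'
#' @param frames Numeric array `height x width x n_frames`.
#' @param times Per-frame preparation times in ms (inversion time, saturation
#'   time, echo time or T2-preparation duration). The anchor frame's time may
#'   be `NA`.
#' @param convention `"magnitude"` or `"signed"` (PSIR).
#' @param model_hint Optional model identifier recorded with the series.
#' @param anchor_index Optional index of the saturation-recovery anchor frame
#'   of a T2-prepared series.
#' @return An `image_series`; frames are sorted by time (anchor last).
#' @export
image_series <- function(frames, times, convention = c("magnitude", "signed"),
                         model_hint = NULL, anchor_index = NULL) {
  convention <- match.arg(convention)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) {
    stop("frames must be a height x width x n_frames array", call. = FALSE)
  }
  n <- dim(frames)[3]
  if (length(times) != n) {
    stop("frame count and time count differ", call. = FALSE)
  }
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
  structure(list(
    frames = frames[, , ord, drop = FALSE],
    times = as.numeric(times)[ord],
    convention = convention,
    model_hint = model_hint,
    anchor_index = if (any(is_anchor)) n else NULL,  # anchor sorted last
    is_anchor = is_anchor[ord]
  ), class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series> %d x %d, %d frames (%s)%s\n", d[1], d[2], d[3],
              x$convention,
              if (!is.null(x$anchor_index)) ", with SR anchor" else ""))
  cat("  times (ms):", paste(signif(x$times, 5), collapse = " "), "\n")
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param mask Logical matrix (or coercible) marking ROI pixels.
#' @return An `roi` object.
#' @export
roi_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask), class = "roi")
}

.series_pixel <- function(series, i, j) {
  pixel_series(series$frames[i, j, ], series$times, series$convention,
               anchor_index = series$anchor_index)
}

#' Fit a relaxation map pixel by pixel
#'
#' Every foreground pixel (optionally restricted to an ROI) runs through
#' initialization, exclusion, Nelder-Mead refinement and residual
#' calculation. Background pixels — maximum absolute signal below
#' `settings$background_fraction` of the image maximum — are skipped and
#' emit 0. Excluded and unrefined pixels also emit 0.
#'
#' @param series An [image_series()].
#' @param model A [signal_model()].
#' @param settings A [fit_settings()].
#' @param roi Optional [roi_mask()] restricting the fit.
#' @return A `relaxation_map` with components `tau_map` (ms; Look-Locker
#'   corrected for MOLLI), `residual_map` (%, `NA` where not refined),
#'   `A_map`, `B_map`, `refined_mask`, `excluded_mask`, `monotone` (simplex
#'   diagnostics) and `provenance`.
#' @export
fit_map <- function(series, model, settings = fit_settings(), roi = NULL) {
  stopifnot(inherits(series, "image_series"), inherits(model, "signal_model"))
  if (series$convention == "signed" && model$signal_convention == "magnitude") {
    stop("signed data cannot be fitted with a magnitude-convention model",
         call. = FALSE)
  }
  if (!is.null(series$anchor_index) && !model$supports_anchor) {
    # anchor frame is only meaningful for the 3-parameter T2-prep fit;
    # other models ignore it entirely
    series$frames <- series$frames[, , !series$is_anchor, drop = FALSE]
    series$times <- series$times[!series$is_anchor]
    series$is_anchor <- series$is_anchor[!series$is_anchor]
    series$anchor_index <- NULL
  }
  d <- dim(series$frames)
  h <- d[1]; w <- d[2]; n <- d[3]

  maxabs <- abs(series$frames[, , 1])
  if (n > 1) for (k in 2:n) maxabs <- pmax(maxabs, abs(series$frames[, , k]))
  gate <- settings$background_fraction * max(maxabs)
  active <- maxabs > gate & maxabs > 0
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi"))
    if (!all(dim(roi$mask) == c(h, w))) {
      stop("roi mask shape does not match the image frames", call. = FALSE)
    }
    active <- active & roi$mask
  }

  tau_map <- matrix(0, h, w)
  residual_map <- matrix(NA_real_, h, w)
  A_map <- matrix(NA_real_, h, w)
  B_map <- matrix(NA_real_, h, w)
  refined_mask <- matrix(FALSE, h, w)
  excluded_mask <- matrix(FALSE, h, w)
  monotone <- TRUE
  n_iter_total <- 0L

  idx <- which(active, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    px <- .series_pixel(series, i, j)
    fit <- fit_pixel(px, model, settings, keep_trace = FALSE)
    tau_map[i, j] <- fit$map_value
    refined_mask[i, j] <- fit$refined
    excluded_mask[i, j] <- fit$excluded
    if (fit$refined) {
      residual_map[i, j] <- fit$residual_pct
      A_map[i, j] <- fit$A
      B_map[i, j] <- fit$B
    }
    monotone <- monotone && fit$monotone
    n_iter_total <- n_iter_total + fit$n_iterations
  }

  structure(list(
    tau_map = tau_map, residual_map = residual_map,
    A_map = A_map, B_map = B_map,
    refined_mask = refined_mask, excluded_mask = excluded_mask,
    active_mask = active, monotone = monotone,
    n_pixels = list(total = h * w, active = sum(active),
                    refined = sum(refined_mask), excluded = sum(excluded_mask)),
    n_iterations_total = n_iter_total,
    times = series$times, convention = series$convention,
    anchor_index = series$anchor_index,
    provenance = list(model_id = model$model_id, variant = model$variant,
                      settings = unclass(settings),
                      settings_digest = settings_digest(settings))
  ), class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf("<relaxation_map> %s %s, %d x %d\n",
              x$provenance$model_id, x$provenance$variant,
              nrow(x$tau_map), ncol(x$tau_map)))
  cat(sprintf("  pixels: %d total, %d fitted, %d refined, %d excluded\n",
              x$n_pixels$total, x$n_pixels$active, x$n_pixels$refined,
              x$n_pixels$excluded))
  if (x$n_pixels$refined > 0) {
    rng <- range(x$tau_map[x$refined_mask])
    cat(sprintf("  tau range (refined): %.1f - %.1f ms\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Fit the ROI-mean signal
#'
#' Averages the signal over the ROI per frame, then runs the single-pixel
#' pipeline on the mean series (ROI-based global mean mapping).
#'
#' @inheritParams fit_map
#' @param roi An [roi_mask()]; must be non-empty.
#' @return A `relax_fit`.
#' @export
fit_roi_mean <- function(series, model, settings = fit_settings(), roi) {
  stopifnot(inherits(series, "image_series"), inherits(roi, "roi"))
  if (!any(roi$mask)) stop("roi is empty", call. = FALSE)
  d <- dim(series$frames)
  if (!all(dim(roi$mask) == d[1:2])) {
    stop("roi mask shape does not match the image frames", call. = FALSE)
  }
  mean_values <- vapply(seq_len(d[3]), function(k) {
    mean(series$frames[, , k][roi$mask])
  }, numeric(1))
  px <- pixel_series(mean_values, series$times, series$convention,
                     anchor_index = series$anchor_index)
  fit_pixel(px, model, settings, keep_trace = TRUE)
}

#' Recompute the spatial residual map
#'
#' Evaluates the normalized mean absolute residual percentage per pixel from
#' the fitted parameter maps. Unrefined pixels carry `NA`.
#'
#' @param series The [image_series()] the map was fitted from.
#' @param map The [fit_map()] result.
#' @param model The [signal_model()] used.
#' @return Numeric matrix of residual percentages.
#' @export
residual_map <- function(series, map, model) {
  stopifnot(inherits(series, "image_series"), inherits(map, "relaxation_map"),
            inherits(model, "signal_model"))
  d <- dim(series$frames)
  if (!all(dim(map$tau_map) == d[1:2])) {
    stop("map shape does not match the series frames", call. = FALSE)
  }
  if (!is.null(series$anchor_index) && !model$supports_anchor) {
    series$frames <- series$frames[, , !series$is_anchor, drop = FALSE]
    series$times <- series$times[!series$is_anchor]
    series$is_anchor <- series$is_anchor[!series$is_anchor]
    series$anchor_index <- NULL
  }
  out <- matrix(NA_real_, d[1], d[2])
  idx <- which(map$refined_mask, arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    px <- .series_pixel(series, i, j)
    fitted <- list(A = map$A_map[i, j], B = map$B_map[i, j],
                   tau = if (model$needs_look_locker)
                     map$tau_map[i, j] / (map$B_map[i, j] - 1)
                   else map$tau_map[i, j])
    out[i, j] <- compute_residual(px, fitted, model)
  }
  out
}
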