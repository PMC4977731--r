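# Synthetic multi-vial gel phantom simulator. Generates image series with
# known per-pixel ground truth so the whole mapping pipeline is testable
# without scanner data.

.SCHEDULES <- list(
  ir_se        = c(21, 60, 100, 200, 300, 500, 660, 900, 1050, 1300, 1600,
                   2000, 2250, 2500, 3000, 3500, 4300),
  psir         = c(150, 300, 400, 500, 700, 900, 1100, 1300, 1800, 2000,
                   2500, 3000, 3700, 4300, 5000, 6300),
  sr_bssfp     = c(150, 300, 400, 500, 700, 900, 1100, 1300, 1800, 2000,
                   2500, 3000, 3700, 4300, 5000, 5600, 6300, 8000),
  molli        = c(130, 210, 1130, 1210, 2130, 2210, 3130, 4130),
  se_t2_single = c(6, 12, 20, 30, 40, 50, 70, 90, 120, 140, 180, 300, 400,
                   600, 1000),
  se_t2_multi  = seq(9, 144, by = 9),
  t2prep       = seq(25, 200, by = 5)
)

#' Preset acquisition timing schedules
#'
#' Returns the preparation-time schedule of one of the supported protocols:
#' inversion times for `"ir_se"`, `"psir"`, `"sr_bssfp"` and `"molli"`
#' (merged 5(3b)3 delays at 60 bpm), echo times for `"se_t2_single"` and
#' `"se_t2_multi"`, and T2-preparation durations for `"t2prep"` (25–200 ms in
#' 5 ms steps plus a saturation-recovery anchor frame).
#'
#' @param preset Schedule name.
#' @return A list with `times` (ms; the anchor slot is `NA`) and
#'   `anchor_index` (or `NULL`).
#' @export
timing_schedule <- function(preset = names(.SCHEDULES)) {
  preset <- match.arg(preset)
  times <- .SCHEDULES[[preset]]
  if (preset == "t2prep") {
    list(times = c(times, NA_real_), anchor_index = length(times) + 1L)
  } else {
    list(times = times, anchor_index = NULL)
  }
}

.default_schedule_for <- function(model_id) {
  switch(model_id,
         ir_se_mag = "ir_se", psir = "psir", sr_bssfp = "sr_bssfp",
         molli_mag = "molli", molli_psir = "molli",
         se_t2 = "se_t2_multi", t2prep_bssfp = "t2prep")
}

.default_B_for <- function(model) {
  if (model$family == "t2") {
    if (model$variant == "3p") 5 else 0
  } else if (model$needs_look_locker) {
    1.8
  } else {
    model$ideal_B
  }
}

#' Specify a synthetic multi-vial phantom
#'
#' @param vials Data frame with one row per vial: columns `cx`, `cy`
#'   (centers, pixels), `radius` (pixels), `T1`, `T2` (ms), `A` (amplitude)
#'   and optionally `B` (efficiency factor / offset; defaults to the model's
#'   nominal value).
#' @param shape Image dimensions `c(height, width)`.
#' @param model A [signal_model()] to synthesize (or a model id string).
#' @param times Schedule of preparation times (ms); defaults to the model's
#'   preset schedule.
#' @param anchor_index Index of the SR anchor frame within `times`, if any.
#' @param noise_sigma Noise standard deviation in signal units (per Gaussian
#'   channel).
#' @param seed Integer seed making the simulation deterministic.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(vials, shape = c(64, 64), model = "sr_bssfp",
                         times = NULL, anchor_index = NULL,
                         noise_sigma = 0, seed = 1L) {
  if (is.character(model)) model <- signal_model(model)
  stopifnot(inherits(model, "signal_model"))
  vials <- as_tibble(vials)
  req <- c("cx", "cy", "radius", "T1", "T2", "A")
  if (!all(req %in% names(vials))) {
    stop("vials must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"B" %in% names(vials)) vials$B <- .default_B_for(model)
  if (!"vial" %in% names(vials)) vials$vial <- seq_len(nrow(vials))
  # non-overlap check
  if (nrow(vials) > 1) {
    for (i in seq_len(nrow(vials) - 1)) {
      for (j in seq(i + 1, nrow(vials))) {
        dd <- sqrt((vials$cx[i] - vials$cx[j])^2 + (vials$cy[i] - vials$cy[j])^2)
        if (dd < vials$radius[i] + vials$radius[j]) {
          stop("vials overlap", call. = FALSE)
        }
      }
    }
  }
  if (is.null(times)) {
    sched <- timing_schedule(.default_schedule_for(model$model_id))
    times <- sched$times
    anchor_index <- sched$anchor_index
  }
  if (length(times) == 0) stop("timing schedule is empty", call. = FALSE)
  structure(list(vials = vials, shape = as.integer(shape), model = model,
                 times = as.numeric(times), anchor_index = anchor_index,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default 12-vial gel phantom presets
#'
#' Builds a 12-vial phantom whose T1 and T2 values span the reference ranges
#' of a commercial gadolinium/agarose gel set at the chosen field strength:
#' 214–1643 ms (T1) and 46–338 ms (T2) at 1.5 T, 229–1752 ms and 45–316 ms
#' at 3 T. Endpoints are included; interior values are log-spaced. Vials are
#' laid out on a 3 x 4 grid with a 10 % margin.
#'
#' @param field `"1.5T"` or `"3T"`.
#' @param shape Image dimensions `c(height, width)`.
#' @param model Model to synthesize (id string or [signal_model()]).
#' @param A Vial amplitude.
#' @param B Optional efficiency factor / offset for all vials.
#' @param noise_sigma,seed See [phantom_spec()].
#' @return A `phantom_spec` with 12 vials.
#' @export
default_eurospin_specs <- function(field = c("1.5T", "3T"), shape = c(64, 64),
                                   model = "sr_bssfp", A = 100, B = NULL,
                                   noise_sigma = 0, seed = 1L) {
  field <- match.arg(field)
  rng <- switch(field,
                "1.5T" = list(T1 = c(214, 1643), T2 = c(46, 338)),
                "3T"   = list(T1 = c(229, 1752), T2 = c(45, 316)))
  logspace <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  T1 <- logspace(rng$T1[1], rng$T1[2], 12)
  T2 <- logspace(rng$T2[1], rng$T2[2], 12)

  h <- shape[1]; w <- shape[2]
  my <- 0.1 * h; mx <- 0.1 * w
  ny <- 4; nx <- 3   # 3 x 4 grid
  cy <- my + (seq_len(ny) - 0.5) * (h - 2 * my) / ny
  cx <- mx + (seq_len(nx) - 0.5) * (w - 2 * mx) / nx
  centers <- expand.grid(cy = cy, cx = cx)
  radius <- 0.3 * min((h - 2 * my) / ny, (w - 2 * mx) / nx)

  vials <- tibble(
    vial = 1:12,
    cx = centers$cx, cy = centers$cy, radius = radius,
    T1 = T1, T2 = T2, A = A
  )
  if (!is.null(B)) vials$B <- B
  phantom_spec(vials, shape = shape, model = model,
               noise_sigma = noise_sigma, seed = seed)
}

#' Simulate a phantom image series with ground truth
#'
#' Synthesizes the noiseless signal of the spec's model at every scheduled
#' time for each vial, then corrupts it with Rician noise for magnitude
#' conventions (modulus of two Gaussian-corrupted channels) or additive
#' Gaussian noise for signed conventions. Deterministic under the spec seed.
#'
#' For MOLLI models the vial `T1` column is the true T1 and the apparent
#' relaxation time used for synthesis is `T1* = T1 / (B - 1)`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `series` (an [image_series()]) and `truth` (a list of
#'   per-pixel `T1`, `T2`, `A`, `B` matrices plus a `vial_masks` list and the
#'   vial table; background pixels carry zeros).
#' @export
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  model <- spec$model
  h <- spec$shape[1]; w <- spec$shape[2]
  n <- length(spec$times)
  is_anchor <- rep(FALSE, n)
  if (!is.null(spec$anchor_index)) is_anchor[spec$anchor_index] <- TRUE
  tt <- spec$times
  tt[is_anchor] <- 0

  frames <- array(0, dim = c(h, w, n))
  T1m <- matrix(0, h, w); T2m <- matrix(0, h, w)
  Am <- matrix(0, h, w); Bm <- matrix(0, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  vial_masks <- vector("list", nrow(spec$vials))

  for (v in seq_len(nrow(spec$vials))) {
    vi <- spec$vials[v, ]
    mask <- (xx - vi$cx)^2 + (yy - vi$cy)^2 <= vi$radius^2
    vial_masks[[v]] <- mask
    tau <- if (model$family == "t1") vi$T1 else vi$T2
    if (model$needs_look_locker) {
      if (vi$B <= 1) stop("MOLLI simulation requires vial B > 1", call. = FALSE)
      tau <- vi$T1 / (vi$B - 1)   # apparent T1*
    }
    curve <- predict_signal(model, list(A = vi$A, B = vi$B, tau = tau),
                            tt, anchor = is_anchor)
    for (k in seq_len(n)) {
      fr <- frames[, , k]
      fr[mask] <- curve[k]
      frames[, , k] <- fr
    }
    T1m[mask] <- vi$T1; T2m[mask] <- vi$T2
    Am[mask] <- vi$A; Bm[mask] <- vi$B
  }

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    sg <- spec$noise_sigma
    if (model$signal_convention == "magnitude") {
      n1 <- array(stats::rnorm(h * w * n, sd = sg), dim = dim(frames))
      n2 <- array(stats::rnorm(h * w * n, sd = sg), dim = dim(frames))
      frames <- sqrt((frames + n1)^2 + n2^2)
    } else {
      frames <- frames + array(stats::rnorm(h * w * n, sd = sg), dim = dim(frames))
    }
  }

  series <- image_series(frames, spec$times, model$signal_convention,
                         model_hint = model$model_id,
                         anchor_index = spec$anchor_index)
  truth <- list(T1 = T1m, T2 = T2m, A = Am, B = Bm,
                vial_masks = vial_masks, vials = spec$vials)
  list(series = series, truth = truth)
}

#' Merged inversion-time schedule of a MOLLI scheme
#'
#' A scheme like `5(3b)3` acquires 5 images after a first inversion, pauses
#' 3 recovery beats, then 3 images after a second inversion; within an
#' inversion epoch successive images are one R-R interval apart. Initial
#' inversion times step by 80 ms per epoch starting at 130 ms, so at 60 bpm
#' `5(3b)3` yields the merged delays 130, 210, 1130, 1210, 2130, 2210, 3130,
#' 4130 ms.
#'
#' @param scheme `"5(3b)3"` or `"4(1b)3(1b)2"`.
#' @param heart_rate_bpm Heart rate in beats per minute (positive).
#' @param ti1 First inversion time, ms.
#' @param ti_increment Inversion-time increment per epoch, ms.
#' @return Sorted numeric vector of effective inversion times, ms.
#' @export
molli_schedule <- function(scheme = c("5(3b)3", "4(1b)3(1b)2"),
                           heart_rate_bpm = 60, ti1 = 130, ti_increment = 80) {
  if (!is.character(scheme) || length(scheme) != 1L) {
    stop("scheme must be a single string", call. = FALSE)
  }
  scheme <- match.arg(scheme)
  if (heart_rate_bpm <= 0) stop("heart rate must be positive", call. = FALSE)
  counts <- as.integer(regmatches(scheme, gregexpr("[0-9]+", scheme))[[1]])
  # odd positions: images per epoch; even positions: recovery beats
  n_images <- counts[seq(1, length(counts), by = 2)]
  rr <- 60000 / heart_rate_bpm
  tis <- unlist(lapply(seq_along(n_images), function(k) {
    ti1 + ti_increment * (k - 1) + rr * (seq_len(n_images[k]) - 1)
  }))
  sort(tis)
}

#' Simulate a MOLLI acquisition at a given heart rate
#'
#' Generates the merged inversion-time schedule implied by the scheme, then
#' synthesizes the phenomenological apparent-T1 signal
#' `S(t) = A (1 - B exp(-t/T1*))` with `T1* = T1/(B - 1)`, so the
#' Look-Locker-corrected ground truth equals the vial `T1`.
#'
#' @param spec A [phantom_spec()] whose model is `molli_mag` or `molli_psir`.
#' @param scheme `"5(3b)3"` (pre-contrast) or `"4(1b)3(1b)2"` (post-contrast).
#' @param heart_rate_bpm Heart rate in beats per minute.
#' @return As [simulate_series()].
#' @export
simulate_molli_series <- function(spec, scheme = "5(3b)3", heart_rate_bpm = 60) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$model$needs_look_locker) {
    stop("simulate_molli_series requires a MOLLI model", call. = FALSE)
  }
  spec$times <- molli_schedule(scheme, heart_rate_bpm)
  spec$anchor_index <- NULL
  simulate_series(spec)
}
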