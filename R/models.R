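# Signal-model registry.
#
# Seven supported sequence families, each with a 2-parameter and/or
# 3-parameter mono-exponential model:
#
#   ir_se_mag     T1 inversion-recovery spin echo, magnitude:
#                   3p  S(t) = |A (1 - B exp(-t/T1))|
#                   2p  S(t) = |A (1 - 2 exp(-t/T1))|
#   psir          T1 phase-sensitive inversion recovery (signed data):
#                   3p  S(t) = A (1 - B exp(-t/T1));  2p fixes B = 2
#   sr_bssfp      T1 saturation-recovery bSSFP:
#                   3p  S(t) = A (1 - B exp(-t/T1));  2p fixes B = 1
#   molli_mag     MOLLI magnitude, 3p only: S(t) = |A (1 - B exp(-t/T1*))|,
#                   followed by Look-Locker correction T1 = T1* (B - 1)
#   molli_psir    MOLLI PSIR, 3p only (signed), same correction
#   se_t2         T2 spin echo (single- or multi-echo):
#                   3p  S(t) = A exp(-t/T2) + B, B >= 0;  2p drops B
#   t2prep_bssfp  T2-prepared bSSFP, same models; the 3p fit may include a
#                   saturation-recovery anchor image predicted as the
#                   asymptote B

.MODEL_REGISTRY <- list(
  ir_se_mag    = list(code = 1L, convention = "magnitude", family = "t1",
                      needs_look_locker = FALSE, ideal_B = 2, variants = c("2p", "3p")),
  psir         = list(code = 2L, convention = "signed", family = "t1",
                      needs_look_locker = FALSE, ideal_B = 2, variants = c("2p", "3p")),
  sr_bssfp     = list(code = 2L, convention = "signed", family = "t1",
                      needs_look_locker = FALSE, ideal_B = 1, variants = c("2p", "3p")),
  molli_mag    = list(code = 1L, convention = "magnitude", family = "t1",
                      needs_look_locker = TRUE, ideal_B = 2, variants = "3p"),
  molli_psir   = list(code = 2L, convention = "signed", family = "t1",
                      needs_look_locker = TRUE, ideal_B = 2, variants = "3p"),
  se_t2        = list(code = 3L, convention = "magnitude", family = "t2",
                      needs_look_locker = FALSE, ideal_B = 0, variants = c("2p", "3p")),
  t2prep_bssfp = list(code = 3L, convention = "magnitude", family = "t2",
                      needs_look_locker = FALSE, ideal_B = 0, variants = c("2p", "3p"))
)

#' Supported signal model identifiers
#'
#' @return Character vector of the stable model identifiers accepted by
#'   [signal_model()] and the command-line interface.
#' @export
model_ids <- function() names(.MODEL_REGISTRY)

#' Construct a relaxation signal model
#'
#' A `signal_model` pairs one of the seven supported sequence families with a
#' fit variant (`"3p"` or `"2p"`). Two-parameter variants fix the
#' recovery/efficiency factor at its ideal value (B = 2 for inversion
#' recovery, B = 1 for saturation recovery) or drop the additive offset
#' (T2 models). The MOLLI models are 3-parameter only and carry a
#' Look-Locker post-correction.
#'
#' @param model_id One of [model_ids()].
#' @param variant `"3p"` (default) or `"2p"`.
#' @return An object of class `signal_model`.
#' @examples
#' m <- signal_model("ir_se_mag", "2p")
#' predict_signal(m, model_params(A = 100, B = 2, tau = 1000), t = 693.1)
#' @export
signal_model <- function(model_id, variant = c("3p", "2p")) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% names(.MODEL_REGISTRY)) {
    stop("unknown model_id; see model_ids()", call. = FALSE)
  }
  variant <- match.arg(variant)
  reg <- .MODEL_REGISTRY[[model_id]]
  if (!variant %in% reg$variants) {
    stop(sprintf("model '%s' does not support the %s variant", model_id, variant),
         call. = FALSE)
  }
  structure(list(
    model_id = model_id,
    variant = variant,
    n_params = if (variant == "3p") 3L else 2L,
    signal_convention = reg$convention,
    needs_look_locker = reg$needs_look_locker,
    family = reg$family,
    ideal_B = reg$ideal_B,
    # offset constrained (B >= 0) only for the 3-parameter T2 rows
    offset_constrained = reg$family == "t2" && variant == "3p",
    supports_anchor = model_id == "t2prep_bssfp" && variant == "3p",
    code = reg$code
  ), class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf("<signal_model> %s (%s, %s, %s convention%s)\n",
              x$model_id, x$variant,
              if (x$family == "t1") "T1" else "T2",
              x$signal_convention,
              if (x$needs_look_locker) ", Look-Locker corrected" else ""))
  invisible(x)
}

#' Model parameters for signal prediction
#'
#' @param A Signal amplitude (arbitrary units).
#' @param B Recovery/efficiency factor (dimensionless, T1 models) or
#'   additive offset in signal units (T2 models).
#' @param tau Relaxation time constant in ms (T1, T1* or T2).
#' @return A `model_params` list.
#' @export
model_params <- function(A, B, tau) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(tau),
            length(A) == 1L, length(B) == 1L, length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(list(A = A, B = B, tau = tau), class = "model_params")
}

#' Evaluate the predicted signal of a model
#'
#' Returns the model curve at preparation times `t` (ms). Magnitude models
#' apply the absolute value; signed models (PSIR, SR) may return negative
#' values. For two-parameter variants the supplied `B` is ignored and the
#' model's fixed value is used.
#'
#' @param model A [signal_model()].
#' @param params A [model_params()] (a plain list with `A`, `B`, `tau` also
#'   works).
#' @param t Numeric vector of preparation times in ms, all `>= 0`.
#' @param anchor Logical vector marking saturation-recovery anchor samples
#'   (predicted as the asymptote `B`); recycled to `length(t)`.
#' @return Numeric vector of predicted signal values.
#' @export
predict_signal <- function(model, params, t, anchor = FALSE) {
  stopifnot(inherits(model, "signal_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("preparation times must be finite and non-negative", call. = FALSE)
  }
  anchor <- rep_len(as.logical(anchor), length(t))
  if (any(anchor) && !model$supports_anchor) {
    stop("anchor samples are only defined for the 3-parameter t2prep_bssfp model",
         call. = FALSE)
  }
  A <- params$A
  B <- if (model$variant == "2p") model$ideal_B else params$B
  tau <- params$tau
  if (model$offset_constrained && B < 0) {
    stop("T2 3-parameter offset B must be non-negative", call. = FALSE)
  }
  e <- exp(-t / tau)
  out <- if (model$code == 3L) A * e + B else A * (1 - B * e)
  if (model$code == 1L) out <- abs(out)
  out[anchor] <- B
  out
}

#' Look-Locker correction from apparent T1* to T1
#'
#' MOLLI-type continuous readout yields an apparent relaxation time T1*;
#' the corrected value is `T1 = T1* (B - 1)`. The correction is only
#' physically meaningful for `B > 1`: entries with `B <= 1` are returned as
#' `NA` (flagged) rather than silently emitted, and a warning is raised.
#'
#' @param t1_star Apparent T1* in ms (positive).
#' @param B Fitted recovery factor (dimensionless).
#' @return Corrected T1 in ms; `NA` where `B <= 1`.
#' @examples
#' look_locker_correct(1000, 2)   # 1000
#' look_locker_correct(700, 2.5)  # 1050
#' @export
look_locker_correct <- function(t1_star, B) {
  stopifnot(is.numeric(t1_star), is.numeric(B))
  if (any(t1_star <= 0, na.rm = TRUE)) stop("t1_star must be positive", call. = FALSE)
  n <- max(length(t1_star), length(B))
  t1_star <- rep_len(t1_star, n)
  B <- rep_len(B, n)
  out <- t1_star * (B - 1)
  bad <- !is.na(B) & B <= 1
  if (any(bad)) {
    out[bad] <- NA_real_
    warning("Look-Locker correction flagged ", sum(bad),
            " value(s) with B <= 1 (non-physical)", call. = FALSE)
  }
  out
}

#' Predicted signal of the saturation-recovery anchor sample
#'
#' In the 3-parameter T2-prepared bSSFP fit, an SR-prepared image with short
#' saturation time anchors the additive offset: it is treated as a sample at
#' effectively infinite preparation duration, whose model prediction is the
#' asymptote `B`.
#'
#' @param model A 3-parameter `t2prep_bssfp` [signal_model()].
#' @param params A [model_params()].
#' @return The predicted anchor signal (`B`).
#' @export
sr_anchor_prediction <- function(model, params) {
  stopifnot(inherits(model, "signal_model"))
  if (!model$supports_anchor) {
    stop("anchor prediction requires the 3-parameter t2prep_bssfp model",
         call. = FALSE)
  }
  params$B
}
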