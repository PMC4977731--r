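# Independent oracles, deliberately coded with plain loops and base R so
# they share no code path with the package internals.

# exhaustive two-pass lookup-table search: normalize pixel by max |value|,
# candidates at unit amplitude / ideal efficiency normalized the same way,
# sum of absolute error, coarse 50 ms pass then fine 5 ms pass within
# +/- 100 ms, ties to the smallest T1
oracle_lookup_t1 <- function(values, times, ideal_B, magnitude,
                             grid_max = 4000, coarse = 50, fine = 5,
                             halfwidth = 100) {
  s <- values / max(abs(values))
  score_one <- function(T1) {
    err <- 0
    cand <- numeric(length(times))
    for (i in seq_along(times)) {
      e <- if (T1 == 0) {
        if (times[i] > 0) 0 else 1
      } else {
        exp(-times[i] / T1)
      }
      cand[i] <- 1 - ideal_B * e
      if (magnitude) cand[i] <- abs(cand[i])
    }
    cand <- cand / max(abs(cand))
    for (i in seq_along(times)) err <- err + abs(cand[i] - s[i])
    err
  }
  best_t1 <- NA_real_
  best_err <- Inf
  for (T1 in seq(0, grid_max, by = coarse)) {
    e <- score_one(T1)
    if (e < best_err) { best_err <- e; best_t1 <- T1 }
  }
  lo <- max(0, best_t1 - halfwidth)
  hi <- min(grid_max, best_t1 + halfwidth)
  best_err <- Inf
  best_fine <- NA_real_
  for (T1 in seq(lo, hi, by = fine)) {
    e <- score_one(T1)
    if (e < best_err) { best_err <- e; best_fine <- T1 }
  }
  best_fine
}

# profile least squares for signed recovery S = A - (A B) exp(-t/tau):
# linear in (A, A*B) given tau, so a dense tau grid gives the global
# least-squares tau to grid resolution
oracle_profile_t1_signed <- function(values, times, tau_grid) {
  rss <- vapply(tau_grid, function(tau) {
    X <- cbind(1, -exp(-times / tau))
    fit <- lm.fit(X, values)
    sum(fit$residuals^2)
  }, numeric(1))
  tau_grid[which.min(rss)]
}

# truncation-enumeration oracle for the weighted log-linear T2 start:
# weighted lm() per truncation level, candidates scored by sum of absolute
# error of the back-transformed curve over all points
oracle_loglinear_t2 <- function(values, times) {
  keep <- values > 0
  S <- values[keep]; t <- times[keep]
  n <- length(S)
  best <- list(score = Inf, t2 = NA_real_)
  for (k in n:3) {
    df <- data.frame(t = t[1:k], y = log(S[1:k]))
    fit <- lm(y ~ t, data = df, weights = S[1:k]^2)
    slope <- coef(fit)[["t"]]
    if (slope >= 0) next
    t2 <- -1 / slope
    A <- exp(coef(fit)[["(Intercept)"]])
    score <- sum(abs(A * exp(-t / t2) - S))
    if (score < best$score) best <- list(score = score, t2 = t2)
  }
  best$t2
}

# build a noiseless (or Gaussian-noisy) pixel series for a model on its
# preset schedule; handles the SR anchor frame and MOLLI apparent T1*
make_pixel <- function(model_id, variant, A = 100, B = NULL, tau = 900,
                       sigma = 0, sched = NULL) {
  m <- signal_model(model_id, variant)
  if (is.null(sched)) {
    sched <- timing_schedule(switch(model_id,
      ir_se_mag = "ir_se", psir = "psir", sr_bssfp = "sr_bssfp",
      molli_mag = "molli", molli_psir = "molli",
      se_t2 = "se_t2_multi", t2prep_bssfp = "t2prep"))
  }
  if (is.null(B)) {
    B <- if (m$family == "t2") {
      if (variant == "3p") 5 else 0
    } else if (m$needs_look_locker) 1.8 else m$ideal_B
  }
  tau_sim <- if (m$needs_look_locker) tau / (B - 1) else tau
  anchor_index <- if (m$supports_anchor) sched$anchor_index else NULL
  tt <- sched$times
  if (!is.null(sched$anchor_index) && is.null(anchor_index)) {
    tt <- tt[-sched$anchor_index]
  }
  is_anchor <- if (is.null(anchor_index)) rep(FALSE, length(tt)) else
    seq_along(tt) == anchor_index
  vals <- predict_signal(m, list(A = A, B = B, tau = tau_sim),
                         ifelse(is.na(tt), 0, tt), anchor = is_anchor)
  if (sigma > 0) vals <- vals + rnorm(length(vals), sd = sigma)
  list(model = m,
       pixel = pixel_series(vals, tt, m$signal_convention,
                            anchor_index = anchor_index),
       truth = list(A = A, B = B, tau = tau, tau_sim = tau_sim))
}

# the twelve supported model/variant combinations
all_variants <- function() {
  list(
    list(id = "ir_se_mag", variant = "3p", B = 1.9),
    list(id = "ir_se_mag", variant = "2p", B = 2),
    list(id = "psir", variant = "3p", B = 1.9),
    list(id = "psir", variant = "2p", B = 2),
    list(id = "sr_bssfp", variant = "3p", B = 0.95),
    list(id = "sr_bssfp", variant = "2p", B = 1),
    list(id = "molli_mag", variant = "3p", B = 1.8),
    list(id = "molli_psir", variant = "3p", B = 1.8),
    list(id = "se_t2", variant = "3p", B = 5),
    list(id = "se_t2", variant = "2p", B = 0),
    list(id = "t2prep_bssfp", variant = "3p", B = 10),
    list(id = "t2prep_bssfp", variant = "2p", B = 0)
  )
}

# small 12-vial phantom that keeps test maps quick
small_phantom <- function(model, field = "1.5T", shape = c(48, 48),
                          sigma = 0, seed = 1L, B = NULL) {
  default_eurospin_specs(field, shape = shape, model = model,
                         B = B, noise_sigma = sigma, seed = seed)
}
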