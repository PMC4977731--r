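test_that("lookup initialization lands on the grid truth and within fine resolution", {
  m <- signal_model("ir_se_mag", "2p")
  sch <- timing_schedule("ir_se")$times
  # grid contains the truth -> exact hit
  px <- pixel_series(predict_signal(m, model_params(100, 2, 1000), sch), sch,
                     "magnitude")
  expect_equal(lookup_init_t1(px, m), 1000)
  # off-grid truth -> within the 5 ms fine-grid resolution
  px2 <- pixel_series(predict_signal(m, model_params(100, 2, 1023), sch), sch,
                      "magnitude")
  expect_lte(abs(lookup_init_t1(px2, m) - 1023), 5)
  # degenerate input
  pz <- pixel_series(rep(0, length(sch)), sch, "magnitude")
  expect_error(lookup_init_t1(pz, m), "no signal")
  expect_error(lookup_init_t1(px, signal_model("se_t2", "2p")), "T1 model")
})

test_that("lookup initialization equals the independently coded grid search", {
  set.seed(401)
  t1_models <- list(c("ir_se_mag", "2p"), c("psir", "3p"), c("sr_bssfp", "3p"),
                    c("molli_mag", "3p"))
  for (mm in t1_models) {
    m <- signal_model(mm[1], mm[2])
    sch <- timing_schedule(switch(mm[1], ir_se_mag = "ir_se", psir = "psir",
                                  sr_bssfp = "sr_bssfp", "molli"))$times
    for (rep in 1:10) {
      tau <- runif(1, 60, 2500)
      B <- m$ideal_B * runif(1, 0.85, 1.1)
      vals <- predict_signal(m, list(A = runif(1, 10, 500), B = B, tau = tau),
                             sch)
      px <- pixel_series(vals, sch, m$signal_convention)
      expect_equal(lookup_init_t1(px, m),
                   oracle_lookup_t1(vals, sch, m$ideal_B, m$code == 1L),
                   label = paste(mm[1], mm[2], "rep", rep))
    }
  }
})

test_that("log-linear T2 initialization is exact on clean decays and matches the truncation oracle", {
  te <- timing_schedule("se_t2_multi")$times
  # noiseless mono-exponential: weighted log-linear algebra is exact
  px <- pixel_series(100 * exp(-te / 80), te, "magnitude")
  expect_equal(loglinear_init_t2(px), 80, tolerance = 1e-9)
  # additive offset: candidate choice must match brute-force enumeration
  set.seed(402)
  for (rep in 1:8) {
    t2 <- runif(1, 40, 250)
    B <- runif(1, 2, 15)
    vals <- 100 * exp(-te / t2) + B + rnorm(length(te), sd = 0.5)
    vals <- pmax(vals, 1e-6)
    pxo <- pixel_series(vals, te, "magnitude")
    expect_equal(loglinear_init_t2(pxo), oracle_loglinear_t2(vals, te),
                 tolerance = 1e-9, label = paste("offset rep", rep))
  }
  # exactly three samples: a single candidate, returned directly
  t3 <- te[1:3]
  px3 <- pixel_series(100 * exp(-t3 / 55), t3, "magnitude")
  expect_equal(loglinear_init_t2(px3), 55, tolerance = 1e-9)
  # too few positive samples -> initialization failure, not an error
  pxn <- pixel_series(c(5, -1, -2, -3), te[1:4], "magnitude")
  expect_true(is.na(loglinear_init_t2(pxn)))
})

test_that("noiseless refinement recovers every model variant to sub-ms accuracy", {
  for (mv in all_variants()) {
    mp <- make_pixel(mv$id, mv$variant, A = 100, B = mv$B,
                     tau = if (signal_model(mv$id, mv$variant)$family == "t2")
                       137 else 1023)
    f <- fit_pixel(mp$pixel, mp$model)
    tau_hat <- if (mp$model$needs_look_locker) f$tau_corrected else f$tau
    expect_true(f$refined, label = paste(mv$id, mv$variant, "refined"))
    expect_lt(abs(tau_hat - mp$truth$tau), 1,
              label = paste(mv$id, mv$variant, "tau"))
    expect_lt(abs(f$A - mp$truth$A) / mp$truth$A * 100, 0.1,
              label = paste(mv$id, mv$variant, "A"))
  }
})

test_that("refined T1 agrees with an independent profile-likelihood grid search", {
  # for signed recovery the model is linear in (A, A B) given tau, so a
  # dense 0.1 ms profile grid is an independent least-squares oracle
  sch <- timing_schedule("sr_bssfp")$times
  m <- signal_model("sr_bssfp", "3p")
  vals <- predict_signal(m, model_params(100, 1, 950), sch)
  px <- pixel_series(vals, sch, m$signal_convention)
  f <- fit_pixel(px, m, keep_trace = TRUE)
  oracle <- oracle_profile_t1_signed(vals, sch, seq(940, 960, by = 0.1))
  expect_lt(abs(f$tau - oracle), 0.5)
  expect_lt(abs(f$tau - 950), 0.5)
})

test_that("MOLLI refinement recovers the Look-Locker corrected T1", {
  mp <- make_pixel("molli_mag", "3p", A = 100, B = 1.8, tau = 560)
  f <- fit_pixel(mp$pixel, mp$model)
  expect_lt(abs(f$tau_corrected - 560), 1)
  # identity by construction: tau_corrected = tau (B - 1)
  expect_equal(f$tau_corrected, f$tau * (f$B - 1), tolerance = 1e-12)
})

test_that("an already-optimal start stays put and the objective never increases", {
  m <- signal_model("psir", "3p")
  sch <- timing_schedule("psir")$times
  truth <- model_params(100, 1.9, 800)
  px <- pixel_series(predict_signal(m, truth, sch), sch, "signed")
  f <- refine_fit(px, m, truth, keep_trace = TRUE)
  expect_lt(abs(f$tau - 800), 0.5)
  expect_true(all(diff(f$trace) <= 1e-12))
  expect_true(f$monotone)
})

test_that("the exclusion rule zeroes T2 outside the open interval", {
  te <- timing_schedule("se_t2_multi")$times
  m <- signal_model("se_t2", "2p")
  for (t2 in c(350, 399)) {
    f <- fit_pixel(pixel_series(100 * exp(-te / t2), te, "magnitude"), m)
    expect_false(f$excluded, label = paste("T2", t2))
    expect_gt(f$map_value, 0)
  }
  for (t2 in c(400, 450)) {
    f <- fit_pixel(pixel_series(100 * exp(-te / t2), te, "magnitude"), m)
    expect_true(f$excluded, label = paste("T2", t2))
    expect_false(f$refined)
    expect_identical(f$map_value, 0)
  }
  # apply_exclusion is idempotent on a retained result
  f <- fit_pixel(pixel_series(100 * exp(-te / 120), te, "magnitude"), m)
  expect_equal(apply_exclusion(f, m)$map_value, f$map_value)
})

test_that("residuals match hand arithmetic and are scale invariant", {
  m <- signal_model("se_t2", "2p")
  # perfect fit -> 0 %
  te <- timing_schedule("se_t2_multi")$times
  px <- pixel_series(100 * exp(-te / 90), te, "magnitude")
  expect_equal(compute_residual(px, list(A = 100, B = 0, tau = 90), m), 0,
               tolerance = 1e-12)
  # two-sample worked example: S = [100, 50], fit = [90, 60] -> 10 %
  t2 <- 100
  tt <- c(0, t2 * log(90 / 60))
  S <- c(100, 50)
  pxh <- pixel_series(S, tt, "magnitude")
  expect_equal(compute_residual(pxh, list(A = 90, B = 0, tau = t2), m), 10,
               tolerance = 1e-9)
  # scaling signal and fit by any c > 0 leaves the residual unchanged
  set.seed(403)
  for (cc in c(0.02, 3, 250)) {
    pxs <- pixel_series(cc * S, tt, "magnitude")
    expect_equal(compute_residual(pxs, list(A = cc * 90, B = 0, tau = t2), m),
                 10, tolerance = 1e-9, label = paste("scale", cc))
  }
  expect_warning(r <- compute_residual(pixel_series(c(0, 0), c(1, 2),
                                                    "magnitude"),
                                       list(A = 1, B = 0, tau = 50), m),
                 "all-zero")
  expect_true(is.na(r))
})

test_that("the median T1 estimate at SNR 50 is unbiased within the grid bound", {
  set.seed(404)
  m <- signal_model("psir", "3p")
  sch <- timing_schedule("psir")$times
  clean <- predict_signal(m, model_params(100, 2, 1000), sch)
  errs <- replicate(500, {
    px <- pixel_series(clean + rnorm(length(sch), sd = 2), sch, "signed")
    fit_pixel(px, m)$tau - 1000
  })
  se_median <- 1.2533 * sd(errs) / sqrt(length(errs))
  expect_lt(abs(median(errs)), 2.5 + 3 * se_median)
})

test_that("pixel series validation rejects malformed input", {
  expect_error(pixel_series(1:3, 1:2, "magnitude"), "equal length")
  expect_error(pixel_series(c(1, 2, 3), c(10, 10, 20), "magnitude"),
               "duplicate")
  expect_error(pixel_series(c(1, 2), c(-5, 10), "magnitude"), "non-negative")
  # signed data cannot enter a magnitude model
  px <- pixel_series(c(-5, 10), c(5, 10), "signed")
  expect_error(fit_pixel(px, signal_model("ir_se_mag", "3p")),
               "signed data")
})
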