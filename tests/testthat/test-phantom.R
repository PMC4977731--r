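test_that("zero-noise simulation is the exact model prediction and is deterministic", {
  spec <- small_phantom(signal_model("ir_se_mag", "3p"))
  sim <- simulate_series(spec)
  v <- spec$vials[3, ]
  ij <- which(sim$truth$vial_masks[[3]], arr.ind = TRUE)[1, ]
  expect_equal(sim$series$frames[ij[1], ij[2], ],
               predict_signal(spec$model, list(A = v$A, B = v$B, tau = v$T1),
                              sim$series$times),
               tolerance = 1e-12)
  # same seed, same arrays; noise path deterministic too
  specn <- small_phantom(signal_model("ir_se_mag", "3p"), sigma = 2, seed = 5)
  expect_identical(simulate_series(specn)$series$frames,
                   simulate_series(specn)$series$frames)
})

test_that("magnitude noise is Rician: background modulus mean is sigma sqrt(pi/2)", {
  sigma <- 3
  spec <- phantom_spec(
    tibble::tibble(vial = 1, cx = 3, cy = 3, radius = 1.2, T1 = 800, T2 = 80,
                   A = 100),
    shape = c(104, 104), model = signal_model("ir_se_mag", "3p"),
    noise_sigma = sigma, seed = 31
  )
  sim <- simulate_series(spec)
  bg <- sim$truth$A == 0
  expect_gt(sum(bg), 1e4)
  vals <- sim$series$frames[, , 1][bg]
  # Rayleigh mean sigma*sqrt(pi/2), SD sigma*sqrt(2 - pi/2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - sigma * sqrt(pi / 2)), 3 * se)
})

test_that("noise realizations under different seeds are independent", {
  mk <- function(seed) {
    spec <- phantom_spec(
      tibble::tibble(vial = 1, cx = 3, cy = 3, radius = 1.2, T1 = 800,
                     T2 = 80, A = 100),
      shape = c(104, 104), model = signal_model("psir", "3p"),
      noise_sigma = 2, seed = seed)
    sim <- simulate_series(spec)
    sim$series$frames[, , 1][sim$truth$A == 0]   # background only
  }
  a <- mk(1); b <- mk(2)
  expect_gt(length(a), 1e4)
  expect_lt(abs(cor(a, b)), 0.05)
})

test_that("gel-phantom presets span the printed reference ranges with 12 vials", {
  s15 <- default_eurospin_specs("1.5T")
  expect_equal(nrow(s15$vials), 12)
  expect_equal(min(s15$vials$T1), 214)
  expect_equal(max(s15$vials$T1), 1643)
  expect_equal(range(s15$vials$T2), c(46, 338))
  s3 <- default_eurospin_specs("3T")
  expect_equal(nrow(s3$vials), 12)
  expect_equal(range(s3$vials$T1), c(229, 1752))
  expect_equal(range(s3$vials$T2), c(45, 316))
  # vials must not overlap
  expect_error(phantom_spec(tibble::tibble(
    vial = 1:2, cx = c(10, 12), cy = c(10, 10), radius = 5, T1 = 500,
    T2 = 50, A = 100), model = "se_t2"), "overlap")
})

test_that("MOLLI schedules merge inversion epochs at the heart rate", {
  # 5(3b)3 at 60 bpm: two epochs, 8 samples, the documented delay list
  expect_equal(molli_schedule("5(3b)3", 60),
               c(130, 210, 1130, 1210, 2130, 2210, 3130, 4130))
  # 4(1b)3(1b)2 at 60 bpm: three epochs, 9 samples
  s2 <- molli_schedule("4(1b)3(1b)2", 60)
  expect_length(s2, 9)
  expect_equal(s2[1:3], c(130, 210, 290))
  # heart rate scales the intra-epoch spacing
  s_fast <- molli_schedule("5(3b)3", 120)
  expect_equal(sort(unique(round(diff(sort(s_fast[c(1, 3, 5, 7, 8)]))))),
               500)
  expect_error(molli_schedule("9(9b)9"), "arg")
  expect_error(molli_schedule("5(3b)3", heart_rate_bpm = 0), "positive")
})

test_that("MOLLI simulation encodes T1* so the corrected truth is the vial T1", {
  spec <- small_phantom(signal_model("molli_mag", "3p"), B = 2)
  sim <- simulate_molli_series(spec, "5(3b)3", 60)
  # B = 2: T1* equals T1 and the correction is the identity
  v <- spec$vials[1, ]
  ij <- which(sim$truth$vial_masks[[1]], arr.ind = TRUE)[1, ]
  expect_equal(sim$series$frames[ij[1], ij[2], ],
               abs(v$A * (1 - 2 * exp(-sim$series$times / v$T1))),
               tolerance = 1e-12)
  expect_error(simulate_molli_series(small_phantom(signal_model("se_t2", "2p"))),
               "MOLLI model")
})

test_that("degenerate phantom specs are rejected", {
  vial <- tibble::tibble(vial = 1, cx = 5, cy = 5, radius = 2, T1 = 500,
                         T2 = 50, A = 100)
  expect_error(phantom_spec(vial, model = "se_t2", times = numeric(0)),
               "empty")
  expect_error(phantom_spec(vial[, 1:3], model = "se_t2"), "columns")
})
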