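test_that("map fitting recovers vial truth and masks background", {
  spec <- small_phantom(signal_model("sr_bssfp", "3p"))
  sim <- simulate_series(spec)
  map <- fit_map(sim$series, spec$model)
  fg <- Reduce(`|`, sim$truth$vial_masks)
  expect_true(all(map$refined_mask[fg]))
  expect_true(all(map$tau_map[!fg] == 0))
  expect_lt(max(abs(map$tau_map[fg] - sim$truth$T1[fg])), 1)
  # residuals defined only where refined, and ~0 on noiseless data
  expect_true(all(is.na(map$residual_map[!map$refined_mask])))
  expect_lt(max(map$residual_map[fg]), 0.01)
})

test_that("an ROI restricts the fit and preserves pixel independence", {
  spec <- small_phantom(signal_model("ir_se_mag", "3p"))
  sim <- simulate_series(spec)
  one_vial <- roi_mask(sim$truth$vial_masks[[5]])
  map_roi <- fit_map(sim$series, spec$model, roi = one_vial)
  expect_true(all(map_roi$tau_map[!one_vial$mask] == 0))
  expect_true(any(map_roi$tau_map[one_vial$mask] > 0))
  # pixel independence: the ROI map equals the full map on the ROI pixels
  map_full <- fit_map(sim$series, spec$model)
  expect_equal(map_roi$tau_map[one_vial$mask], map_full$tau_map[one_vial$mask])
  expect_error(fit_map(sim$series, spec$model,
                       roi = roi_mask(matrix(TRUE, 2, 2))),
               "shape")
})

test_that("maps are invariant to consistent frame reordering", {
  spec <- small_phantom(signal_model("se_t2", "2p"), sigma = 1, seed = 9)
  sim <- simulate_series(spec)
  perm <- sample(seq_along(sim$series$times))
  shuffled <- image_series(sim$series$frames[, , perm],
                           sim$series$times[perm], sim$series$convention)
  m <- signal_model("se_t2", "2p")
  expect_equal(fit_map(shuffled, m)$tau_map, fit_map(sim$series, m)$tau_map)
})

test_that("a uniform zero stack yields an all-zero, unrefined map", {
  z <- image_series(array(0, dim = c(8, 8, 6)),
                    c(10, 30, 60, 120, 240, 480), "magnitude")
  map <- fit_map(z, signal_model("se_t2", "2p"))
  expect_true(all(map$tau_map == 0))
  expect_true(all(!map$refined_mask))
})

test_that("ROI-mean fitting matches single pixels on homogeneous data and beats them under noise", {
  spec <- small_phantom(signal_model("sr_bssfp", "3p"))
  sim <- simulate_series(spec)
  vial <- sim$truth$vial_masks[[8]]
  m <- spec$model
  roi <- roi_mask(vial)
  roi_fit <- fit_roi_mean(sim$series, m, roi = roi)
  ij <- which(vial, arr.ind = TRUE)[1, ]
  px_fit <- fit_pixel(pixel_series(sim$series$frames[ij[1], ij[2], ],
                                   sim$series$times, "signed"), m)
  # homogeneous noiseless vial: averaging changes nothing
  expect_lt(abs(roi_fit$tau - px_fit$tau), 0.5)
  # a one-pixel ROI is the pixel fit
  single <- matrix(FALSE, nrow(vial), ncol(vial))
  single[ij[1], ij[2]] <- TRUE
  roi1 <- fit_roi_mean(sim$series, m, roi = roi_mask(single))
  expect_equal(roi1$tau, px_fit$tau, tolerance = 1e-9)
  expect_error(fit_roi_mean(sim$series, m,
                            roi = roi_mask(matrix(FALSE, nrow(vial),
                                                  ncol(vial)))),
               "empty")

  # variance reduction: ROI mean is closer to truth than the median pixel
  specn <- small_phantom(signal_model("sr_bssfp", "3p"), shape = c(40, 40),
                         sigma = 2, seed = 77)
  specn$vials <- specn$vials[6, ]
  specn$vials$cx <- 20; specn$vials$cy <- 20; specn$vials$radius <- 9
  simn <- simulate_series(specn)
  vialn <- simn$truth$vial_masks[[1]]
  truth <- specn$vials$T1[1]
  mapn <- fit_map(simn$series, specn$model, roi = roi_mask(vialn))
  median_px_err <- median(abs(mapn$tau_map[vialn & mapn$refined_mask] - truth))
  roi_err <- abs(fit_roi_mean(simn$series, specn$model,
                              roi = roi_mask(vialn))$tau - truth)
  expect_lt(roi_err, median_px_err)
})

test_that("the residual map recomputation matches the stored map and exposes model mismatch", {
  spec <- small_phantom(signal_model("se_t2", "3p"))
  sim <- simulate_series(spec)
  m <- spec$model
  map <- fit_map(sim$series, m)
  rm2 <- residual_map(sim$series, map, m)
  sel <- map$refined_mask
  expect_equal(rm2[sel], map$residual_map[sel], tolerance = 1e-8)
  # offset data fitted with the 2-parameter model leaves a larger residual
  te <- timing_schedule("se_t2_multi")$times
  vals <- 100 * exp(-te / 120) + 12
  px <- pixel_series(vals, te, "magnitude")
  r2 <- fit_pixel(px, signal_model("se_t2", "2p"))$residual_pct
  r3 <- fit_pixel(px, signal_model("se_t2", "3p"))$residual_pct
  expect_gt(r2, r3)
})

test_that("convention and anchor handling in series construction", {
  expect_error(image_series(array(0, c(4, 4, 3)), c(1, 2), "magnitude"),
               "frame count")
  expect_error(image_series(array(0, c(4, 4, 3)), c(1, 2, 2), "magnitude"),
               "duplicate")
  spec <- small_phantom(signal_model("psir", "3p"))
  sim <- simulate_series(spec)
  expect_error(fit_map(sim$series, signal_model("ir_se_mag", "3p")),
               "signed data")
  # frames arrive sorted by preparation time, anchor last
  s <- image_series(array(1, c(2, 2, 3)), c(50, NA, 10), "magnitude",
                    anchor_index = 2L)
  expect_equal(s$times[1:2], c(10, 50))
  expect_equal(s$anchor_index, 3L)
})
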