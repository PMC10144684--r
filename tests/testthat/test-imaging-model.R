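test_that("diffusion forward model evaluates the monoexponential decay", {
  expect_equal(predict_diffusion_signal(1000, 0, c(0, 150, 700)),
               c(1000, 1000, 1000))
  expect_equal(predict_diffusion_signal(1000, 1e-3, 0), 1000)
  expect_equal(predict_diffusion_signal(1000, 1e-3, 700), 1000 * exp(-0.7))
  expect_error(predict_diffusion_signal(0, 1e-3, 0), "s0")
  expect_error(predict_diffusion_signal(1000, -1e-3, 0), "adc")
})

test_that("series constructors enforce axis and spacing invariants", {
  arr <- array(1, dim = c(2, 2, 1, 3))
  expect_error(diffusion_series(arr, c(0, 150)), "4th")
  expect_error(diffusion_series(arr, c(0, 150, 150)), "increasing")
  expect_error(diffusion_series(arr, c(-5, 0, 150)), "nonnegative")
  expect_error(diffusion_series(arr, c(0, 150, 700), c(1, 0, 1)),
               "voxel_spacing")
  expect_error(dynamic_series(arr, c(0, 10, 5)), "increasing")
})

test_that("noiseless ADC fits reproduce the generating slope on both b-sets", {
  b_sets <- list(preclinical = c(0, 150, 700),
                 clinical = c(0, 100, 600, 800))
  adc_grid <- c(0, 1e-4, 5e-4, 1e-3, 2e-3, 3e-3)
  for (b in b_sets) {
    for (adc in adc_grid) {
      sig <- if (adc == 0) rep(1000, length(b))
             else predict_diffusion_signal(1000, adc, b)
      fit <- fit_adc_map(voxel_dwi(sig, b))$values[1, 1, 1]
      if (adc == 0) expect_equal(fit, 0, tolerance = 1e-12)
      else expect_lt(abs(fit - adc) / adc, 1e-9)
    }
  }
})

test_that("voxels with nonpositive signal or outside the mask are NaN", {
  b <- c(0, 150, 700)
  arr <- array(1000, dim = c(2, 1, 1, 3))
  arr[1, 1, 1, 2] <- 0
  fit <- fit_adc_map(diffusion_series(arr, b))
  expect_true(is.nan(fit$values[1, 1, 1]))
  expect_false(is.nan(fit$values[2, 1, 1]))

  mask <- mask_at(c(2, 1, 1), cbind(2, 1, 1))
  fit2 <- fit_adc_map(diffusion_series(array(1000, c(2, 1, 1, 3)), b), mask)
  expect_true(is.nan(fit2$values[1, 1, 1]))
  expect_equal(fit2$values[2, 1, 1], 0, tolerance = 1e-12)
  expect_equal(fit2$voxel_spacing, c(1, 1, 1))
})

test_that("ADC fitting rejects degenerate inputs", {
  arr <- array(1000, dim = c(1, 1, 1, 2))
  expect_error(fit_adc_map(diffusion_series(arr, c(0, 100))[c(1, 2)]),
               class = "error")  # not a series object
  one_b <- structure(list(voxels = array(1000, c(1, 1, 1, 1)),
                          b_values = 0, voxel_spacing = c(1, 1, 1)),
                     class = "diffusion_series")
  expect_error(fit_adc_map(one_b), "2 distinct")
  bad_mask <- mask_at(c(2, 2, 2), cbind(1, 1, 1))
  expect_error(fit_adc_map(diffusion_series(arr, c(0, 100)), bad_mask),
               "shape")
})

test_that("noisy ADC recovery at SNR 50 keeps median relative error under 5%", {
  set.seed(42)
  b <- c(0, 150, 700)
  n <- 600L
  s0 <- 1000
  true_adc <- runif(n, 0.5e-3, 2.5e-3)
  sig <- vapply(true_adc, function(a) predict_diffusion_signal(s0, a, b),
                numeric(length(b)))
  sig <- sig + rnorm(length(sig), 0, s0 / 50)
  sig[sig <= 0] <- 1e-6
  arr <- array(t(sig), dim = c(n, 1, 1, length(b)))
  fit <- fit_adc_map(diffusion_series(arr, b))
  rel <- abs(fit$values[, 1, 1] - true_adc) / true_adc
  expect_lt(median(rel, na.rm = TRUE), 0.05)
})

test_that("SER reproduces the hand-worked enhancement ratio", {
  # 10 baseline frames at 100, ramp to a 300 peak, 200 at ~6 min post peak
  tms <- seq(0, by = 30, length.out = 26)
  curve <- c(rep(100, 10), 200, 300, 300 - (1:14) * (100 / 12))
  # frame nearest peak(t=330)+360 = 690 is frame 24 -> value 300 - 12*100/12 = 200
  ser <- compute_ser_map(voxel_dce(curve, tms))$values[1, 1, 1]
  expect_equal(ser, (300 - 100) / (200 - 100), tolerance = 1e-12)
})

test_that("SER handles plateau and non-enhancing voxels", {
  tms <- seq(0, by = 30, length.out = 26)
  plateau <- c(rep(100, 10), rep(300, 16))
  expect_equal(compute_ser_map(voxel_dce(plateau, tms))$values[1, 1, 1], 1)
  flat <- rep(100, 26)
  expect_true(is.nan(compute_ser_map(voxel_dce(flat, tms))$values[1, 1, 1]))
})

test_that("SER is invariant under affine rescaling of the series", {
  tr <- phantom_truth(center = c(6, 6, 6), semiaxes = c(3, 2, 2), ser = 2.5)
  ph <- make_dce_phantom(tr, grid = c(12L, 12L, 12L))
  base <- compute_ser_map(ph$series, ph$mask)$values
  scaled <- dynamic_series(7.3 * ph$series$voxels + 55,
                           ph$series$frame_times, ph$series$voxel_spacing)
  again <- compute_ser_map(scaled, ph$mask)$values
  expect_equal(again, base, tolerance = 1e-9)
})

test_that("SER peak search starts after the baseline window and ties go early", {
  tms <- seq(0, by = 30, length.out = 26)
  # baseline contains a spurious high frame that must not be the peak
  curve <- c(rep(100, 9), 500, 200, 300, rep(200, 14))
  map <- compute_ser_map(voxel_dce(curve, tms))
  s_base <- mean(curve[1:10])
  expect_equal(map$values[1, 1, 1], (300 - s_base) / (200 - s_base),
               tolerance = 1e-12)
})

test_that("late frames beyond the acquisition clamp to the end and are flagged", {
  tms <- seq(0, by = 30, length.out = 13)      # ends 360 s
  curve <- c(rep(100, 10), 200, 300, 250)      # peak at t=330; +360 beyond end
  map <- compute_ser_map(voxel_dce(curve, tms))
  expect_equal(map$values[1, 1, 1], (300 - 100) / (250 - 100),
               tolerance = 1e-12)
  expect_true(attr(map, "clamped")[1, 1, 1])
})

test_that("SER input contracts reject short series and bad offsets", {
  tms <- seq(0, by = 30, length.out = 10)
  arr <- voxel_dce(rep(100, 10), tms)
  expect_error(compute_ser_map(arr), "frames")
  tms2 <- seq(0, by = 30, length.out = 26)
  arr2 <- voxel_dce(rep(100, 26), tms2)
  expect_error(compute_ser_map(arr2, late_offset = 0), "late_offset")
})

test_that("ROI-level peak definition is available and consistent on uniform lesions", {
  tr <- phantom_truth(center = c(6, 6, 6), semiaxes = c(3, 2, 2), ser = 2)
  ph <- make_dce_phantom(tr, grid = c(12L, 12L, 12L))
  vox <- compute_ser_map(ph$series, ph$mask, peak = "voxel")$values
  roi <- compute_ser_map(ph$series, ph$mask, peak = "roi")$values
  expect_equal(roi[ph$mask$mask], vox[ph$mask$mask], tolerance = 1e-12)
})
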