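test_that("noiseless diffusion phantoms are inverted exactly by the fitter", {
  tr <- phantom_truth(center = c(8, 8, 8), semiaxes = c(4, 3, 3),
                      adc = 1.3e-3)
  ph <- make_dwi_phantom(tr, grid = c(16L, 16L, 16L))
  fit <- fit_adc_map(ph$series, ph$mask)
  inside <- fit$values[ph$mask$mask]
  expect_lt(max(abs(inside - tr$adc)) / tr$adc, 1e-9)
  expect_true(all(is.nan(fit$values[!ph$mask$mask])))
  # background decays with its own ADC
  fit_all <- fit_adc_map(ph$series)
  expect_lt(max(abs(fit_all$values[!ph$mask$mask] - tr$adc_background)) /
              tr$adc_background, 1e-9)
})

test_that("phantoms are deterministic in their seed", {
  tr <- phantom_truth(center = c(8, 8, 8), semiaxes = c(4, 3, 3))
  a <- make_dwi_phantom(tr, grid = c(16L, 16L, 16L), noise_sigma = 15,
                        seed = 7)
  b <- make_dwi_phantom(tr, grid = c(16L, 16L, 16L), noise_sigma = 15,
                        seed = 7)
  expect_identical(a$series$voxels, b$series$voxels)
  c <- make_dwi_phantom(tr, grid = c(16L, 16L, 16L), noise_sigma = 15,
                        seed = 8)
  expect_false(identical(a$series$voxels, c$series$voxels))
})

test_that("phantom masks digitize the truth ellipsoid to 2% volume accuracy", {
  tr <- phantom_truth(center = c(8, 6, 6), semiaxes = c(6, 4, 4))
  ph <- make_dwi_phantom(tr, grid = c(64L, 48L, 48L),
                         spacing = rep(0.25, 3))
  vol <- tumor_volume(ph$mask)
  analytic <- 4 / 3 * pi * prod(tr$semiaxes)
  expect_lt(abs(vol - analytic) / analytic, 0.02)
  expect_error(make_dwi_phantom(tr, grid = c(10L, 10L, 10L)),
               "exceeds the phantom grid")
})

test_that("DCE phantoms invert the enhancement-ratio construction", {
  for (ser in c(1.0, 1.5, 2.0, 3.0)) {
    tr <- phantom_truth(center = c(6, 6, 6), semiaxes = c(3, 2, 2),
                        ser = ser)
    ph <- make_dce_phantom(tr, grid = c(12L, 12L, 12L))
    map <- compute_ser_map(ph$series, ph$mask)
    vals <- map$values[ph$mask$mask]
    expect_lt(max(abs(vals - ser)) / ser, 1e-9)
  }
  # background never enhances
  tr <- phantom_truth(center = c(6, 6, 6), semiaxes = c(3, 2, 2), ser = 2)
  ph <- make_dce_phantom(tr, grid = c(12L, 12L, 12L))
  full <- compute_ser_map(ph$series)
  expect_true(all(is.nan(full$values[!ph$mask$mask])))
  expect_error(make_dce_phantom(tr, frame_times = seq(0, by = 20,
                                                      length.out = 14)),
               "too short")
  expect_error(phantom_truth(center = c(6, 6, 6), semiaxes = c(3, 2, 2),
                             ser = 0.8), ">= 1")
})

test_that("cohorts list every study and respect the responder contract", {
  cohort <- make_cohort(n_patients = 4L, n_pdx = 2L, imaging = "none",
                        seed = 12)
  expect_equal(nrow(cohort$manifest), 2L * (4L + 2L))
  expect_equal(sum(cohort$manifest$cohort == "patient"), 8L)

  all_resp <- make_cohort(n_patients = 4L, n_pdx = 2L,
                          responder_fraction = 1, imaging = "none",
                          seed = 13)
  rr <- with(all_resp$subjects,
             100 * (volume_t1 - volume_t0) / volume_t0)
  expect_true(all(rr < 0))
  expect_equal(rr, 100 * all_resp$subjects$volume_change, tolerance = 1e-9)

  again <- make_cohort(n_patients = 4L, n_pdx = 2L, imaging = "none",
                       seed = 12)
  expect_identical(cohort$subjects, again$subjects)
  expect_identical(unclass(cohort$expression$patient),
                   unclass(again$expression$patient))
})

test_that("extracted phantom features round-trip to the truth manifest", {
  cohort <- make_cohort(n_patients = 2L, n_pdx = 1L, imaging = "full",
                        seed = 3)
  feats <- coclin:::cohort_features(cohort)
  subj <- cohort$subjects
  for (i in seq_len(nrow(subj))) {
    f0 <- feats[feats$subject_id == subj$subject_id[i] &
                  feats$timepoint == "T0", ]
    expect_lt(abs(f0$adc_median - subj$adc_t0[i]) / subj$adc_t0[i], 1e-9)
    expect_lt(abs(f0$ser_median - subj$ser_t0[i]) / subj$ser_t0[i], 1e-9)
    expect_lt(abs(f0$volume - subj$volume_t0[i]) / subj$volume_t0[i], 0.06)
    # digitization (one in-plane voxel diagonal) plus the off-centre
    # axial-slice shrink of an ellipsoid sampled at voxel centres
    sp <- if (subj$cohort[i] == "PDX") c(0.45, 0.9) else c(1.25, 2.5)
    shrink <- 1 - sqrt(1 - (sp[2] / 2 / subj$a0_z[i])^2)
    expect_lt(abs(f0$longest_diameter - 2 * subj$a0_x[i]),
              sqrt(2) * sp[1] + shrink * 2 * subj$a0_x[i])
  }
})

test_that("planted association signal is recoverable from the cohort", {
  cohort <- make_cohort(seed = 41, imaging = "none")
  rr <- stats::setNames(100 * cohort$subjects$volume_change,
                        cohort$subjects$subject_id)
  res <- spearman_associate(cohort$expression$patient,
                            rr[cohort$subjects$cohort == "patient"])
  pl <- cohort$planted_genes
  expect_true(all(pl$gene[pl$sign > 0] %in% res$top_list))
  expect_true(all(pl$gene[pl$sign < 0] %in% res$bottom_list))
})
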