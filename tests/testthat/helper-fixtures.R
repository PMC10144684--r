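# Shared fixture builders; everything is generated in code.

# Single-voxel diffusion series with the given per-b signals.
voxel_dwi <- function(signals, b_values, spacing = c(1, 1, 1)) {
  diffusion_series(array(signals, dim = c(1, 1, 1, length(b_values))),
                   b_values, spacing)
}

# Single-voxel dynamic series from a frame-value vector.
voxel_dce <- function(curve, frame_times, spacing = c(1, 1, 1)) {
  dynamic_series(array(curve, dim = c(1, 1, 1, length(curve))),
                 frame_times, spacing)
}

# Mask with foreground at the given (x, y, z) index rows.
mask_at <- function(dim3, idx, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dim = dim3)
  m[as.matrix(idx)] <- TRUE
  roi_mask(m, spacing)
}

# Digitised sphere mask.
sphere_mask <- function(radius_mm, voxel_mm) {
  n <- ceiling(2 * radius_mm / voxel_mm) + 4L
  grid <- c(n, n, n)
  center <- grid * voxel_mm / 2
  ax <- (seq_len(n) - 0.5) * voxel_mm
  d2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, `+`),
              (ax - center[3])^2, `+`)
  roi_mask(d2 <= radius_mm^2, rep(voxel_mm, 3))
}

# Small expression matrix with distinct positive values.
tiny_expr <- function(n_genes = 20L, n_samples = 6L, seed = 1L,
                      cohort = "patient") {
  set.seed(seed)
  expression_matrix(
    matrix(stats::rlnorm(n_genes * n_samples, 4, 1.5),
           nrow = n_genes,
           dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n_samples)))),
    cohort = cohort)
}

# Brute-force in-plane longest diameter (all-pairs, per slice).
brute_diameter <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  sp <- mask$voxel_spacing
  best <- 0
  for (z in unique(idx[, 3])) {
    pts <- idx[idx[, 3] == z, 1:2, drop = FALSE]
    if (nrow(pts) < 2) next
    for (i in seq_len(nrow(pts) - 1)) {
      dx <- (pts[i, 1] - pts[-(1:i), 1]) * sp[1]
      dy <- (pts[i, 2] - pts[-(1:i), 2]) * sp[2]
      best <- max(best, sqrt(max(dx^2 + dy^2)))
    }
  }
  best
}

# Minimal complete feature table for response-table tests.
feature_rows <- function(subjects, timepoints, volumes,
                         cohort = "patient") {
  n <- length(subjects)
  tibble::tibble(
    subject_id = subjects, cohort = cohort,
    lesion_label = paste0(subjects, " lesion"), timepoint = timepoints,
    longest_diameter = volumes / 10, volume = volumes,
    adc_mean = 1e-3, adc_median = 1e-3, ser_mean = 2, ser_median = 2,
    modality = "MRI", study_date = ifelse(timepoints == "T0",
                                          "2026-01-05", "2026-02-02"))
}
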