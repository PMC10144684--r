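#' Ground truth record for one digital phantom
#'
#' Captures everything needed to generate a subject's synthetic imaging and
#' to recompute its expected features analytically: the ellipsoidal lesion
#' geometry, the true ADC inside and outside the lesion, the true SER and
#' the enhancement curve levels.
#'
#' @param center Ellipsoid centre in mm (length 3).
#' @param semiaxes Ellipsoid semi-axes in mm (length 3, all > 0).
#' @param adc True lesion ADC, mm^2/s.
#' @param ser True lesion SER (>= 1: enhancement followed by washout or
#'   plateau; persistent-enhancement curves with SER < 1 are not modelled).
#' @param s0 Diffusion signal at b = 0.
#' @param adc_background Background ADC, mm^2/s (distinct from the lesion).
#' @param dce_baseline,dce_peak Baseline and peak levels of the dynamic
#'   enhancement curve inside the lesion.
#' @return A list of class `phantom_truth`.
#' @export
phantom_truth <- function(center, semiaxes, adc = 1.0e-3, ser = 2.0,
                          s0 = 1000, adc_background = 2.2e-3,
                          dce_baseline = 100, dce_peak = 300) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L,
            all(semiaxes > 0), adc >= 0, adc_background >= 0, s0 > 0,
            dce_peak > dce_baseline)
  if (ser < 1) stop("phantom SER must be >= 1", call. = FALSE)
  structure(
    list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
         adc = adc, ser = ser, s0 = s0, adc_background = adc_background,
         dce_baseline = dce_baseline, dce_peak = dce_peak),
    class = "phantom_truth"
  )
}

# Exact ellipsoid digitisation on voxel centres at (i - 0.5) * spacing.
digitize_ellipsoid <- function(grid, spacing, center, semiaxes) {
  ax <- (seq_len(grid[1]) - 0.5) * spacing[1]
  ay <- (seq_len(grid[2]) - 0.5) * spacing[2]
  az <- (seq_len(grid[3]) - 0.5) * spacing[3]
  qx <- ((ax - center[1]) / semiaxes[1])^2
  qy <- ((ay - center[2]) / semiaxes[2])^2
  qz <- ((az - center[3]) / semiaxes[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  q <= 1
}

check_ellipsoid_in_grid <- function(grid, spacing, center, semiaxes) {
  lo <- center - semiaxes
  hi <- center + semiaxes
  if (any(lo < 0) || any(hi > grid * spacing)) {
    stop("ellipsoid exceeds the phantom grid", call. = FALSE)
  }
}

#' Digital diffusion-weighted phantom
#'
#' Generates a multi-b-value series whose voxel signal follows the
#' monoexponential forward model of [predict_diffusion_signal()]: lesion
#' voxels decay with the truth ADC, background voxels with a distinct
#' background ADC, plus optional additive Gaussian noise. The returned mask
#' is the exact digitisation of the truth ellipsoid, so a noiseless
#' phantom is inverted exactly by [fit_adc_map()].
#'
#' @param truth A [phantom_truth()].
#' @param b_values Diffusion weightings, s/mm^2 (default the three-point
#'   preclinical set 0/150/700).
#' @param grid Integer length-3 grid size (voxels).
#' @param spacing Voxel size, mm.
#' @param noise_sigma Additive Gaussian noise SD in signal units.
#' @param seed Integer seed for the noise draw.
#' @return List with `series` ([diffusion_series()]) and `mask`
#'   ([roi_mask()]).
#' @export
make_dwi_phantom <- function(truth, b_values = c(0, 150, 700),
                             grid = c(32L, 32L, 16L), spacing = c(1, 1, 1),
                             noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  check_ellipsoid_in_grid(grid, spacing, truth$center, truth$semiaxes)
  inside <- digitize_ellipsoid(grid, spacing, truth$center, truth$semiaxes)
  nb <- length(b_values)
  adc_field <- ifelse(inside, truth$adc, truth$adc_background)
  arr <- array(0, dim = c(grid, nb))
  for (k in seq_len(nb)) {
    arr[, , , k] <- truth$s0 * exp(-adc_field * b_values[k])
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    arr <- arr + stats::rnorm(length(arr), 0, noise_sigma)
  }
  list(
    series = diffusion_series(arr, b_values, spacing),
    mask = roi_mask(inside, spacing, label = "phantom lesion")
  )
}

#' Digital dynamic contrast-enhanced phantom
#'
#' Lesion voxels follow a piecewise-linear enhancement curve: a flat
#' baseline over the first 10 frames, a linear rise to the peak, then a
#' monotone washout whose level at the frame nearest (peak time + 6 min)
#' is chosen so that the enhancement ratio
#' `(peak - baseline) / (late - baseline)` equals the truth SER exactly
#' (a plateau when SER = 1). Background voxels hold the baseline level and
#' are therefore `NaN` (non-enhancing) in the derived SER map.
#'
#' @param truth A [phantom_truth()].
#' @param frame_times Frame times in seconds; must extend past the phantom
#'   peak + `late_offset`. Defaults to 30 frames at 20 s spacing.
#' @param grid,spacing,noise_sigma,seed As in [make_dwi_phantom()].
#' @param n_baseline Baseline frame count the curve is built around.
#' @param late_offset Seconds from peak to the washout reading (360 = 6
#'   min).
#' @return List with `series` ([dynamic_series()]), `mask`
#'   ([roi_mask()]), and `peak_frame` (index of the peak).
#' @export
make_dce_phantom <- function(truth, frame_times = seq(0, by = 20,
                                                      length.out = 30),
                             grid = c(32L, 32L, 16L), spacing = c(1, 1, 1),
                             noise_sigma = 0, seed = 1L,
                             n_baseline = 10L, late_offset = 360) {
  stopifnot(inherits(truth, "phantom_truth"))
  check_ellipsoid_in_grid(grid, spacing, truth$center, truth$semiaxes)
  nt <- length(frame_times)
  if (nt < n_baseline + 2L) {
    stop("need at least n_baseline + 2 frames", call. = FALSE)
  }
  peak_frame <- n_baseline + 2L     # one rising frame between baseline and peak
  t_peak <- frame_times[peak_frame]
  if (frame_times[nt] < t_peak + late_offset) {
    stop("frame grid too short: must span the peak + late_offset",
         call. = FALSE)
  }
  late_frame <- which.min(abs(frame_times - (t_peak + late_offset)))

  B <- truth$dce_baseline
  P <- truth$dce_peak
  L <- B + (P - B) / truth$ser      # inverts the enhancement-ratio formula
  curve <- numeric(nt)
  curve[seq_len(n_baseline)] <- B
  rise <- seq(n_baseline, peak_frame)
  curve[rise] <- B + (P - B) * (rise - n_baseline) / (peak_frame - n_baseline)
  wash <- seq(peak_frame, nt)
  slope <- (L - P) / (frame_times[late_frame] - t_peak)
  curve[wash] <- P + slope * (frame_times[wash] - t_peak)

  inside <- digitize_ellipsoid(grid, spacing, truth$center, truth$semiaxes)
  arr <- array(B, dim = c(grid, nt))
  nvox <- prod(grid)
  m <- matrix(arr, nvox, nt)
  m[as.vector(inside), ] <- rep(curve, each = sum(inside))
  arr <- array(m, dim = c(grid, nt))
  if (noise_sigma > 0) {
    set.seed(seed)
    arr <- arr + stats::rnorm(length(arr), 0, noise_sigma)
  }
  list(
    series = dynamic_series(arr, frame_times, spacing),
    mask = roi_mask(inside, spacing, label = "phantom lesion"),
    peak_frame = peak_frame
  )
}
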