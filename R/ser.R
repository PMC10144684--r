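#' Compute a voxel-wise signal enhancement ratio (SER) map
#'
#' Semi-quantitative analysis of a dynamic contrast-enhanced series:
#' per voxel,
#' `SER = (S_early - S_baseline) / (S_late - S_baseline)`, where
#' `S_baseline` is the mean of the first `n_baseline` frames, `S_early` is
#' the peak signal over the post-baseline frames (earliest frame wins ties),
#' and `S_late` is the signal at the frame whose acquisition time is closest
#' to that voxel's peak time plus `late_offset` seconds. When the offset
#' falls beyond the acquisition the last frame is used and the voxel is
#' flagged in the `clamped` quality channel. Voxels whose enhancement
#' denominator `|S_late - S_baseline|` is below `epsilon` (non-enhancing
#' voxels) are `NaN`.
#'
#' With `peak = "roi"` the peak time is taken from the mask-averaged (or,
#' without a mask, grid-averaged) enhancement curve and shared by all
#' voxels, matching a whole-ROI reading; the default `"voxel"` definition is
#' the one whose ROI mean/median summarises the map itself.
#'
#' @param series A [dynamic_series()] with at least `n_baseline + 1` frames.
#' @param mask Optional [roi_mask()]; voxels outside it are `NaN`.
#' @param n_baseline Number of pre-contrast frames averaged into
#'   `S_baseline` (default 10).
#' @param late_offset Seconds after the peak at which the washout signal is
#'   read (default 360, i.e. 6 minutes).
#' @param epsilon Denominator guard; default `1e-6 * max(signal)`, a
#'   scale-free threshold.
#' @param peak `"voxel"` (default) or `"roi"` peak-time definition.
#' @return A [parameter_map()] named `"SER"` (dimensionless) with an
#'   attribute `clamped`: a logical 3-D array marking voxels whose late
#'   frame was clamped to the end of the acquisition.
#' @export
compute_ser_map <- function(series, mask = NULL, n_baseline = 10L,
                            late_offset = 360, epsilon = NULL,
                            peak = c("voxel", "roi")) {
  stopifnot(inherits(series, "dynamic_series"))
  peak <- match.arg(peak)
  n_baseline <- as.integer(n_baseline)
  tms <- series$frame_times
  nt <- length(tms)
  if (n_baseline < 1L) stop("`n_baseline` must be >= 1", call. = FALSE)
  if (nt < n_baseline + 1L) {
    stop(sprintf("SER needs at least %d frames (%d baseline + 1), got %d",
                 n_baseline + 1L, n_baseline, nt), call. = FALSE)
  }
  if (!is.finite(late_offset) || late_offset <= 0) {
    stop("`late_offset` must be > 0", call. = FALSE)
  }
  dm <- dim(series$voxels)
  check_mask_shape(mask, dm[1:3])

  nvox <- prod(dm[1:3])
  sig <- matrix(series$voxels, nrow = nvox, ncol = nt)
  if (is.null(epsilon)) epsilon <- 1e-6 * max(sig, 0)

  sel <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask$mask)
  out <- rep(NaN, nvox)
  clamped <- rep(FALSE, nvox)

  if (any(sel)) {
    y <- sig[sel, , drop = FALSE]
    s_base <- rowMeans(y[, seq_len(n_baseline), drop = FALSE])
    post <- (n_baseline + 1L):nt
    ypost <- y[, post, drop = FALSE]
    peak_col <- max.col(ypost, ties.method = "first")   # earliest tie wins
    s_early <- ypost[cbind(seq_len(nrow(y)), peak_col)]

    if (peak == "roi") {
      roi_curve <- colMeans(ypost)
      peak_col[] <- which.max(roi_curve)
    }
    t_peak <- tms[post][peak_col]
    target <- t_peak + late_offset
    # nearest frame to the target time; ties resolved to the earlier frame
    late_idx <- vapply(target, function(tt) which.min(abs(tms - tt)), 1L)
    s_late <- y[cbind(seq_len(nrow(y)), late_idx)]

    denom <- s_late - s_base
    ser <- (s_early - s_base) / denom
    ser[abs(denom) < epsilon] <- NaN
    out[sel] <- ser
    clamped[sel] <- target > tms[nt]
  }

  map <- parameter_map(array(out, dim = dm[1:3]), name = "SER",
                       voxel_spacing = series$voxel_spacing)
  attr(map, "clamped") <- array(clamped, dim = dm[1:3])
  attr(map, "epsilon") <- epsilon
  map
}
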