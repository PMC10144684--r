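#' Longest in-plane diameter of a lesion mask
#'
#' RECIST-convention diameter: for each axial slice (third array axis), the
#' maximum Euclidean distance in mm between centres of any two foreground
#' voxels, using the in-plane spacing; the result is the maximum over
#' slices. A slice with a single foreground voxel contributes 0. With
#' `full_3d = TRUE` the maximum is taken over all foreground voxel pairs in
#' 3-D instead.
#'
#' Distances are between voxel centres, so the digitised diameter of a
#' convex shape underestimates its continuous diameter by up to one voxel.
#'
#' @param mask A nonempty [roi_mask()].
#' @param full_3d Measure across slices as well (default `FALSE`).
#' @return Diameter in mm.
#' @export
longest_diameter <- function(mask, full_3d = FALSE) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground voxels", call. = FALSE)
  sp <- mask$voxel_spacing
  if (full_3d) {
    pts <- sweep(idx, 2, sp, `*`)
    return(max_pairwise_distance(pts))
  }
  best <- 0
  for (z in unique(idx[, 3])) {
    pts <- idx[idx[, 3] == z, 1:2, drop = FALSE]
    if (nrow(pts) < 2L) next
    pts <- sweep(pts, 2, sp[1:2], `*`)
    best <- max(best, max_pairwise_distance(pts))
  }
  best
}

# Maximum pairwise distance; for planar point sets the search is pruned to
# the convex hull, which carries the diameter. 3-D sets fall back to an
# all-pairs scan (masks are lesion-sized).
max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (ncol(pts) == 2L && n > 8L) {
    hull <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]),
                     error = function(e) seq_len(n))
    if (length(hull) >= 2L) pts <- pts[hull, , drop = FALSE]
  }
  sqrt(max(as.vector(stats::dist(pts))^2))
}

#' Tumor volume from a binary mask
#'
#' Foreground voxel count times voxel volume (product of the spacings).
#'
#' @param mask A nonempty [roi_mask()].
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- sum(mask$mask)
  if (n == 0L) stop("mask has no foreground voxels", call. = FALSE)
  n * prod(mask$voxel_spacing)
}

#' Summary statistics of a parameter map over an ROI
#'
#' Mean and median over the finite map values inside the mask; `NaN`
#' voxels (invalid fits, non-enhancing voxels) are excluded and the number
#' of valid voxels is reported. An all-`NaN` ROI yields `NaN` statistics
#' with `n_valid = 0`. Even-count medians use midpoint averaging.
#'
#' @param map A [parameter_map()].
#' @param mask A nonempty [roi_mask()] with the same spatial shape.
#' @return List with `mean`, `median`, `n_valid`.
#' @export
roi_statistics <- function(map, mask) {
  stopifnot(inherits(map, "parameter_map"), inherits(mask, "roi_mask"))
  if (!identical(dim(map$values), dim(mask$mask))) {
    stop("map and mask shapes differ", call. = FALSE)
  }
  if (!any(mask$mask)) stop("mask has no foreground voxels", call. = FALSE)
  v <- map$values[mask$mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    return(list(mean = NaN, median = NaN, n_valid = 0L))
  }
  list(mean = mean(v), median = stats::median(v), n_valid = length(v))
}

#' Caliper tumor volume
#'
#' The bench formula used to size subcutaneous xenograft tumors from
#' two-axis caliper readings: `length x width^2 x 0.5` (mm^3). A 175 mm^3
#' result is the conventional randomization threshold for PDX treatment
#' arms.
#'
#' @param length Longest caliper axis, mm; must satisfy
#'   `length >= width > 0`.
#' @param width Perpendicular caliper axis, mm.
#' @return Volume in mm^3.
#' @examples
#' caliper_volume(14, 5)  # 175
#' @export
caliper_volume <- function(length, width) {
  if (!is.finite(length) || !is.finite(width) || width <= 0 || length < width) {
    stop("need `length >= width > 0`", call. = FALSE)
  }
  length * width^2 * 0.5
}

#' Extract the lesion-level imaging biomarker set
#'
#' One row per lesion and timepoint: longest diameter, volume, and
#' mean/median of the ADC and SER maps over the mask — the scalar feature
#' set consumed by the response and association stages.
#'
#' @param mask A nonempty [roi_mask()].
#' @param adc_map,ser_map Optional [parameter_map()]s; their summary
#'   statistics are `NA` when absent.
#' @param subject_id,timepoint,cohort,modality,study_date Metadata carried
#'   into downstream tables. `timepoint` is one of `"T0"`, `"T1"`, `"T2"`.
#' @return A one-row [tibble::tibble()].
#' @export
extract_lesion_features <- function(mask, adc_map = NULL, ser_map = NULL,
                                    subject_id = "S1",
                                    timepoint = c("T0", "T1", "T2"),
                                    cohort = c("patient", "PDX"),
                                    modality = "MRI", study_date = NA) {
  timepoint <- match.arg(timepoint)
  cohort <- match.arg(cohort)
  adc <- if (is.null(adc_map)) list(mean = NA_real_, median = NA_real_)
         else roi_statistics(adc_map, mask)
  ser <- if (is.null(ser_map)) list(mean = NA_real_, median = NA_real_)
         else roi_statistics(ser_map, mask)
  tibble::tibble(
    subject_id = subject_id, cohort = cohort, lesion_label = mask$label,
    timepoint = timepoint,
    longest_diameter = longest_diameter(mask),
    volume = tumor_volume(mask),
    adc_mean = adc$mean, adc_median = adc$median,
    ser_mean = ser$mean, ser_median = ser$median,
    modality = modality, study_date = study_date
  )
}
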