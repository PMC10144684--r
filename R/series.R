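#' Construct a diffusion-weighted MRI series
#'
#' A 4-D voxel grid indexed (x, y, z, b-index) together with its diffusion
#' weightings. Signal is in arbitrary scanner units; b-values in s/mm^2.
#'
#' @param voxels 4-D numeric array of nonnegative signal, 4th axis = b-index.
#' @param b_values Strictly increasing, nonnegative diffusion weightings
#'   (s/mm^2), one per 4th-axis index. At least two distinct values are
#'   required for ADC fitting.
#' @param voxel_spacing Positive length-3 numeric, voxel size in mm.
#' @return An object of class `diffusion_series`.
#' @examples
#' arr <- array(1000, dim = c(2, 2, 1, 3))
#' diffusion_series(arr, b_values = c(0, 150, 700), voxel_spacing = c(1, 1, 1))
#' @export
diffusion_series <- function(voxels, b_values, voxel_spacing = c(1, 1, 1)) {
  voxels <- check_series_array(voxels, length(b_values), "b_values")
  b_values <- as.numeric(b_values)
  if (any(b_values < 0) || any(diff(b_values) <= 0)) {
    stop("`b_values` must be nonnegative and strictly increasing", call. = FALSE)
  }
  structure(
    list(voxels = voxels, b_values = b_values,
         voxel_spacing = check_spacing(voxel_spacing)),
    class = "diffusion_series"
  )
}

#' Construct a dynamic contrast-enhanced MRI series
#'
#' A 4-D voxel grid indexed (x, y, z, frame) with frame acquisition times in
#' seconds. Signal enhancement ratio computation requires at least
#' `n_baseline + 1` frames (10 pre-contrast frames plus one post-baseline
#' frame under the defaults).
#'
#' @param voxels 4-D numeric array of nonnegative signal, 4th axis = frame.
#' @param frame_times Strictly increasing frame times in seconds.
#' @param voxel_spacing Positive length-3 numeric, voxel size in mm.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, frame_times, voxel_spacing = c(1, 1, 1)) {
  voxels <- check_series_array(voxels, length(frame_times), "frame_times")
  frame_times <- as.numeric(frame_times)
  if (any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(voxels = voxels, frame_times = frame_times,
         voxel_spacing = check_spacing(voxel_spacing)),
    class = "dynamic_series"
  )
}

#' Construct a binary region-of-interest (lesion) mask
#'
#' @param mask 3-D logical (or 0/1 numeric) array marking lesion voxels.
#' @param voxel_spacing Positive length-3 numeric, voxel size in mm.
#' @param label Free-text lesion name/location.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_spacing = c(1, 1, 1), label = "lesion") {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a 3-D array", call. = FALSE)
  }
  storage <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(storage)) stop("`mask` contains NA", call. = FALSE)
  structure(
    list(mask = storage, voxel_spacing = check_spacing(voxel_spacing),
         label = as.character(label)[1]),
    class = "roi_mask"
  )
}

#' Construct a voxel-wise parameter map
#'
#' Derived 3-D map (ADC in mm^2/s or the dimensionless SER); `NaN` marks
#' voxels where the parameter is undefined (outside the mask, nonpositive
#' signal, vanishing enhancement denominator).
#'
#' @param values 3-D numeric array; `NaN` for invalid voxels.
#' @param name Either `"ADC"` or `"SER"`.
#' @param voxel_spacing Positive length-3 numeric, mm.
#' @return An object of class `parameter_map` with a `units` field
#'   (`"mm^2/s"` for ADC, `""` for SER).
#' @export
parameter_map <- function(values, name = c("ADC", "SER"),
                          voxel_spacing = c(1, 1, 1)) {
  name <- match.arg(name)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  finite <- values[is.finite(values)]
  if (name == "ADC" && length(finite) && any(finite < 0)) {
    stop("finite ADC values must be >= 0", call. = FALSE)
  }
  structure(
    list(values = values, name = name,
         units = if (name == "ADC") "mm^2/s" else "",
         voxel_spacing = check_spacing(voxel_spacing)),
    class = "parameter_map"
  )
}

#' @export
print.diffusion_series <- function(x, ...) {
  cat("<diffusion_series> ", paste(dim(x$voxels)[1:3], collapse = "x"),
      " voxels, b = [", paste(x$b_values, collapse = ", "), "] s/mm^2\n",
      sep = "")
  invisible(x)
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat("<dynamic_series> ", paste(dim(x$voxels)[1:3], collapse = "x"),
      " voxels, ", length(x$frame_times), " frames over ",
      diff(range(x$frame_times)), " s\n", sep = "")
  invisible(x)
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("<parameter_map> ", x$name, ", ",
      paste(dim(x$values), collapse = "x"), ", ",
      length(v), " valid voxels",
      if (length(v)) sprintf(", median %.4g", stats::median(v)), "\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", x$label, "', ", sum(x$mask), "/", length(x$mask),
      " foreground voxels\n", sep = "")
  invisible(x)
}

check_series_array <- function(voxels, n4, axis_name) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    stop("`voxels` must be a 4-D array", call. = FALSE)
  }
  if (dim(voxels)[4] != n4) {
    stop(sprintf("length of `%s` (%d) must equal the 4th array dimension (%d)",
                 axis_name, n4, dim(voxels)[4]), call. = FALSE)
  }
  storage.mode(voxels) <- "double"
  voxels
}

check_spacing <- function(voxel_spacing) {
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be 3 positive numbers (mm)", call. = FALSE)
  }
  voxel_spacing
}

check_mask_shape <- function(mask, spatial_dim) {
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "roi_mask"))
    if (!identical(dim(mask$mask), as.integer(spatial_dim))) {
      stop("mask shape does not match the series spatial shape", call. = FALSE)
    }
  }
  invisible(NULL)
}
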