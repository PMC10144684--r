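#' Read a 4-D series from NIfTI with a JSON timing sidecar
#'
#' The sidecar carries either `b_values` (s/mm^2, giving a
#' [diffusion_series()]) or `frame_times` (seconds, giving a
#' [dynamic_series()]); voxel spacing is taken from the NIfTI header.
#'
#' @param nifti_path Path to a NIfTI-1 volume (`.nii` / `.nii.gz`).
#' @param sidecar_path Path to the JSON sidecar; defaults to the NIfTI path
#'   with a `.json` extension.
#' @return A [diffusion_series()] or [dynamic_series()].
#' @export
read_series <- function(nifti_path,
                        sidecar_path = sub("\\.nii(\\.gz)?$", ".json",
                                           nifti_path)) {
  if (!file.exists(sidecar_path)) {
    stop("timing sidecar not found: ", sidecar_path, call. = FALSE)
  }
  img <- RNifti::readNifti(nifti_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  arr <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[1:3]
  if (!is.null(side$b_values)) {
    diffusion_series(arr, side$b_values, spacing)
  } else if (!is.null(side$frame_times)) {
    dynamic_series(arr, side$frame_times, spacing)
  } else {
    stop("sidecar has neither `b_values` nor `frame_times`", call. = FALSE)
  }
}

#' Write a 4-D series as NIfTI plus a JSON sidecar
#'
#' @param series A [diffusion_series()] or [dynamic_series()].
#' @param nifti_path Output NIfTI path; the sidecar is written alongside
#'   with a `.json` extension.
#' @return `nifti_path`, invisibly.
#' @export
write_series <- function(series, nifti_path) {
  side <- if (inherits(series, "diffusion_series")) {
    list(b_values = series$b_values)
  } else if (inherits(series, "dynamic_series")) {
    list(frame_times = series$frame_times)
  } else stop("not a series object", call. = FALSE)
  img <- RNifti::asNifti(series$voxels)
  RNifti::pixdim(img) <- c(series$voxel_spacing, 1)
  RNifti::writeNifti(img, nifti_path)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", nifti_path),
                       auto_unbox = FALSE, digits = NA)
  invisible(nifti_path)
}

#' Read/write a binary ROI mask as NIfTI
#'
#' @param path NIfTI path. Voxels > 0.5 are foreground.
#' @param label Lesion label attached on read.
#' @return [roi_mask()] for `read_mask`; the path (invisibly) for
#'   `write_mask`.
#' @export
read_mask <- function(path, label = "lesion") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim = dim(img)),
           voxel_spacing = RNifti::pixdim(img)[1:3], label = label)
}

#' @rdname read_mask
#' @param mask A [roi_mask()].
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- mask$voxel_spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a parameter map as float32 NIfTI with a provenance sidecar
#'
#' Invalid voxels are `NaN` in the written volume; the JSON sidecar records
#' the map name, units, and tool version.
#'
#' @param map A [parameter_map()].
#' @param path Output NIfTI path.
#' @param extra Named list merged into the sidecar (fit parameters etc.).
#' @return `path`, invisibly.
#' @export
write_parameter_map <- function(map, path, extra = list()) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_spacing
  RNifti::writeNifti(img, path, datatype = "float")
  side <- c(list(name = map$name, units = map$units,
                 version = as.character(utils::packageVersion("coclin"))),
            extra)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: a header row of sample ids, first column
#' `gene_symbol`, remaining columns nonnegative numeric values. Duplicate
#' symbols, negative values, and ragged rows are rejected with the
#' offending line.
#'
#' @param path TSV file path.
#' @param cohort,timepoint Metadata attached to the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, cohort = "patient", timepoint = "T0") {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (header[1] != "gene_symbol") {
    stop("first column must be `gene_symbol`", call. = FALSE)
  }
  ncol_expect <- length(header)
  body <- parts[-1]
  genes <- character(length(body))
  vals <- matrix(NA_real_, length(body), ncol_expect - 1L)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expect) {
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L,
                   ncol_expect, length(row)), call. = FALSE)
    }
    genes[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric expression value", i + 1L),
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("line %d: negative expression value for %s", i + 1L,
                   row[1]), call. = FALSE)
    }
    vals[i, ] <- v
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene symbol: ", dup[1], call. = FALSE)
  }
  dimnames(vals) <- list(genes, header[-1])
  expression_matrix(vals, cohort = cohort, timepoint = timepoint)
}

#' Write an expression matrix as TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  con <- file(path, open = "wb")         # \n endings on every platform
  on.exit(close(con))
  writeLines(paste(c("gene_symbol", colnames(m)), collapse = "\t"), con)
  body <- apply(unclass(m), 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Export a factor assignment for audit
#'
#' Two TSVs: the 4 per-sample factors and the per-gene factor index.
#'
#' @param assignment A `factor_assignment` from [simulate_on_treatment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_factor_assignment <- function(assignment, dir) {
  stopifnot(inherits(assignment, "factor_assignment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(factor_index = 1:4, assignment$factors, check.names = FALSE),
    file.path(dir, "factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = rownames(assignment$index), assignment$index,
               check.names = FALSE),
    file.path(dir, "factor_index.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
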