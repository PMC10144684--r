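#' Monoexponential diffusion signal model
#'
#' Forward model `S(b) = S0 * exp(-ADC * b)` used both by the digital
#' phantoms and as the residual model of [fit_adc_map()].
#'
#' @param s0 Signal at b = 0, must be > 0.
#' @param adc Apparent diffusion coefficient in mm^2/s, must be >= 0.
#' @param b_values Diffusion weightings in s/mm^2.
#' @return Numeric vector of predicted signals, one per b-value.
#' @examples
#' predict_diffusion_signal(1000, 1e-3, c(0, 150, 700))
#' @export
predict_diffusion_signal <- function(s0, adc, b_values) {
  if (!is.finite(s0) || s0 <= 0) stop("`s0` must be > 0", call. = FALSE)
  if (!is.finite(adc) || adc < 0) stop("`adc` must be >= 0", call. = FALSE)
  s0 * exp(-adc * as.numeric(b_values))
}

#' Fit a voxel-wise ADC map from a diffusion-weighted series
#'
#' Estimates, per voxel, the apparent diffusion coefficient minimising the
#' least-squares misfit of the monoexponential decay
#' `S(b) = S0 * exp(-ADC * b)`. The fit is initialised from the closed-form
#' log-linear regression of `log S` on `b` and refined by a damped
#' Gauss-Newton iteration with ADC constrained to `adc_bounds`; on noiseless
#' data the log-linear start is already the exact least-squares optimum and
#' the refinement leaves it untouched.
#'
#' Voxels outside `mask` (when given) and voxels with any nonpositive signal
#' are `NaN` in the output: the log transform is undefined there and
#' clipping would bias the estimate.
#'
#' @param series A [diffusion_series()] with at least 2 distinct b-values.
#' @param mask Optional [roi_mask()] restricting the fit.
#' @param adc_bounds Length-2 fit bounds in mm^2/s; default `c(0, 0.01)`
#'   covers all physiological tissue water diffusion.
#' @param max_iter,tol Gauss-Newton iteration cap and relative step
#'   tolerance.
#' @return A [parameter_map()] named `"ADC"` in mm^2/s.
#' @seealso [predict_diffusion_signal()], [make_dwi_phantom()]
#' @export
fit_adc_map <- function(series, mask = NULL, adc_bounds = c(0, 0.01),
                        max_iter = 50L, tol = 1e-12) {
  stopifnot(inherits(series, "diffusion_series"))
  b <- series$b_values
  if (length(unique(b)) < 2L) {
    stop("ADC fitting requires at least 2 distinct b-values", call. = FALSE)
  }
  dm <- dim(series$voxels)
  check_mask_shape(mask, dm[1:3])

  nvox <- prod(dm[1:3])
  sig <- matrix(series$voxels, nrow = nvox, ncol = dm[4])

  fit_sel <- rowSums(sig <= 0 | !is.finite(sig)) == 0L
  if (!is.null(mask)) fit_sel <- fit_sel & as.vector(mask$mask)

  out <- rep(NaN, nvox)
  if (any(fit_sel)) {
    y <- sig[fit_sel, , drop = FALSE]
    est <- adc_loglinear(y, b)
    est$adc <- pmin(pmax(est$adc, adc_bounds[1]), adc_bounds[2])
    est <- adc_gauss_newton(y, b, est$s0, est$adc, adc_bounds, max_iter, tol)
    out[fit_sel] <- est$adc
  }
  parameter_map(array(out, dim = dm[1:3]), name = "ADC",
                voxel_spacing = series$voxel_spacing)
}

# Closed-form log-linear start: OLS of log(S) on b, vectorised over voxels.
adc_loglinear <- function(y, b) {
  ly <- log(y)
  bc <- b - mean(b)
  slope <- as.vector(ly %*% bc) / sum(bc^2)
  intercept <- rowMeans(ly) - slope * mean(b)
  list(s0 = exp(intercept), adc = -slope)
}

# Damped Gauss-Newton on (S0, ADC) per voxel, all voxels advanced jointly;
# the 2x2 normal equations are solved in closed form.
adc_gauss_newton <- function(y, b, s0, adc, bounds, max_iter, tol) {
  sse <- function(s0, adc, rows = seq_len(nrow(y))) {
    pred <- exp(outer(-adc, b)) * s0
    rowSums((pred - y[rows, , drop = FALSE])^2)
  }
  cur_sse <- sse(s0, adc)
  for (iter in seq_len(max_iter)) {
    E <- exp(outer(-adc, b))           # nvox x nb
    pred <- E * s0
    R <- pred - y
    # Jacobian columns: d/ds0 = E ; d/dADC = -s0 * b * E
    Jb <- -(pred * rep(b, each = nrow(E)))
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * Jb)
    a22 <- rowSums(Jb * Jb)
    g1 <- rowSums(E * R)
    g2 <- rowSums(Jb * R)
    det <- a11 * a22 - a12^2
    det[det <= .Machine$double.eps] <- NA_real_
    d_s0 <- -(a22 * g1 - a12 * g2) / det
    d_adc <- -(a11 * g2 - a12 * g1) / det
    d_s0[is.na(d_s0)] <- 0
    d_adc[is.na(d_adc)] <- 0

    step <- rep(1, length(s0))
    new_s0 <- s0
    new_adc <- adc
    active <- rep(TRUE, length(s0))
    for (h in 1:12) {                 # backtracking halving
      if (!any(active)) break
      cand_s0 <- pmax(s0[active] + step[active] * d_s0[active],
                      .Machine$double.xmin)
      cand_adc <- pmin(pmax(adc[active] + step[active] * d_adc[active],
                            bounds[1]), bounds[2])
      idx <- which(active)
      cand_sse <- sse(cand_s0, cand_adc, rows = idx)
      ok <- cand_sse <= cur_sse[active] + 1e-14 * (1 + cur_sse[active])
      new_s0[idx[ok]] <- cand_s0[ok]
      new_adc[idx[ok]] <- cand_adc[ok]
      cur_sse[idx[ok]] <- cand_sse[ok]
      active[idx[ok]] <- FALSE
      step[active] <- step[active] / 2
    }
    moved <- max(abs(new_adc - adc) / (abs(adc) + 1e-6),
                 abs(new_s0 - s0) / (abs(s0) + 1e-12))
    s0 <- new_s0
    adc <- new_adc
    if (moved < tol) break
  }
  list(s0 = s0, adc = adc)
}
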