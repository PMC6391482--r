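#' Fit the apparent diffusion coefficient from multi-b DWI
#'
#' Ordinary least-squares fit of `ln S` versus b per voxel; ADC is the
#' negated slope, converted to um^2/ms (1e-3 mm^2/s = 1 um^2/ms, and b is in
#' s/mm^2, so the raw slope in mm^2/s is multiplied by 1e3). Voxels with any
#' non-positive signal are masked (NA).
#'
#' @param dwi Array `b x nx x ny x nz` (or `b x n`), e.g. from
#'   [simulate_dwi()].
#' @param b_values Numeric vector of b-values in s/mm^2, length matching the
#'   first dimension; >= 2 distinct values required. Defaults to the
#'   `b_values` attribute of `dwi` if present.
#' @return Array of ADC in um^2/ms over the spatial dimensions.
#' @export
fit_adc <- function(dwi, b_values = attr(dwi, "b_values")) {
  d <- dim(dwi)
  if (is.null(d)) stop("dwi must be an array with b along the first dimension")
  if (is.null(b_values) || length(b_values) != d[1]) {
    stop("b_values must match the first dimension of dwi")
  }
  if (length(unique(b_values)) < 2) stop("need >= 2 distinct b-values")
  spatial <- d[-1]
  m <- matrix(dwi, d[1])
  ok <- colSums(is.finite(m) & m > 0) == d[1]
  slope <- rep(NA_real_, ncol(m))
  if (any(ok)) {
    b <- b_values - mean(b_values)
    ls <- log(m[, ok, drop = FALSE])
    slope[ok] <- as.numeric(crossprod(b, ls)) / sum(b^2)
  }
  adc <- -slope * 1e3               # (1/(s/mm^2)) -> mm^2/s -> um^2/ms
  if (length(spatial) > 1) array(adc, dim = spatial) else adc
}

#' Contrast-agent leakage correction of a dR2*(t) curve
#'
#' Linear-regression correction of voxel-level `dR2*(t)` against a reference
#' curve from non-leaky tissue. In `unidirectional` mode the voxel curve is
#' modelled as `K1 * ref(t) - K2 * int_0^t ref`, accounting for contrast flux
#' out of the vasculature; the `bidirectional` variant adds a first-order
#' influx (back-flux) term, the double integral of the reference, so that
#' flux back into the vasculature is also absorbed by the model. The
#' corrected curve is the voxel curve minus the fitted leakage terms
#' (`K1 * ref` plus residual), preserving voxel-specific shape.
#'
#' @param d_r2star_t Numeric vector (one voxel) or `time x n` matrix of
#'   baseline-referenced dR2* curves, ms^-1.
#' @param reference_curve Mean dR2*(t) over a designated non-leaky mask.
#' @param time_axis Time axis in seconds (uniform spacing).
#' @param mode One of `"bidirectional"` (default), `"unidirectional"`,
#'   `"none"`.
#' @return A list: `corrected` (same shape as input), `k1`, `k2` and (for
#'   bidirectional) `k_back`, per voxel.
#' @export
leakage_correct <- function(d_r2star_t, reference_curve, time_axis,
                            mode = c("bidirectional", "unidirectional", "none")) {
  mode <- match.arg(mode)
  vec_in <- is.null(dim(d_r2star_t))
  m <- if (vec_in) matrix(d_r2star_t) else d_r2star_t
  nt <- nrow(m)
  stopifnot(length(reference_curve) == nt, length(time_axis) == nt)
  if (mode == "none") {
    out <- list(corrected = d_r2star_t,
                k1 = rep(1, ncol(m)), k2 = rep(0, ncol(m)))
    return(out)
  }
  if (all(abs(reference_curve) < .Machine$double.eps)) {
    stop("degenerate reference curve (all zeros)")
  }
  cint <- pracma::cumtrapz(time_axis, reference_curve)[, 1]
  x <- cbind(ref = reference_curve, efflux = cint)
  if (mode == "bidirectional") {
    x <- cbind(x, influx = pracma::cumtrapz(time_axis, cint)[, 1])
  }
  beta <- qr.solve(x, m)             # columns: per-voxel coefficients
  leak <- x[, -1, drop = FALSE] %*% beta[-1, , drop = FALSE]
  corrected <- m - leak
  res <- list(corrected = if (vec_in) corrected[, 1] else corrected,
              k1 = beta[1, ], k2 = -beta[2, ])
  if (mode == "bidirectional") res$k_back <- -beta[3, ]
  res
}

#' Cerebral blood volume proxy from the dR2*(t) integral
#'
#' Trapezoidal integral of the (leakage-corrected) dR2*(t) curve over the
#' integration window. Units are ms^-1 * s (arbitrary, removed by the NAWM
#' normalization).
#'
#' @param d_r2star_t Vector or `time x n` matrix of dR2* curves.
#' @param time_axis Time axis in seconds.
#' @param integration_window Integer index window (default: full series).
#' @return Numeric vector of raw CBV per voxel (scalar for vector input).
#' @export
compute_cbv <- function(d_r2star_t, time_axis,
                        integration_window = seq_along(time_axis)) {
  vec_in <- is.null(dim(d_r2star_t))
  m <- if (vec_in) matrix(d_r2star_t) else d_r2star_t
  stopifnot(nrow(m) == length(time_axis))
  w <- as.integer(integration_window)
  if (length(w) < 2 || any(w < 1) || any(w > length(time_axis))) {
    stop("integration window must contain >= 2 samples inside the series")
  }
  tt <- time_axis[w]
  out <- apply(m[w, , drop = FALSE], 2, function(y) {
    if (all(is.finite(y))) pracma::trapz(tt, y) else NA_real_
  })
  if (vec_in) out[[1]] else out
}

#' Normalize raw CBV to contralateral normal-appearing white matter
#'
#' Divides the raw CBV map by its mean over the NAWM mask, so the NAWM mean
#' of the result is 1 by construction. Idempotent and invariant to positive
#' rescaling of the input.
#'
#' @param cbv_raw Numeric array / vector of raw CBV.
#' @param nawm_mask Logical array / vector of the same shape, non-empty.
#' @return rCBV array of the same shape (dimensionless).
#' @export
normalize_cbv <- function(cbv_raw, nawm_mask) {
  stopifnot(length(cbv_raw) == length(nawm_mask))
  if (!any(nawm_mask, na.rm = TRUE)) stop("NAWM mask is empty")
  ref <- mean(cbv_raw[which(as.logical(nawm_mask))], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) stop("non-positive NAWM mean CBV")
  cbv_raw / ref
}
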