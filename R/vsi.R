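#' Voxel-wise vessel size index map
#'
#' Combines rCBV, ADC and the peak transverse relaxation-rate changes into
#' the vessel size index
#' `VSI = k * sqrt(rCBV * ADC) * dR2*_max / dR2_max^{3/2}`,
#' in micrometres when ADC is in um^2/ms and the rates are in ms^-1
#' (dimensionally, (um^2/ms)^{1/2} * ms^{1/2} = um). Note the grouping: the
#' gradient-echo peak is divided by the 3/2 power of the spin-echo peak, not
#' the 3/2 power of their ratio. Voxels where the spin-echo peak is <= 0, or
#' where `rCBV * ADC` is negative, or any input is missing, are marked
#' invalid (NA).
#'
#' @param rcbv Dimensionless rCBV array.
#' @param adc ADC array in um^2/ms, same shape.
#' @param d_r2star_max Peak dR2* array, ms^-1.
#' @param d_r2_max Peak dR2 array, ms^-1.
#' @param constant_k Proportionality constant of the cylinder-network model
#'   (default 0.867; exposed because the constant's calibration between MRI
#'   and histology has not been thoroughly validated).
#' @return A list of class `vsi_map`: `vsi` (um, same shape as inputs, NA
#'   where invalid), `valid` (logical), `constant_k`.
#' @export
compute_vsi <- function(rcbv, adc, d_r2star_max, d_r2_max,
                        constant_k = 0.867) {
  dims <- dim(rcbv)
  same <- function(x) identical(dim(x), dims) && length(x) == length(rcbv)
  if (!same(adc) || !same(d_r2star_max) || !same(d_r2_max)) {
    stop("all input maps must share one voxel grid")
  }
  prod_ba <- rcbv * adc
  valid <- is.finite(prod_ba) & is.finite(d_r2star_max) & is.finite(d_r2_max) &
    d_r2_max > 0 & prod_ba >= 0
  vsi <- rep(NA_real_, length(rcbv))
  vsi[valid] <- constant_k * sqrt(prod_ba[valid]) *
    d_r2star_max[valid] / d_r2_max[valid]^1.5
  if (!is.null(dims)) {
    dim(vsi) <- dims
    dim(valid) <- dims
  }
  structure(list(vsi = vsi, valid = valid, constant_k = constant_k),
            class = "vsi_map")
}

#' Histologic vessel size index from a set of vessel radii
#'
#' Cylinder-network summary of a radius distribution:
#' `VSI_histo = (sum n(r_i) r_i^{4/3} / sum n(r_i) r_i^2)^{-3/2}`,
#' modelling vessels as randomly oriented continuous cylinders. The printed
#' -3/2 exponent on the ratio is used literally; it is algebraically
#' identical to `(sum n r^2 / sum n r^{4/3})^{3/2}`, the form more common in
#' the literature. For a monodisperse set (all radii equal r) the result is
#' exactly r, and the value always lies within [min(radii), max(radii)].
#'
#' @param radii Vessel radii in um (> 0). May be empty.
#' @param counts Optional multiplicities `n(r_i)` (default all 1).
#' @return VSI in um, or NA for an empty set.
#' @export
vsi_from_radii <- function(radii, counts = rep(1, length(radii))) {
  stopifnot(length(counts) == length(radii))
  if (!length(radii)) return(NA_real_)
  if (any(radii <= 0) || any(counts < 0)) stop("radii must be > 0, counts >= 0")
  (sum(counts * radii^(4 / 3)) / sum(counts * radii^2))^(-3 / 2)
}
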