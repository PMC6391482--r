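#' Simulate a paired MRI-histology biopsy cohort
#'
#' Draws per-target paired observations from a bivariate-normal latent model
#' with requested population correlations: (rCBV, vessel density) at
#' `rho_density` and (VSI_MRI, VSI_histology) at `rho_caliber`. Marginal
#' means and SDs default to the cohort conditions the pipeline emulates
#' (26 targets; median rCBV 1.39, density 40.6 /mm^2, VSI_MRI 13.67 um,
#' VSI_histology 12.60 um; spreads consistent with the reported
#' interquartile ranges; 17 grade-III and 9 grade-IV targets, matching 7
#' grade-III and 4 grade-IV patients contributing one to three targets
#' each). Negative draws of intrinsically positive quantities are truncated
#' at a small positive floor.
#'
#' @param n_targets Number of biopsy targets (>= 3).
#' @param rho_density Population correlation of (rCBV, density), |rho| <= 1.
#' @param rho_caliber Population correlation of (VSI_MRI, VSI_histo).
#' @param means Named list: `rcbv`, `density`, `vsi_mri`, `vsi_histo`.
#' @param sds Named list of marginal SDs (the "noise scales"), same names.
#' @param grade_fraction_iii Fraction of targets labelled grade III.
#' @param seed Integer seed.
#' @return A tibble with one row per target: `target`, `grade` ("III"/"IV"),
#'   `rcbv`, `density`, `vsi_mri`, `vsi_histo`, and the standard-normal
#'   latents `z_rcbv`, `z_density`, `z_vsi_mri`, `z_vsi_histo`.
#' @export
make_paired_cohort <- function(n_targets = 26,
                               rho_density = 0.42,
                               rho_caliber = 0.49,
                               means = list(rcbv = 1.39, density = 40.6,
                                            vsi_mri = 13.67, vsi_histo = 12.60),
                               sds = list(rcbv = 1.0, density = 25,
                                          vsi_mri = 2.3, vsi_histo = 2.7),
                               grade_fraction_iii = 17 / 26,
                               seed = 1L) {
  if (n_targets < 3) stop("n_targets must be >= 3")
  if (abs(rho_density) > 1 || abs(rho_caliber) > 1) stop("|rho| must be <= 1")
  set.seed(seed)
  pair <- function(rho) {
    z1 <- stats::rnorm(n_targets)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_targets)
    cbind(z1, z2)
  }
  zd <- pair(rho_density)
  zc <- pair(rho_caliber)
  clip <- function(x) pmax(x, 0.01)
  n3 <- round(grade_fraction_iii * n_targets)
  grade <- sample(rep(c("III", "IV"), c(n3, n_targets - n3)))
  tibble::tibble(
    target = seq_len(n_targets),
    grade = grade,
    rcbv = clip(means$rcbv + sds$rcbv * zd[, 1]),
    density = clip(means$density + sds$density * zd[, 2]),
    vsi_mri = clip(means$vsi_mri + sds$vsi_mri * zc[, 1]),
    vsi_histo = clip(means$vsi_histo + sds$vsi_histo * zc[, 2]),
    z_rcbv = zd[, 1], z_density = zd[, 2],
    z_vsi_mri = zc[, 1], z_vsi_histo = zc[, 2]
  )
}
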