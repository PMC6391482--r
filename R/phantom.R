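#' Digital phantom specification for the SAGE simulator
#'
#' Describes a labelled 3-D grid (tumor / normal-appearing white matter /
#' background) together with per-class ground-truth parameters of the
#' four-echo SAGE signal model: proton-density signal `S0`, slice-profile
#' factor `delta` (the multiplicative residual between the pre- and
#' post-refocusing echo trains), baseline transverse relaxation rates
#' `R2*` and `R2` in ms^-1, bolus-induced peak changes of those rates,
#' apparent diffusion coefficient in um^2/ms, and a contrast-leakage rate.
#'
#' Default class values follow the study conditions the pipeline is meant to
#' emulate: tumor ADC 1.30 um^2/ms, tumor peak dR2* 1.39x the white-matter
#' peak (so the normalized rCBV of the tumor class is 1.39), and a tumor
#' peak-dR2 chosen so the class ground-truth vessel size index is 13.67 um.
#'
#' @param grid_shape Integer length-3 vector of voxels, e.g. `c(32, 32, 8)`.
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @param classes Data frame with one row per tissue class and columns
#'   `class`, `s0`, `delta`, `r2star0`, `r20` (ms^-1), `peak_dr2star`,
#'   `peak_dr2` (ms^-1), `adc` (um^2/ms), `leakage_rate`.
#' @param labels Optional integer array of `grid_shape` with values indexing
#'   rows of `classes`; if `NULL` a concentric layout is built (background
#'   shell, NAWM body, central tumor block).
#' @param noise_sigma Additive Gaussian noise SD in signal units (>= 0).
#' @param seed Integer seed for the noise stream.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 8),
                         voxel_size = c(1.875, 1.875, 5),
                         classes = phantom_classes(),
                         labels = NULL,
                         noise_sigma = 0,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            noise_sigma >= 0)
  req <- c("class", "s0", "delta", "r2star0", "r20",
           "peak_dr2star", "peak_dr2", "adc", "leakage_rate")
  if (!all(req %in% names(classes))) {
    stop("classes must have columns: ", paste(req, collapse = ", "))
  }
  if (any(classes$delta < 1)) stop("delta must be >= 1 for every class")
  if (any(classes$s0 <= 0) || any(classes$r2star0 <= 0) || any(classes$r20 <= 0)) {
    stop("S0 and baseline rates must be > 0")
  }
  if (any(classes$peak_dr2star < classes$peak_dr2)) {
    stop("peak_dr2star must be >= peak_dr2 (gradient-echo effect >= spin-echo)")
  }
  if (is.null(labels)) labels <- default_phantom_labels(grid_shape, classes$class)
  stopifnot(all(dim(labels) == grid_shape),
            all(labels >= 1), all(labels <= nrow(classes)))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 classes = tibble::as_tibble(classes),
                 labels = labels,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-class ground-truth table
#'
#' Tumor peak rates are scaled 1.39x relative to NAWM so that the
#' NAWM-normalized rCBV of the tumor class is 1.39; the tumor peak dR2 is
#' set so the tumor ground-truth VSI (0.867 * sqrt(rCBV * ADC) *
#' dR2* / dR2^{3/2}) equals 13.67 um.
#'
#' @param tumor_vsi Target ground-truth tumor VSI in um.
#' @param tumor_rcbv Tumor-to-NAWM peak-dR2* (and hence rCBV) ratio.
#' @param tumor_adc Tumor ADC in um^2/ms.
#' @param tumor_leakage Tumor leakage rate (a.u. of accumulated bolus -> ms^-1).
#' @return A tibble with one row per class; row order is background, nawm,
#'   tumor.
#' @export
phantom_classes <- function(tumor_vsi = 13.67, tumor_rcbv = 1.39,
                            tumor_adc = 1.30, tumor_leakage = 0) {
  nawm_peak_s <- 0.010                      # ms^-1, plausible 3T first pass
  tumor_peak_s <- tumor_rcbv * nawm_peak_s
  # invert the VSI formula for the tumor peak dR2
  tumor_peak_se <- (0.867 * sqrt(tumor_rcbv * tumor_adc) * tumor_peak_s /
                      tumor_vsi)^(2 / 3)
  tibble::tibble(
    class        = c("background", "nawm", "tumor"),
    s0           = c(50, 1000, 1200),
    delta        = c(1.0, 1.05, 1.05),
    r2star0      = c(0.001, 0.020, 0.022),  # ms^-1
    r20          = c(0.001, 0.012, 0.013),  # ms^-1
    peak_dr2star = c(0, nawm_peak_s, tumor_peak_s),
    peak_dr2     = c(0, nawm_peak_s / 1.25, tumor_peak_se),
    adc          = c(3.0, 0.80, tumor_adc), # um^2/ms (background ~ fluid)
    leakage_rate = c(0, 0, tumor_leakage)
  )
}

# background shell 2 voxels thick in-plane, tumor block in the grid centre
default_phantom_labels <- function(grid_shape, class_names) {
  lab <- array(match("nawm", class_names), dim = grid_shape)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  bg <- match("background", class_names)
  lab[c(1:2, (nx - 1):nx), , ] <- bg
  lab[, c(1:2, (ny - 1):ny), ] <- bg
  tx <- seq.int(max(3, floor(nx * 0.35)), min(nx - 2, ceiling(nx * 0.65)))
  ty <- seq.int(max(3, floor(ny * 0.35)), min(ny - 2, ceiling(ny * 0.65)))
  tz <- seq.int(max(1, floor(nz * 0.3)), min(nz, ceiling(nz * 0.7)))
  lab[tx, ty, tz] <- match("tumor", class_names)
  lab
}

#' Simulate a four-echo SAGE-EPI DSC acquisition
#'
#' Evaluates the exact four-echo forward model per voxel and timepoint with
#' time-varying rates `R2*(t) = R2*_0 + dR2*(t)` and `R2(t) = R2_0 + dR2(t)`,
#' where the bolus-induced changes are the class peak values scaled by a
#' shared gamma-variate bolus (so the dR2*/dR2 ratio of a class is constant
#' over the bolus and its ground-truth VSI is well defined). A leaky class
#' additionally accumulates `leakage_rate` times the back-flux-decayed bolus
#' integral on its dR2* curve. Gaussian noise of SD `noise_sigma` is added
#' per echo sample.
#'
#' The four echoes follow the log-linear model: the two gradient echoes decay
#' as `S0 exp(-TE R2*)`; the asymmetric spin echo as
#' `(S0/delta) exp((TE3 - TE4) R2* + (TE4 - 2 TE3) R2)`; the spin echo as
#' `(S0/delta) exp(-TE4 R2)`.
#'
#' @param phantom A [phantom_spec()].
#' @param bolus A [bolus_model()].
#' @param echo_times Four echo times in ms, strictly increasing
#'   (default `c(14.0, 34.1, 58.0, 92.4)`).
#' @param tr Repetition time in ms (default 2000).
#' @param n_timepoints Number of repetitions (default 90).
#' @param leak_back_rate Back-flux decay rate of the leakage kernel, s^-1.
#'
#' @return A list with `signal` (array `echo x time x nx x ny x nz`),
#'   `echo_times`, `time_axis` (s) and `truth` — a list carrying the bolus
#'   curve, per-class `dr2star_t`/`dr2_t` matrices (class x time, the
#'   vascular terms without leakage), leakage terms, per-voxel parameter maps
#'   and per-class ground-truth VSI and dR2* integrals.
#' @export
simulate_sage_dataset <- function(phantom, bolus,
                                  echo_times = c(14.0, 34.1, 58.0, 92.4),
                                  tr = 2000, n_timepoints = 90,
                                  leak_back_rate = 0.01) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(bolus, "bolus_model"))
  tes <- echo_times(echo_times)
  nt <- as.integer(n_timepoints)
  stopifnot(nt >= 2)
  time_axis <- (seq_len(nt) - 1) * tr / 1000  # seconds
  curve <- gamma_variate_bolus(time_axis, bolus)
  # back-flux-decayed accumulated bolus (units a.u. * s), trapezoid kernel sum
  dt <- tr / 1000
  leak_term <- decayed_cumsum(curve, dt, leak_back_rate)

  cls <- phantom$classes
  ncl <- nrow(cls)
  dr2star_t <- outer(cls$peak_dr2star, curve)        # class x time, ms^-1
  dr2_t <- outer(cls$peak_dr2, curve)
  dr2star_obs <- dr2star_t + outer(cls$leakage_rate, leak_term)

  # class x time rate matrices
  r2star_ct <- sweep(dr2star_obs, 1, cls$r2star0, `+`)
  r2_ct <- sweep(dr2_t, 1, cls$r20, `+`)

  # signal per class/echo/time via the forward model, then scatter to voxels
  grid <- phantom$grid_shape
  nvox <- prod(grid)
  sig <- array(0, dim = c(4L, nt, grid))
  lab_vec <- as.integer(phantom$labels)
  for (k in seq_len(ncl)) {
    sk <- sage_forward(cls$s0[k], cls$delta[k], r2star_ct[k, ], r2_ct[k, ], tes)
    idx <- which(lab_vec == k)
    if (!length(idx)) next
    # sig dims: 4 x nt x nvox (flattened); assign class block
    dim(sig) <- c(4L, nt, nvox)
    sig[, , idx] <- array(sk, dim = c(4L, nt, length(idx)))
    dim(sig) <- c(4L, nt, grid)
  }
  if (phantom$noise_sigma > 0) {
    set.seed(phantom$seed)
    sig <- sig + array(stats::rnorm(length(sig), 0, phantom$noise_sigma),
                       dim = dim(sig))
  }

  class_maps <- function(v) array(v[lab_vec], dim = grid)
  vsi_class <- 0.867 * sqrt((cls$peak_dr2star / cls$peak_dr2star[cls$class == "nawm"]) *
                              cls$adc) *
    ifelse(cls$peak_dr2 > 0, cls$peak_dr2star / cls$peak_dr2^1.5, NA_real_)
  truth <- list(
    time_axis = time_axis,
    bolus_curve = curve,
    leak_term = leak_term,
    classes = cls,
    labels = phantom$labels,
    dr2star_t = dr2star_t,
    dr2_t = dr2_t,
    dr2star_obs = dr2star_obs,
    dr2star_integral = as.numeric(dr2star_t %*% rep(dt, nt)) -
      dt / 2 * (dr2star_t[, 1] + dr2star_t[, nt]),
    vsi_class = vsi_class,
    s0_map = class_maps(cls$s0),
    delta_map = class_maps(cls$delta),
    r2star0_map = class_maps(cls$r2star0),
    r20_map = class_maps(cls$r20),
    adc_map = class_maps(cls$adc)
  )
  list(signal = sig, echo_times = tes, tr = tr, time_axis = time_axis,
       truth = truth)
}

# forward model for one parameter set over a rate time course -> 4 x nt
sage_forward <- function(s0, delta, r2star_t, r2_t, tes) {
  rbind(s0 * exp(-tes$te1 * r2star_t),
        s0 * exp(-tes$te2 * r2star_t),
        (s0 / delta) * exp((tes$te3 - tes$te4) * r2star_t +
                             (tes$te4 - 2 * tes$te3) * r2_t),
        (s0 / delta) * exp(-tes$te4 * r2_t))
}

# cumulative \int_0^t f(tau) exp(-k (t - tau)) dtau on a uniform grid
decayed_cumsum <- function(f, dt, k) {
  n <- length(f)
  out <- numeric(n)
  decay <- exp(-k * dt)
  for (i in 2:n) {
    out[i] <- out[i - 1] * decay + dt / 2 * (f[i] + f[i - 1] * decay)
  }
  out
}

#' Simulate a multi-b diffusion-weighted acquisition
#'
#' Monoexponential forward model `S(b) = S0 exp(-b * ADC)` with ADC given in
#' um^2/ms and b in s/mm^2 (1 um^2/ms = 1e-3 mm^2/s, so the exponent is
#' `-b * adc * 1e-3`), plus additive Gaussian noise.
#'
#' @param adc_map 3-D array of ADC in um^2/ms.
#' @param s0_map 3-D array of b=0 signal (a.u.), same shape.
#' @param b_values Non-negative b-values in s/mm^2, must include 0
#'   (default `c(0, 500, 1000)`).
#' @param noise_sigma Gaussian noise SD in signal units.
#' @param seed Integer seed.
#'
#' @return Array `b x nx x ny x nz` plus attribute `b_values`.
#' @export
simulate_dwi <- function(adc_map, s0_map, b_values = c(0, 500, 1000),
                         noise_sigma = 0, seed = 1L) {
  stopifnot(all(dim(adc_map) == dim(s0_map)), noise_sigma >= 0)
  if (any(b_values < 0)) stop("b-values must be non-negative")
  if (!any(b_values == 0)) stop("b-values must include b = 0")
  nb <- length(b_values)
  dims <- dim(adc_map)
  out <- array(0, dim = c(nb, dims))
  flat_s0 <- as.numeric(s0_map)
  flat_adc <- as.numeric(adc_map)
  dim(out) <- c(nb, prod(dims))
  for (i in seq_len(nb)) {
    out[i, ] <- flat_s0 * exp(-b_values[i] * flat_adc * 1e-3)
  }
  dim(out) <- c(nb, dims)
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- out + array(stats::rnorm(length(out), 0, noise_sigma), dim = dim(out))
  }
  attr(out, "b_values") <- b_values
  out
}
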