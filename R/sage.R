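#' Echo-time set of a SAGE-EPI readout
#'
#' Four echo times in ms: two gradient echoes, an asymmetric spin echo and
#' the spin echo. The asymmetric spin echo must fall after the
#' refocusing-symmetric midpoint, i.e. `te3 > te4 / 2`, so the `te4 - 2*te3`
#' coefficient of the signal model is negative (true for the default
#' acquisition 14.0 / 34.1 / 58.0 / 92.4 ms).
#'
#' @param tes Numeric vector of 4 echo times in ms, strictly increasing.
#' @return An object of class `echo_times` with elements `te1`..`te4`.
#' @export
echo_times <- function(tes = c(14.0, 34.1, 58.0, 92.4)) {
  if (inherits(tes, "echo_times")) return(tes)
  if (length(tes) != 4) stop("exactly 4 echo times are required")
  if (any(diff(tes) <= 0) || tes[1] <= 0) {
    stop("echo times must be positive and strictly increasing")
  }
  if (tes[3] <= tes[4] / 2) {
    stop("te3 must exceed te4/2 (asymmetric spin echo after the midpoint)")
  }
  structure(list(te1 = tes[1], te2 = tes[2], te3 = tes[3], te4 = tes[4]),
            class = "echo_times")
}

#' Coefficient matrix of the four-echo SAGE log-signal model
#'
#' Builds the 4x4 matrix `Y` linking the parameter vector
#' `A = (ln S0, ln delta, R2*, R2)` to the log-signals
#' `S = (ln S1, ..., ln S4)` via `Y A = S`. Rows:
#' `(1, 0, -TE1, 0)`, `(1, 0, -TE2, 0)`,
#' `(1, -1, TE3 - TE4, TE4 - 2*TE3)`, `(1, -1, 0, -TE4)`.
#' The matrix is invertible for any valid echo-time set, so the per-voxel
#' fit is an exactly determined linear solve, not a least-squares problem.
#'
#' @param tes An [echo_times()] object or a numeric vector of 4 TEs in ms.
#' @return 4x4 numeric matrix with attribute `te_units = "ms"`.
#' @export
sage_design_matrix <- function(tes) {
  tes <- echo_times(tes)
  y <- rbind(c(1, 0, -tes$te1, 0),
             c(1, 0, -tes$te2, 0),
             c(1, -1, -tes$te4 + tes$te3, tes$te4 - 2 * tes$te3),
             c(1, -1, 0, -tes$te4))
  if (abs(det(y)) < 1e-12) stop("singular SAGE design matrix")  # cannot occur
  attr(y, "te_units") <- "ms"
  y
}

#' Invert the SAGE model for a single voxel
#'
#' Solves `A = Y^-1 S` for one 4-echo signal vector and exponentiates the
#' first two components.
#'
#' @param signals Numeric vector of 4 positive signal magnitudes (a.u.).
#' @param tes Echo times ([echo_times()] or numeric 4-vector, ms).
#' @return A list of class `sage_fit`: `s0` (a.u.), `delta`
#'   (dimensionless), `r2star`, `r2` (ms^-1), and `delta_flagged` (TRUE when
#'   delta falls outside the plausible [0.8, 1.5] band).
#' @export
fit_sage_voxel <- function(signals, tes) {
  stopifnot(length(signals) == 4)
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    return(structure(list(s0 = NA_real_, delta = NA_real_, r2star = NA_real_,
                          r2 = NA_real_, delta_flagged = NA), class = "sage_fit"))
  }
  a <- solve(sage_design_matrix(tes), log(signals))
  delta <- exp(a[2])
  structure(list(s0 = exp(a[1]), delta = delta, r2star = a[3], r2 = a[4],
                 delta_flagged = delta < 0.8 || delta > 1.5),
            class = "sage_fit")
}

#' Invert the SAGE model over a full time series
#'
#' Vectorised per-voxel, per-timepoint linear inversion of a 5-D stack
#' (echo x time x volume). Voxels with any non-positive or non-finite signal
#' at a timepoint are marked invalid at that timepoint (NA in every output
#' map) rather than raising an error.
#'
#' @param stack Array `4 x time x nx x ny x nz` (or `4 x time x n` for a
#'   voxel list).
#' @param tes Echo times in ms.
#' @param mask Optional logical array over the spatial dimensions; voxels
#'   outside the mask are skipped (NA outputs).
#' @return A list of class `sage_series`: arrays `s0`, `delta`, `r2star`,
#'   `r2` of shape `time x <spatial>`, the logical `valid` array of the same
#'   shape, `invalid_fraction` (share of in-mask voxel-timepoints that could
#'   not be fitted) and `delta_variation` (per-voxel max percent variation of
#'   delta over time, a slice-profile stability diagnostic).
#' @export
fit_sage_series <- function(stack, tes, mask = NULL) {
  d <- dim(stack)
  if (is.null(d) || d[1] != 4) stop("stack must be echo x time x volume with 4 echoes")
  nt <- d[2]
  spatial <- d[-(1:2)]
  nvox <- prod(spatial)
  yinv <- solve(sage_design_matrix(tes))

  dim(stack) <- c(4L, nt * nvox)
  ok <- colSums(is.finite(stack) & stack > 0) == 4L
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == spatial) || length(mask) == nvox)
    ok <- ok & rep(as.logical(mask), each = nt)
  }
  a <- matrix(NA_real_, 4, nt * nvox)
  if (any(ok)) a[, ok] <- yinv %*% log(stack[, ok, drop = FALSE])

  shape <- c(nt, spatial)
  out <- list(
    s0 = array(exp(a[1, ]), dim = shape),
    delta = array(exp(a[2, ]), dim = shape),
    r2star = array(a[3, ], dim = shape),
    r2 = array(a[4, ], dim = shape),
    valid = array(ok, dim = shape)
  )
  in_mask <- if (is.null(mask)) rep(TRUE, nt * nvox) else rep(as.logical(mask), each = nt)
  out$invalid_fraction <- if (any(in_mask)) mean(!ok[in_mask]) else 0
  # delta stability: max |delta - median| / median per voxel, percent
  dm <- matrix(a[2, ], nt, nvox)
  dvar <- apply(dm, 2, function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 2) return(NA_real_)
    m <- stats::median(exp(z))
    100 * max(abs(exp(z) - m)) / m
  })
  out$delta_variation <- if (length(spatial) > 1) array(dvar, dim = spatial) else dvar
  out$tes <- echo_times(tes)
  class(out) <- "sage_series"
  out
}

#' Baseline-referenced relaxation-rate change curves and their peaks
#'
#' Subtracts the pre-bolus baseline mean from the fitted `R2*(t)` and
#' `R2(t)` series and extracts per-voxel peak changes. If no baseline window
#' is given, bolus arrival is detected on the volume-mean `R2*(t)` curve as
#' the first timepoint exceeding the provisional baseline mean by 5 baseline
#' SDs; the window is then timepoints 5 to (arrival - 3). On a series with
#' no detectable bolus the whole series is the baseline. Peaks are the
#' maxima of the (optionally 3-point moving-average smoothed) change curves;
#' voxels whose peak is negative are marked invalid rather than clipped to
#' zero, to avoid fake zero-caliber voxels downstream.
#'
#' @param series A `sage_series` from [fit_sage_series()].
#' @param baseline_window Optional integer vector of timepoint indices; must
#'   have length >= 3 and must not contain the bolus peak.
#' @param smooth Logical, apply 3-point moving-average smoothing before peak
#'   extraction (default TRUE).
#' @return A list of class `relaxogram`: `d_r2star_t`, `d_r2_t`
#'   (time x spatial), `d_r2star_max`, `d_r2_max` (spatial), `peak_valid`,
#'   `baseline_window`.
#' @export
delta_curves <- function(series, baseline_window = NULL, smooth = TRUE) {
  stopifnot(inherits(series, "sage_series"))
  shape <- dim(series$r2star)
  nt <- shape[1]
  spatial <- shape[-1]
  r2s <- matrix(series$r2star, nt)
  r2 <- matrix(series$r2, nt)

  gmean <- rowMeans(r2s, na.rm = TRUE)
  if (is.null(baseline_window)) {
    nb <- max(3L, min(8L, nt %/% 4L))
    base_mean <- mean(gmean[seq_len(nb)], na.rm = TRUE)
    base_sd <- stats::sd(gmean[seq_len(nb)], na.rm = TRUE)
    thr <- base_mean + 5 * max(base_sd, .Machine$double.eps)
    arrival <- which(gmean > thr)[1]
    if (is.na(arrival)) {
      baseline_window <- seq_len(nt)  # no bolus: whole series is baseline
    } else {
      start <- min(5L, nt)
      end <- arrival - 3L
      if (end - start + 1L < 3L) {
        stop("detected bolus arrival too early for a >= 3-point baseline; ",
             "supply baseline_window explicitly")
      }
      baseline_window <- seq.int(start, end)
    }
  }
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) < 3 || any(baseline_window < 1) ||
      any(baseline_window > nt)) {
    stop("baseline window must contain >= 3 valid timepoints")
  }
  peak_at <- which.max(gmean - mean(gmean[baseline_window], na.rm = TRUE))
  if (max(gmean, na.rm = TRUE) - mean(gmean[baseline_window], na.rm = TRUE) >
      1e-12 * max(1, abs(mean(gmean[baseline_window], na.rm = TRUE))) &&
      peak_at %in% baseline_window) {
    warning("baseline window overlaps the bolus peak; refusing")
    stop("baseline window overlaps the bolus peak")
  }

  d_r2s <- sweep(r2s, 2, colMeans(r2s[baseline_window, , drop = FALSE], na.rm = TRUE), `-`)
  d_r2 <- sweep(r2, 2, colMeans(r2[baseline_window, , drop = FALSE], na.rm = TRUE), `-`)

  peak_of <- function(m) {
    if (smooth && nt >= 3) m <- apply(m, 2, smooth3)
    suppressWarnings(apply(m, 2, max, na.rm = TRUE))
  }
  pk_s <- peak_of(d_r2s)
  pk_se <- peak_of(d_r2)
  pk_s[!is.finite(pk_s)] <- NA_real_
  pk_se[!is.finite(pk_se)] <- NA_real_
  valid <- is.finite(pk_s) & is.finite(pk_se) & pk_s >= 0 & pk_se >= 0
  pk_s[!valid] <- NA_real_
  pk_se[!valid] <- NA_real_

  shp <- function(v, d) if (length(d) > 1) array(v, dim = d) else v
  structure(list(
    d_r2star_t = array(d_r2s, dim = shape),
    d_r2_t = array(d_r2, dim = shape),
    d_r2star_max = shp(pk_s, spatial),
    d_r2_max = shp(pk_se, spatial),
    peak_valid = shp(valid, spatial),
    baseline_window = baseline_window
  ), class = "relaxogram")
}

# centred 3-point moving average, endpoints kept
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}
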