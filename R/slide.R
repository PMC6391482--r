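#' Synthetic stained-slide specification
#'
#' Describes a rendered RGB histology field emulating an endothelium-stained
#' (e.g. CD31 with a red-brown chromogen) section: vessels drawn as stained
#' endothelial rings around paler lumens, counterstained nuclei blobs, and a
#' pale background tint — the three-hue structure a hue-based segmenter
#' relies on.
#'
#' When `vessel_radii` is `NULL`, radii are drawn from a lognormal
#' distribution (meanlog `log(12.6) - (5/3) * 0.3^2`, sdlog 0.3, truncated to
#' 3–30 um) whose expected cylinder-model vessel size index is 12.6 um, the
#' condition the renderer emulates; with the default 1 mm^2 field and 41
#' vessels the expected density is 41 /mm^2.
#'
#' @param image_shape Height, width in px.
#' @param um_per_px Micrometres per pixel (> 0).
#' @param vessel_radii Optional explicit radii (um); recycled/truncated to
#'   `vessel_count_target` if lengths differ.
#' @param vessel_count_target Number of vessels to place.
#' @param lumen_fraction Lumen radius as a fraction of the vessel radius.
#' @param stain_hue_vessel,stain_hue_nuclei,stain_hue_background HSV triples
#'   (h, s, v in [0, 1]).
#' @param nuclei_density Nuclei per mm^2.
#' @param allow_overlap Allow vessels to overlap (default FALSE).
#' @param oblique Render oblique elliptical sections (default FALSE; the
#'   cylinder-orientation correction is handled analytically downstream).
#' @param noise_sd SD of Gaussian brightness noise added to the V channel.
#' @param seed Integer seed.
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(image_shape = c(1000, 1000),
                       um_per_px = 1.0,
                       vessel_radii = NULL,
                       vessel_count_target = 41,
                       lumen_fraction = 0.6,
                       stain_hue_vessel = c(0.03, 0.75, 0.45),
                       stain_hue_nuclei = c(0.65, 0.55, 0.50),
                       stain_hue_background = c(0.08, 0.12, 0.93),
                       nuclei_density = 800,
                       allow_overlap = FALSE,
                       oblique = FALSE,
                       noise_sd = 0.005,
                       seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16), um_per_px > 0,
            vessel_count_target >= 0, lumen_fraction > 0, lumen_fraction < 1,
            nuclei_density >= 0, noise_sd >= 0)
  if (!is.null(vessel_radii) && any(vessel_radii <= 0)) {
    stop("vessel radii must be > 0")
  }
  structure(list(image_shape = as.integer(image_shape), um_per_px = um_per_px,
                 vessel_radii = vessel_radii,
                 vessel_count_target = as.integer(vessel_count_target),
                 lumen_fraction = lumen_fraction,
                 stain_hue_vessel = stain_hue_vessel,
                 stain_hue_nuclei = stain_hue_nuclei,
                 stain_hue_background = stain_hue_background,
                 nuclei_density = nuclei_density,
                 allow_overlap = allow_overlap, oblique = oblique,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "slide_spec")
}

hsv_to_rgb <- function(hsv) as.numeric(grDevices::col2rgb(
  grDevices::hsv(hsv[1], hsv[2], hsv[3]))) / 255

#' Render a synthetic stained slide with known vessel truth
#'
#' Places the requested vessels as non-overlapping circular cross-sections
#' (rejection sampling with a 2 px separation margin), draws each as a
#' stained endothelial ring around a paler lumen, scatters counterstained
#' nuclei, and tints the background. Fails explicitly — never by silent
#' truncation — if the requested vessels cannot be packed into the field.
#'
#' @param spec A [slide_spec()].
#' @return A list of class `rendered_slide`: `image` (H x W x 3 array in
#'   [0, 1]), `truth` (tibble: id, cy_px, cx_px, radius_um, radius_px,
#'   area_um2), `truth_summary` (count, density per mm^2, vsi_histo um from
#'   the exact truth radii), `field_area_mm2`, `um_per_px`, `spec`.
#' @export
render_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  set.seed(spec$seed)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  n <- spec$vessel_count_target
  radii_um <- if (is.null(spec$vessel_radii)) {
    if (n > 0) draw_radii(n) else numeric(0)
  } else {
    rep_len(spec$vessel_radii, n)
  }
  radii_px <- radii_um / spec$um_per_px

  # packing feasibility: total padded disk area must stay below 35% of field
  if (n > 0) {
    pad <- radii_px + 2
    if (!spec$allow_overlap && sum(pi * pad^2) > 0.35 * h * w) {
      stop("impossible packing: requested vessels exceed the packing bound")
    }
    if (any(2 * radii_px + 4 > min(h, w))) {
      stop("impossible packing: a vessel does not fit in the field")
    }
  }

  centers <- place_disks(h, w, radii_px, spec$allow_overlap)

  bg <- hsv_to_rgb(spec$stain_hue_background)
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3))

  # nuclei: small stained blobs, Poisson count from density
  area_mm2 <- h * w * spec$um_per_px^2 / 1e6
  n_nuc <- stats::rpois(1, spec$nuclei_density * area_mm2)
  nuc_col <- hsv_to_rgb(spec$stain_hue_nuclei)
  if (n_nuc > 0) {
    ny <- stats::runif(n_nuc, 1, h); nx <- stats::runif(n_nuc, 1, w)
    nr <- pmax(1.5, stats::rnorm(n_nuc, 3 / spec$um_per_px, 0.5))
    for (i in seq_len(n_nuc)) {
      img <- paint_disk(img, ny[i], nx[i], nr[i], nuc_col)
    }
  }

  # vessels: stained wall ring + pale lumen (drawn after nuclei so nuclei
  # never occlude a vessel wall)
  wall_col <- hsv_to_rgb(spec$stain_hue_vessel)
  lum <- spec$stain_hue_background
  lumen_col <- hsv_to_rgb(c(lum[1], lum[2] * 0.3, min(1, lum[3] + 0.05)))
  ecc <- if (spec$oblique) 1 / cos(stats::runif(n, 0, pi / 4)) else rep(1, n)
  ang <- stats::runif(max(n, 1), 0, pi)
  for (i in seq_len(n)) {
    r_out <- radii_px[i]
    r_in <- max(r_out * spec$lumen_fraction, r_out - max(2, 0.4 * r_out))
    img <- paint_disk(img, centers[i, 1], centers[i, 2], r_out, wall_col,
                      ecc = ecc[i], theta = ang[i])
    img <- paint_disk(img, centers[i, 1], centers[i, 2], r_in, lumen_col,
                      ecc = ecc[i], theta = ang[i])
  }

  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }

  truth <- tibble::tibble(
    id = seq_len(n),
    cy_px = if (n) centers[, 1] else numeric(0),
    cx_px = if (n) centers[, 2] else numeric(0),
    radius_um = radii_um,
    radius_px = radii_px,
    area_um2 = pi * radii_um^2
  )
  structure(list(
    image = img,
    truth = truth,
    truth_summary = list(count = n,
                         density = n / area_mm2,
                         vsi_histo = vsi_from_radii(radii_um)),
    field_area_mm2 = area_mm2,
    um_per_px = spec$um_per_px,
    spec = spec
  ), class = "rendered_slide")
}

# lognormal radii calibrated so the expected cylinder-model VSI is 12.6 um
draw_radii <- function(n) {
  mu <- log(12.6) - (5 / 3) * 0.3^2
  r <- stats::rlnorm(n, mu, 0.3)
  pmin(pmax(r, 3), 30)
}

# rejection-sample non-overlapping disk centres (2 px margin)
place_disks <- function(h, w, radii_px, allow_overlap, max_tries = 400) {
  n <- length(radii_px)
  centers <- matrix(0, n, 2)
  if (!n) return(centers)
  ord <- order(radii_px, decreasing = TRUE)   # place large vessels first
  for (k in seq_len(n)) {
    i <- ord[k]
    r <- radii_px[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cy <- stats::runif(1, r + 2, h - r - 1)
      cx <- stats::runif(1, r + 2, w - r - 1)
      if (allow_overlap || k == 1) {
        ok <- TRUE
      } else {
        prev <- ord[seq_len(k - 1)]
        ok <- all(sqrt((centers[prev, 1] - cy)^2 + (centers[prev, 2] - cx)^2) >
                    radii_px[prev] + r + 2)
      }
      if (ok) { centers[i, ] <- c(cy, cx); placed <- TRUE; break }
    }
    if (!placed) stop("impossible packing: could not place vessel ", i,
                      " after ", max_tries, " attempts")
  }
  centers
}

# paint a filled (possibly elliptical) disk into an RGB array
paint_disk <- function(img, cy, cx, r, col, ecc = 1, theta = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rmax <- r * max(ecc, 1)
  ys <- max(1, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  xs <- max(1, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- ys - cy
  dx <- xs - cx
  u <- outer(dy, xs * 0) + dy            # H' x W' of dy
  v <- t(outer(dx, ys * 0) + dx)         # H' x W' of dx
  if (ecc != 1) {
    a <- u * cos(theta) + v * sin(theta)
    b <- -u * sin(theta) + v * cos(theta)
    inside <- (a / (r * ecc))^2 + (b / r)^2 <= 1
  } else {
    inside <- u^2 + v^2 <= r^2
  }
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx)) {
    for (ch in 1:3) {
      img[cbind(ys[idx[, 1]], xs[idx[, 2]], ch)] <- col[ch]
    }
  }
  img
}
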