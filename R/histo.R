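#' Default HSV hue model for stained-slide segmentation
#'
#' Hue / saturation / value gates for the three classes a stained section
#' exhibits: stained endothelium (red-brown chromogen), counterstained
#' nuclei, and pale background. `tolerance` widens the vessel hue window and
#' relaxes the saturation gate during region growing.
#'
#' @param vessel_hue,nuclei_hue Length-2 hue windows in [0, 1].
#' @param vessel_s_min Minimum saturation of a vessel seed pixel.
#' @param vessel_v_max Maximum value (brightness) of a vessel seed pixel.
#' @param tolerance Hue widening / saturation relaxation for region growing.
#' @return A list of class `hue_model`.
#' @export
hue_model <- function(vessel_hue = c(0.00, 0.07), vessel_s_min = 0.45,
                      vessel_v_max = 0.75, nuclei_hue = c(0.55, 0.75),
                      tolerance = 0.03) {
  if (max(vessel_hue) >= min(nuclei_hue) && min(vessel_hue) <= max(nuclei_hue)) {
    stop("vessel and nuclei hue ranges must not overlap")
  }
  structure(list(vessel_hue = vessel_hue, vessel_s_min = vessel_s_min,
                 vessel_v_max = vessel_v_max, nuclei_hue = nuclei_hue,
                 tolerance = tolerance), class = "hue_model")
}

#' Segment stained vessels from an RGB slide image
#'
#' Seed-and-grow segmentation in HSV colour space: pixels inside the vessel
#' hue/saturation/value gates become seeds; a relaxed gate (hue window
#' widened by `tolerance`, saturation threshold lowered) defines the
#' growable region; connected components of the relaxed region that contain
#' at least one seed are kept and labelled. Components smaller than
#' `min_object_px` are discarded as stain debris.
#'
#' @param image H x W x 3 RGB array in [0, 1] (or 8/16-bit integers,
#'   rescaled automatically).
#' @param model A [hue_model()].
#' @param min_object_px Minimum object area in px (default 5).
#' @return Integer H x W label matrix (0 = background), with the seed mask
#'   attached as attribute `seeds`.
#' @export
segment_vessels <- function(image, model = hue_model(), min_object_px = 5) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an H x W x 3 RGB array")
  }
  if (prod(dim(image)) == 0) stop("empty image")
  if (max(image) > 1) image <- image / ifelse(max(image) > 255, 65535, 255)
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(rbind(as.numeric(image[, , 1]),
                                  as.numeric(image[, , 2]),
                                  as.numeric(image[, , 3])), maxColorValue = 1)
  hue <- matrix(hsv[1, ], h, w)
  sat <- matrix(hsv[2, ], h, w)
  val <- matrix(hsv[3, ], h, w)
  if (max(sat) < 0.05) {
    stop("degenerate hue model: image has no colour separation (grayscale?)")
  }
  in_hue <- function(x, rng) x >= rng[1] & x <= rng[2]
  seeds <- in_hue(hue, model$vessel_hue) & sat >= model$vessel_s_min &
    val <= model$vessel_v_max
  grow_rng <- c(max(0, model$vessel_hue[1] - model$tolerance),
                min(1, model$vessel_hue[2] + model$tolerance))
  grow <- in_hue(hue, grow_rng) & sat >= model$vessel_s_min * 0.5 &
    val <= min(1, model$vessel_v_max + 0.1)
  if (all(grow)) stop("degenerate hue model: every pixel is a vessel candidate")
  lab <- EBImage::bwlabel(grow)
  keep <- sort(unique(lab[seeds & lab > 0]))
  if (length(keep)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- keep[sizes[keep] >= min_object_px]
  }
  out <- matrix(0L, h, w)
  if (length(keep)) {
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0 & lab %in% keep
    out[pos] <- remap[lab[pos]]
  }
  attr(out, "seeds") <- seeds
  out
}

#' Morphological refinement of a vessel label image
#'
#' Applies the four refinement tasks in order: (1) *join* — objects whose
#' boundary gap is at most `join_distance_um` are merged (dilation by half
#' the gap, relabel, map back); (2) *close* — morphological closing with a
#' disc of `closing_radius_px` seals narrow peripheral gaps so lumens become
#' true holes; (3) *split* — objects whose filled mask contains two or more
#' interior lumens larger than `min_lumen_area_px` are divided between the
#' lumens by seeded Voronoi propagation; (4) *hole fill* — lumens are
#' included in each vessel's area so the equivalent radius reflects the full
#' vessel cross-section.
#'
#' @param labels Integer H x W label matrix from [segment_vessels()].
#' @param um_per_px Micrometres per pixel.
#' @param join_distance_um Maximum gap merged in step 1 (default 5 um).
#' @param closing_radius_px Disc radius for step 2 (default 2 px).
#' @param min_lumen_area_px Minimum lumen area to count in step 3
#'   (default 10 px).
#' @return Refined integer label matrix (objects filled).
#' @export
refine_objects <- function(labels, um_per_px = 1,
                           join_distance_um = 5,
                           closing_radius_px = 2,
                           min_lumen_area_px = 10) {
  stopifnot(is.matrix(labels))
  mask <- labels > 0
  if (!any(mask)) return(matrix(0L, nrow(labels), ncol(labels)))

  # (1) join across small gaps: dilate, connect, pull back to original mask
  join_px <- max(1, round(join_distance_um / um_per_px / 2))
  dil <- EBImage::dilate(mask * 1, EBImage::makeBrush(brush_size(join_px), "disc"))
  joined <- EBImage::bwlabel(dil > 0)
  mask_lab <- matrix(as.integer(joined), nrow(labels)) * mask

  # (2) closing seals narrow peripheral gaps
  closed <- EBImage::closing(
    (mask_lab > 0) * 1, EBImage::makeBrush(brush_size(closing_radius_px), "disc"))
  closed <- closed > 0

  # (3)+(4) fill lumens; split multi-lumen objects between their lumens
  filled <- EBImage::fillHull(closed * 1) > 0
  holes <- filled & !closed
  hole_lab <- matrix(as.integer(EBImage::bwlabel(holes * 1)), nrow(labels))
  hole_sizes <- if (max(hole_lab) > 0) tabulate(hole_lab[hole_lab > 0]) else integer(0)
  big_holes <- which(hole_sizes >= min_lumen_area_px)

  obj_lab <- matrix(as.integer(EBImage::bwlabel(filled * 1)), nrow(labels))
  n_obj <- max(obj_lab)
  out <- matrix(0L, nrow(labels), ncol(labels))
  next_id <- 0L
  for (o in seq_len(n_obj)) {
    opix <- obj_lab == o
    lum_ids <- unique(hole_lab[opix & hole_lab > 0])
    lum_ids <- intersect(lum_ids, big_holes)
    if (length(lum_ids) >= 2) {
      seeds <- matrix(0L, nrow(labels), ncol(labels))
      for (j in seq_along(lum_ids)) seeds[hole_lab == lum_ids[j] & opix] <- j
      split <- EBImage::propagate(x = opix * 1, seeds = seeds, mask = opix)
      split <- matrix(as.integer(split), nrow(labels))
      for (j in seq_along(lum_ids)) {
        next_id <- next_id + 1L
        out[split == j] <- next_id
      }
      # propagate covers the whole mask; stray unassigned pixels join the last id
      left <- opix & out == 0L
      if (any(left)) out[left] <- next_id
    } else {
      next_id <- next_id + 1L
      out[opix] <- next_id
    }
  }
  out
}

brush_size <- function(r) {
  s <- 2L * as.integer(r) + 1L
  max(s, 3L)
}

#' Morphometry of a labelled vessel image
#'
#' Per-object equivalent-circle radius `r_i = sqrt(area_i / pi) * um_per_px`,
#' vessel density (count per mm^2 of field), and the cylinder-model vessel
#' size index of the radius set ([vsi_from_radii()]).
#'
#' @param labels Integer H x W label matrix (refined).
#' @param um_per_px Micrometres per pixel.
#' @param field_area_mm2 Field area in mm^2 (default: full image area).
#' @return A list of class `morphometry`: `vessel_count`, `density` (N/mm^2),
#'   `vsi_histo` (um, NA when no vessels), `radii_um`,
#'   `objects` (tibble: label, area_px, area_um2, radius_um, centroid px),
#'   `field_area_mm2`.
#' @export
quantify_vessels <- function(labels, um_per_px,
                             field_area_mm2 = prod(dim(labels)) * um_per_px^2 / 1e6) {
  stopifnot(is.matrix(labels), um_per_px > 0)
  if (field_area_mm2 <= 0) stop("field area must be > 0")
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(structure(list(vessel_count = 0L, density = 0,
                          vsi_histo = NA_real_, radii_um = numeric(0),
                          objects = tibble::tibble(label = integer(0),
                                                   area_px = numeric(0),
                                                   area_um2 = numeric(0),
                                                   radius_um = numeric(0),
                                                   cy_px = numeric(0),
                                                   cx_px = numeric(0)),
                          field_area_mm2 = field_area_mm2),
                     class = "morphometry"))
  }
  area_px <- tabulate(labels[labels > 0])[ids]
  rc <- which(labels > 0, arr.ind = TRUE)
  lv <- labels[labels > 0]
  cy <- tapply(rc[, 1], lv, mean)[as.character(ids)]
  cx <- tapply(rc[, 2], lv, mean)[as.character(ids)]
  radius_um <- sqrt(area_px / pi) * um_per_px
  objects <- tibble::tibble(label = ids, area_px = area_px,
                            area_um2 = area_px * um_per_px^2,
                            radius_um = radius_um,
                            cy_px = as.numeric(cy), cx_px = as.numeric(cx))
  structure(list(vessel_count = length(ids),
                 density = length(ids) / field_area_mm2,
                 vsi_histo = vsi_from_radii(radius_um),
                 radii_um = radius_um,
                 objects = objects,
                 field_area_mm2 = field_area_mm2),
            class = "morphometry")
}

#' Average morphometry over regions of interest
#'
#' Per-target summary: arithmetic mean of density and VSI across the ROIs of
#' one biopsy target (the study protocol averages 3 ROIs per target), with
#' counts summed and radii concatenated for reporting.
#'
#' @param results List of `morphometry` objects (>= 1; 3 in the default
#'   protocol).
#' @param expected_n Expected ROI count (warn when different; default 3).
#' @return A `morphometry`-like list with `n_rois` added.
#' @export
aggregate_rois <- function(results, expected_n = 3) {
  if (length(results) < 1) stop("at least one ROI result is required")
  stopifnot(all(vapply(results, inherits, logical(1), "morphometry")))
  if (length(results) != expected_n) {
    warning("expected ", expected_n, " ROIs, got ", length(results))
  }
  vsis <- vapply(results, function(r) r$vsi_histo, numeric(1))
  structure(list(
    n_rois = length(results),
    vessel_count = sum(vapply(results, function(r) r$vessel_count, integer(1))),
    density = mean(vapply(results, function(r) r$density, numeric(1))),
    vsi_histo = if (all(is.na(vsis))) NA_real_ else mean(vsis, na.rm = TRUE),
    radii_um = unlist(lapply(results, function(r) r$radii_um)),
    field_area_mm2 = sum(vapply(results, function(r) r$field_area_mm2, numeric(1)))
  ), class = "morphometry")
}

#' Select square regions of interest from a slide
#'
#' Draws `n` non-overlapping square tiles uniformly at random (seeded);
#' `hotspot` mode instead ranks candidate tiles by stained-pixel fraction
#' and keeps the densest non-overlapping ones.
#'
#' @param slide A `rendered_slide` or an H x W x 3 RGB array.
#' @param n Number of ROIs (default 3).
#' @param roi_px ROI side length in px (default: one third of the shorter
#'   image side).
#' @param mode `"random"` (default) or `"hotspot"`.
#' @param model Hue model used for hotspot ranking.
#' @param seed Integer seed.
#' @return List of `n` lists: `image` (sub-array), `y0`, `x0` (1-based
#'   offsets), `roi_px`.
#' @export
slide_rois <- function(slide, n = 3, roi_px = NULL,
                       mode = c("random", "hotspot"),
                       model = hue_model(), seed = 1L) {
  mode <- match.arg(mode)
  img <- if (inherits(slide, "rendered_slide")) slide$image else slide
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.null(roi_px)) roi_px <- floor(min(h, w) / 3)
  stopifnot(roi_px >= 8, roi_px <= min(h, w))
  set.seed(seed)
  cand_n <- if (mode == "hotspot") 40L else 400L
  y0 <- floor(stats::runif(cand_n, 1, h - roi_px + 1))
  x0 <- floor(stats::runif(cand_n, 1, w - roi_px + 1))
  if (mode == "hotspot") {
    score <- vapply(seq_len(cand_n), function(i) {
      sub <- img[y0[i]:(y0[i] + roi_px - 1), x0[i]:(x0[i] + roi_px - 1), , drop = FALSE]
      mean(segment_vessels(sub, model) > 0)
    }, numeric(1))
    ordn <- order(score, decreasing = TRUE)
  } else {
    ordn <- seq_len(cand_n)
  }
  picked <- list()
  for (i in ordn) {
    ok <- all(vapply(picked, function(p) {
      abs(p$y0 - y0[i]) >= roi_px || abs(p$x0 - x0[i]) >= roi_px
    }, logical(1)))
    if (ok) {
      picked[[length(picked) + 1]] <- list(y0 = y0[i], x0 = x0[i])
      if (length(picked) == n) break
    }
  }
  if (length(picked) < n) stop("could not place ", n, " non-overlapping ROIs")
  lapply(picked, function(p) {
    list(image = img[p$y0:(p$y0 + roi_px - 1), p$x0:(p$x0 + roi_px - 1), ,
                     drop = FALSE],
         y0 = p$y0, x0 = p$x0, roi_px = roi_px)
  })
}
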