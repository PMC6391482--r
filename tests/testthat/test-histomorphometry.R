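test_that("renderer handles empty slides and refuses impossible packings", {
  sl <- render_slide(slide_spec(image_shape = c(128, 128),
                                vessel_count_target = 0, seed = 1))
  expect_equal(nrow(sl$truth), 0)
  expect_equal(sl$truth_summary$count, 0)
  expect_equal(max(segment_vessels(sl$image)), 0)
  expect_error(render_slide(slide_spec(image_shape = c(64, 64),
                                       vessel_radii = rep(20, 50),
                                       vessel_count_target = 50, seed = 1)),
               "packing")
})

test_that("monodisperse and two-radius slides carry the identity truths", {
  # 10 disks of radius 5 um in a 1 mm^2 field
  sl <- render_slide(slide_spec(image_shape = c(1000, 1000), um_per_px = 1,
                                vessel_radii = rep(5, 10),
                                vessel_count_target = 10, seed = 2))
  expect_equal(sl$truth_summary$density, 10)
  expect_equal(sl$truth_summary$vsi_histo, 5, tolerance = 1e-12)
  sl2 <- render_slide(slide_spec(image_shape = c(512, 512), um_per_px = 1,
                                 vessel_radii = c(5, 10),
                                 vessel_count_target = 2, seed = 3))
  expect_equal(sl2$truth_summary$vsi_histo, 8.4653, tolerance = 1e-4)
})

test_that("segmentation recovers well-separated stained disks exactly", {
  sl <- render_slide(slide_spec(image_shape = c(512, 512), um_per_px = 1,
                                vessel_radii = rep(c(6, 9, 12, 15, 18), 2),
                                vessel_count_target = 10, seed = 4))
  lab <- segment_vessels(sl$image)
  expect_equal(max(lab), 10)
  expect_error(segment_vessels(array(0.5, c(32, 32, 3))), "degenerate")
  gray <- array(rep(matrix(runif(32 * 32), 32), 3), c(32, 32, 3))
  expect_error(segment_vessels(gray), "degenerate")
  expect_error(segment_vessels(matrix(1, 4, 4)), "RGB")
})

test_that("refinement is a fixed point on a solid disk and fills annuli", {
  m <- matrix(0L, 80, 80)
  d <- sqrt(outer((1:80 - 40)^2, rep(1, 80)) + outer(rep(1, 80), (1:80 - 40)^2))
  solid <- m; solid[d <= 15] <- 1L
  ref <- refine_objects(solid, um_per_px = 1)
  expect_equal(sum(ref > 0), sum(solid > 0))
  expect_equal(max(ref), 1)
  # annulus of outer radius 20: after hole fill, equivalent radius within 1 px
  ring <- matrix(0L, 100, 100)
  d2 <- sqrt(outer((1:100 - 50)^2, rep(1, 100)) + outer(rep(1, 100), (1:100 - 50)^2))
  ring[d2 <= 20 & d2 >= 14] <- 1L
  q <- quantify_vessels(refine_objects(ring, 1), 1)
  expect_equal(q$vessel_count, 1)
  expect_lt(abs(q$radii_um - 20), 1)
})

test_that("double-lumen objects are split into individual vessels", {
  m <- matrix(0L, 120, 200)
  dd <- function(cy, cx) sqrt(outer((1:120 - cy)^2, rep(1, 200)) +
                                outer(rep(1, 120), (1:200 - cx)^2))
  d1 <- dd(60, 80); d2 <- dd(60, 118)
  m[(d1 <= 20 & d1 >= 14) | (d2 <= 20 & d2 >= 14)] <- 1L
  expect_equal(max(EBImage::bwlabel(m)), 1)   # fused double-lumen fixture
  ref <- refine_objects(m, um_per_px = 1)
  q <- quantify_vessels(ref, 1)
  expect_equal(q$vessel_count, 2)
  expect_true(all(abs(q$radii_um - 20) < 3))
})

test_that("nearby fragments of one vessel are joined within join_distance", {
  m <- matrix(0L, 60, 60)
  m[20:40, 20:28] <- 1L
  m[20:40, 33:41] <- 1L              # 4 px gap
  q <- quantify_vessels(refine_objects(m, um_per_px = 1, join_distance_um = 5), 1)
  expect_equal(q$vessel_count, 1)
  # with the merge radius and closing both below the gap, objects stay apart
  qf <- quantify_vessels(refine_objects(m, um_per_px = 1, join_distance_um = 0.5,
                                        closing_radius_px = 1), 1)
  expect_equal(qf$vessel_count, 2)
})

test_that("quantification computes density, radius and VSI from labels", {
  expect_error(quantify_vessels(matrix(0L, 4, 4), 1, field_area_mm2 = 0),
               "field area")
  q0 <- quantify_vessels(matrix(0L, 10, 10), 1)
  expect_equal(q0$vessel_count, 0)
  expect_equal(q0$density, 0)
  expect_true(is.na(q0$vsi_histo))
  # one 100-px object at 2 um/px: r = sqrt(100/pi)*2
  m <- matrix(0L, 30, 30); m[1:10, 1:10] <- 1L
  q <- quantify_vessels(m, um_per_px = 2)
  expect_equal(q$radii_um, sqrt(100 / pi) * 2, tolerance = 1e-12)
  expect_equal(q$density, 1 / (900 * 4 / 1e6))
})

test_that("tiling a field into quadrants conserves counts and density", {
  set.seed(6)
  full <- matrix(0L, 200, 200)
  centers <- expand.grid(cy = c(30, 70, 130, 170), cx = c(30, 70, 130, 170))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((1:200 - centers$cy[i])^2, rep(1, 200)) +
                outer(rep(1, 200), (1:200 - centers$cx[i])^2))
    full[d <= 10] <- i
  }
  q_full <- quantify_vessels(full, 1)
  tiles <- list(full[1:100, 1:100], full[1:100, 101:200],
                full[101:200, 1:100], full[101:200, 101:200])
  counts <- vapply(tiles, function(tl) quantify_vessels(tl, 1)$vessel_count,
                   integer(1))
  expect_equal(sum(counts), q_full$vessel_count)
  expect_equal(sum(counts) / (4 * 0.01), q_full$density)
})

test_that("ROI aggregation averages density and VSI across regions", {
  mk <- function(dens, vsi, n = 5L) {
    structure(list(vessel_count = n, density = dens, vsi_histo = vsi,
                   radii_um = rep(vsi, n), field_area_mm2 = n / dens),
              class = "morphometry")
  }
  agg <- aggregate_rois(list(mk(10, 10), mk(20, 12), mk(30, 14)))
  expect_equal(agg$density, 20)
  expect_equal(agg$vsi_histo, 12)
  expect_equal(agg$vessel_count, 15L)
  same <- aggregate_rois(list(mk(10, 8), mk(10, 8), mk(10, 8)))
  expect_equal(same$density, 10)
  expect_equal(same$vsi_histo, 8)
  expect_error(aggregate_rois(list()), "at least one")
  expect_warning(aggregate_rois(list(mk(10, 8), mk(10, 8))), "expected 3")
})

test_that("full histology chain recovers truth on a rendered slide", {
  set.seed(9)
  radii <- runif(30, 4, 18)
  sl <- render_slide(slide_spec(image_shape = c(768, 768), um_per_px = 1,
                                vessel_radii = radii,
                                vessel_count_target = 30, seed = 10))
  lab <- segment_vessels(sl$image)
  ref <- refine_objects(lab, um_per_px = 1)
  q <- quantify_vessels(ref, um_per_px = 1)
  expect_equal(q$vessel_count, 30)
  expect_equal(q$density, sl$truth_summary$density)
  # match recovered objects to truth by centroid; radius error <= max(1px, 5%)
  err <- vapply(seq_len(nrow(sl$truth)), function(i) {
    d <- sqrt((q$objects$cy_px - sl$truth$cy_px[i])^2 +
                (q$objects$cx_px - sl$truth$cx_px[i])^2)
    abs(q$objects$radius_um[which.min(d)] - sl$truth$radius_um[i])
  }, numeric(1))
  expect_true(all(err <= pmax(1, 0.05 * sl$truth$radius_um)))
  expect_equal(q$vsi_histo, sl$truth_summary$vsi_histo, tolerance = 0.05)
})

test_that("ROI selection returns disjoint in-bounds tiles deterministically", {
  sl <- render_slide(slide_spec(image_shape = c(300, 300),
                                vessel_count_target = 8, seed = 12))
  r1 <- slide_rois(sl, n = 3, seed = 2)
  r2 <- slide_rois(sl, n = 3, seed = 2)
  expect_identical(lapply(r1, `[[`, "y0"), lapply(r2, `[[`, "y0"))
  for (a in 1:2) for (b in (a + 1):3) {
    expect_true(abs(r1[[a]]$y0 - r1[[b]]$y0) >= r1[[a]]$roi_px ||
                  abs(r1[[a]]$x0 - r1[[b]]$x0) >= r1[[a]]$roi_px)
  }
})
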