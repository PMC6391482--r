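#' Write a 3-D map as NIfTI
#'
#' @param map 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Length-3 voxel size in mm (stored in the header).
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map as a plain array
#'
#' @param path NIfTI file path.
#' @return List: `data` (array), `voxel_size` (mm).
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img))
}

#' Write a simulated SAGE acquisition as per-echo 4-D NIfTI files
#'
#' One `echo<k>.nii.gz` per echo (x, y, z, time), with the voxel size in the
#' header and echo times in a JSON sidecar.
#'
#' @param sim Output of [simulate_sage_dataset()].
#' @param dir Output directory (created if needed).
#' @param voxel_size Length-3 voxel size in mm.
#' @return Character vector of the four echo file paths.
#' @export
write_sage_nifti <- function(sim, dir, voxel_size = c(1.875, 1.875, 5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(sim$signal)              # echo x time x nx x ny x nz
  paths <- character(4)
  for (e in 1:4) {
    vol <- aperm(array(sim$signal[e, , , , ], dim = d[-1]), c(2, 3, 4, 1))
    paths[e] <- file.path(dir, sprintf("echo%d.nii.gz", e))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(voxel_size, sim$tr / 1000)
    RNifti::writeNifti(img, paths[e])
  }
  jsonlite::write_json(
    list(echo_times_ms = unlist(sim$echo_times, use.names = TRUE),
         tr_ms = sim$tr),
    file.path(dir, "sage_meta.json"), auto_unbox = TRUE, digits = NA)
  paths
}

#' Read per-echo 4-D NIfTI files into a SAGE stack
#'
#' @param paths Four per-echo NIfTI paths (x, y, z, time each).
#' @return Array `4 x time x nx x ny x nz`.
#' @export
read_sage_nifti <- function(paths) {
  stopifnot(length(paths) == 4)
  vols <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim = dim(img))
  })
  d <- dim(vols[[1]])
  stack <- array(0, dim = c(4L, d[4], d[1:3]))
  for (e in 1:4) stack[e, , , , ] <- aperm(vols[[e]], c(4, 1, 2, 3))
  stack
}

#' Write a DWI stack with an FSL-style .bval sidecar
#'
#' @param dwi Array `b x nx x ny x nz` with a `b_values` attribute (or pass
#'   `b_values`).
#' @param path NIfTI output path; the `.bval` file sits next to it.
#' @param voxel_size Length-3 voxel size in mm.
#' @param b_values Optional b-values, s/mm^2.
#' @return The NIfTI path, invisibly.
#' @export
write_dwi_nifti <- function(dwi, path, voxel_size = c(1.875, 1.875, 5),
                            b_values = attr(dwi, "b_values")) {
  vol <- aperm(dwi, c(2, 3, 4, 1))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_size, 1)
  RNifti::writeNifti(img, path)
  writeLines(paste(b_values, collapse = " "),
             sub("\\.nii(\\.gz)?$", ".bval", path))
  invisible(path)
}

#' Read a DWI NIfTI + .bval sidecar
#'
#' @param path NIfTI path (expects the `.bval` alongside).
#' @return Array `b x nx x ny x nz` with `b_values` attribute.
#' @export
read_dwi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(4, 1, 2, 3))
  bval_path <- sub("\\.nii(\\.gz)?$", ".bval", path)
  attr(arr, "b_values") <- scan(bval_path, quiet = TRUE)
  arr
}

#' Write a rendered slide as RGB TIFF with a scale sidecar
#'
#' @param slide A `rendered_slide` (or an H x W x 3 array plus `um_per_px`).
#' @param path TIFF output path; the `.json` scale sidecar sits next to it.
#' @param um_per_px Micrometres per pixel (taken from the slide if missing).
#' @return The TIFF path, invisibly.
#' @export
write_slide_tiff <- function(slide, path, um_per_px = NULL) {
  img <- if (inherits(slide, "rendered_slide")) slide$image else slide
  if (is.null(um_per_px)) um_per_px <- slide$um_per_px
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  jsonlite::write_json(list(um_per_px = um_per_px),
                       sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RGB slide TIFF and its scale sidecar
#'
#' @param path TIFF path.
#' @return List: `image` (H x W x 3 array in [0, 1]), `um_per_px`.
#' @export
read_slide_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- sub("\\.tiff?$", ".json", path)
  umpp <- if (file.exists(side)) {
    jsonlite::read_json(side)$um_per_px
  } else {
    NA_real_
  }
  list(image = img, um_per_px = umpp)
}
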