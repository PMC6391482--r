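#' Default end-to-end run configuration
#'
#' A small-phantom configuration that exercises every stage (simulate,
#' relax, perfuse, vsi, histo, validate) in seconds: a 32 x 32 x 8 voxel
#' phantom with 40 repetitions, one rendered slide per biopsy target, three
#' ROIs per slide, and the full agreement report. All stochastic stages
#' derive their streams from the single top-level `seed`.
#'
#' @param seed Integer master seed.
#' @return A nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    stages = c("simulate", "relax", "perfuse", "vsi", "histo", "validate"),
    seed = as.integer(seed),
    simulate = list(
      grid = c(32L, 32L, 8L),
      voxel_size = c(1.875, 1.875, 5),
      n_timepoints = 40L,
      tr_ms = 2000,
      echo_times_ms = c(14.0, 34.1, 58.0, 92.4),
      noise_sigma = 5,
      tumor_leakage = 0,
      bolus = list(t0 = 20, alpha = 3, beta = 3.5,
                   recirculation_fraction = 0.15),
      dwi = list(b_values = c(0, 500, 1000), noise_sigma = 5),
      n_targets = 4L,
      slide = list(image_px = c(640L, 640L), um_per_px = 1.0,
                   vessels_per_slide = 17L)
    ),
    relax = list(smooth = TRUE),
    perfuse = list(leak_mode = "bidirectional"),
    vsi = list(constant_k = 0.867),
    histo = list(rois = 3L, join_distance_um = 5, closing_radius_px = 2L,
                 min_lumen_area_px = 10L),
    validate = list(radius_mm = 5)
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Missing blocks are filled from [default_run_config()]; unknown stages and
#' invalid dependency orders are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% 1L)
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_run_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  known <- c("simulate", "relax", "perfuse", "vsi", "histo", "validate")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(relax = "simulate", perfuse = "relax", vsi = "perfuse",
               histo = "simulate", validate = c("vsi", "histo"))
  for (s in cfg$stages) {
    need <- deps[[s]]
    missing <- setdiff(need, cfg$stages)
    if (length(missing)) {
      stop("stage '", s, "' requires upstream stage(s): ",
           paste(missing, collapse = ", "))
    }
    if (any(match(need, cfg$stages) > match(s, cfg$stages))) {
      stop("stages are not in a valid dependency order near '", s, "'")
    }
  }
  sim <- cfg$simulate
  stopifnot(length(sim$grid) == 3, sim$n_timepoints >= 8,
            length(sim$echo_times_ms) == 4, sim$n_targets >= 1)
  invisible(cfg)
}

#' Run the full vessel-size-imaging pipeline
#'
#' Executes the configured stages in order, carrying intermediate products
#' in memory, optionally writing every artifact (NIfTI maps, slide TIFFs,
#' per-target CSV, report JSON, log, manifest with file hashes) into a run
#' directory. Rerunning with the same configuration reproduces all
#' stochastic stages bit-identically.
#'
#' @param config A `run_config` list ([default_run_config()],
#'   [read_run_config()]) or a YAML path.
#' @param out_dir Optional run directory (created; artifacts + manifest
#'   written there).
#' @return A list of class `pipeline_run` with elements per executed stage:
#'   `sim`, `relaxometry`, `relaxogram`, `maps` (rcbv, adc), `vsi`,
#'   `histology` (per-target morphometry), `targets` (tibble), `report`
#'   (agreement report, when the validate stage ran), `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  state <- list(config = config)
  need <- function(field, stage) {
    if (is.null(state[[field]])) {
      stop("missing upstream artifact '", field, "' for stage '", stage, "'")
    }
  }
  sim_cfg <- config$simulate

  for (stage in config$stages) {
    say("stage %s", stage)
    if (stage == "simulate") {
      phantom <- phantom_spec(
        grid_shape = sim_cfg$grid, voxel_size = sim_cfg$voxel_size,
        classes = phantom_classes(tumor_leakage = sim_cfg$tumor_leakage),
        noise_sigma = sim_cfg$noise_sigma, seed = config$seed)
      bolus <- bolus_model(
        t0 = sim_cfg$bolus$t0, alpha = sim_cfg$bolus$alpha,
        beta = sim_cfg$bolus$beta,
        recirculation_fraction = sim_cfg$bolus$recirculation_fraction %||% 0.15)
      sim <- simulate_sage_dataset(
        phantom, bolus, echo_times = sim_cfg$echo_times_ms,
        tr = sim_cfg$tr_ms, n_timepoints = sim_cfg$n_timepoints)
      dwi <- simulate_dwi(sim$truth$adc_map, sim$truth$s0_map,
                          b_values = sim_cfg$dwi$b_values,
                          noise_sigma = sim_cfg$dwi$noise_sigma,
                          seed = config$seed + 1L)
      slides <- lapply(seq_len(sim_cfg$n_targets), function(i) {
        render_slide(slide_spec(
          image_shape = sim_cfg$slide$image_px,
          um_per_px = sim_cfg$slide$um_per_px,
          vessel_count_target = sim_cfg$slide$vessels_per_slide,
          seed = config$seed * 1000L + i))
      })
      # biopsy-target centres: random tumor voxels, one per target
      tum <- which(sim$truth$labels ==
                     match("tumor", phantom$classes$class), arr.ind = TRUE)
      set.seed(config$seed + 2L)
      rows <- tum[sample(nrow(tum), sim_cfg$n_targets), , drop = FALSE]
      centers <- sweep(rows - 1, 2, sim_cfg$voxel_size, `*`)
      state$phantom <- phantom
      state$sim <- sim
      state$dwi <- dwi
      state$slides <- slides
      state$target_centers <- centers
    } else if (stage == "relax") {
      need("sim", stage)
      fit <- fit_sage_series(state$sim$signal, state$sim$echo_times)
      state$relaxometry <- fit
      state$relaxogram <- delta_curves(fit, smooth = config$relax$smooth)
      say("  invalid-fit fraction %.4f", fit$invalid_fraction)
    } else if (stage == "perfuse") {
      need("relaxogram", stage)
      labels <- state$sim$truth$labels
      nawm <- labels == match("nawm", state$phantom$classes$class)
      nt <- dim(state$relaxogram$d_r2star_t)[1]
      dmat <- matrix(state$relaxogram$d_r2star_t, nt)
      ref <- rowMeans(dmat[, as.logical(nawm), drop = FALSE], na.rm = TRUE)
      lc <- leakage_correct(dmat, ref, state$sim$time_axis,
                            mode = config$perfuse$leak_mode)
      cbv_raw <- compute_cbv(lc$corrected, state$sim$time_axis)
      rcbv <- normalize_cbv(cbv_raw, as.logical(nawm))
      adc <- fit_adc(state$dwi)
      dim(rcbv) <- dim(labels)
      state$maps <- list(rcbv = rcbv, adc = adc, cbv_raw = cbv_raw,
                         leakage = lc[c("k1", "k2", "k_back")], nawm = nawm)
    } else if (stage == "vsi") {
      need("maps", stage)
      state$vsi <- compute_vsi(state$maps$rcbv, state$maps$adc,
                               state$relaxogram$d_r2star_max,
                               state$relaxogram$d_r2_max,
                               constant_k = config$vsi$constant_k)
    } else if (stage == "histo") {
      need("slides", stage)
      hc <- config$histo
      state$histology <- lapply(seq_along(state$slides), function(i) {
        sl <- state$slides[[i]]
        rois <- slide_rois(sl, n = hc$rois, seed = config$seed * 100L + i)
        per_roi <- lapply(rois, function(r) {
          lab <- segment_vessels(r$image)
          ref <- refine_objects(lab, um_per_px = sl$um_per_px,
                                join_distance_um = hc$join_distance_um,
                                closing_radius_px = hc$closing_radius_px,
                                min_lumen_area_px = hc$min_lumen_area_px)
          quantify_vessels(ref, um_per_px = sl$um_per_px)
        })
        aggregate_rois(per_roi, expected_n = hc$rois)
      })
    } else if (stage == "validate") {
      need("vsi", stage)
      need("histology", stage)
      vx <- config$simulate$voxel_size
      r <- config$validate$radius_mm
      targets <- purrr::map_dfr(seq_len(nrow(state$target_centers)), function(i) {
        ctr <- state$target_centers[i, ]
        h <- state$histology[[i]]
        tibble::tibble(
          target = i,
          grade = if (i %% 2 == 0) "IV" else "III",
          rcbv = extract_target(state$maps$rcbv, ctr, vx, r)$value,
          adc = extract_target(state$maps$adc, ctr, vx, r)$value,
          vsi_mri = extract_target(state$vsi$vsi, ctr, vx, r)$value,
          density = h$density,
          vsi_histo = h$vsi_histo,
          vessel_count = h$vessel_count
        )
      })
      state$targets <- targets
      state$report <- tryCatch(build_report(targets),
                               error = function(e) {
                                 say("  report skipped: %s", conditionMessage(e))
                                 NULL
                               })
    }
  }

  run <- structure(state, class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir, log_lines)
  run
}

# persist a pipeline run with a hash manifest
write_run <- function(run, out_dir, log_lines = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  vx <- cfg$simulate$voxel_size
  if (!is.null(run$sim)) {
    write_sage_nifti(run$sim, file.path(out_dir, "sage"), voxel_size = vx)
    write_dwi_nifti(run$dwi, file.path(out_dir, "dwi.nii.gz"), voxel_size = vx)
    for (i in seq_along(run$slides)) {
      write_slide_tiff(run$slides[[i]],
                       file.path(out_dir, sprintf("slide_%02d.tif", i)))
    }
  }
  if (!is.null(run$maps)) {
    write_map_nifti(run$maps$rcbv, file.path(out_dir, "rcbv.nii.gz"), vx)
    write_map_nifti(run$maps$adc, file.path(out_dir, "adc.nii.gz"), vx)
  }
  if (!is.null(run$vsi)) {
    write_map_nifti(run$vsi$vsi, file.path(out_dir, "vsi.nii.gz"), vx)
  }
  if (!is.null(run$targets)) {
    utils::write.csv(run$targets, file.path(out_dir, "targets.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$report)) {
    jsonlite::write_json(
      list(n_targets = run$report$n_targets,
           correlations = run$report$correlations,
           bland_altman = run$report$bland_altman[
             c("mean_difference", "loa_low", "loa_high")],
           t_test = run$report$t_test),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("vsimetry")),
    seed = cfg$seed,
    stages = cfg$stages,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Verify the integrity of a written pipeline run
#'
#' Recomputes the MD5 hash of every file recorded in the run manifest and
#' fails loudly on any mismatch or missing file.
#'
#' @param run_dir Directory written by [run_pipeline()] with `out_dir` set.
#' @return TRUE invisibly if all hashes match.
#' @export
verify_run <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(mf_path)
  for (f in names(manifest$files)) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) stop("provenance error: missing artifact ", f)
    h <- unname(tools::md5sum(p))
    if (!identical(h, manifest$files[[f]])) {
      stop("provenance error: hash mismatch for ", f)
    }
  }
  invisible(TRUE)
}
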