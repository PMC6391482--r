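#' Median map value over a spherical biopsy target
#'
#' Summarises a quantitative map over a 5-mm-radius (default) spherical
#' target. Sphere membership is by voxel-centre Euclidean distance (no
#' partial-volume weighting); voxel centres sit at `(index - 1) * voxel_size`
#' mm so the first voxel centre is the coordinate origin.
#'
#' @param map 3-D numeric array (NA = invalid voxel).
#' @param center_mm Length-3 target centre in the map's own mm frame.
#' @param voxel_size Length-3 voxel size in mm.
#' @param radius_mm Sphere radius in mm (default 5).
#' @param summary `"median"` (default, matching the per-target medians the
#'   protocol reports) or `"mean"`.
#' @return A list: `value` (summary over valid voxels in the sphere),
#'   `n_voxels` (valid voxels contributing).
#' @export
extract_target <- function(map, center_mm, voxel_size, radius_mm = 5,
                           summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(length(dim(map)) == 3, length(center_mm) == 3,
            length(voxel_size) == 3, radius_mm > 0)
  fov <- (dim(map) - 1) * voxel_size
  if (any(center_mm < 0) || any(center_mm > fov)) {
    stop("target centre is outside the field of view")
  }
  # candidate index ranges, then exact distance test
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((center_mm[a] - radius_mm) / voxel_size[a]) + 1L)
    hi <- min(dim(map)[a], ceiling((center_mm[a] + radius_mm) / voxel_size[a]) + 1L)
    lo:hi
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- (( g$i - 1) * voxel_size[1] - center_mm[1])^2 +
    ((g$j - 1) * voxel_size[2] - center_mm[2])^2 +
    ((g$k - 1) * voxel_size[3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2
  vals <- map[cbind(g$i, g$j, g$k)][inside]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid voxels inside the target sphere")
  list(value = if (summary == "median") stats::median(vals) else mean(vals),
       n_voxels = length(vals))
}

#' Bland-Altman agreement between two measurement techniques
#'
#' Elementwise differences `d = x - y`, their mean, and the limits of
#' agreement `mean(d) +/- 1.96 * SD(d)` using the sample (n-1) SD.
#'
#' @param x,y Numeric vectors of equal length (n >= 2), same units.
#' @return A list of class `bland_altman`: `n`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, and a tibble `data` with
#'   per-pair means and differences for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(n = length(d), mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 data = tibble::tibble(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' Pearson correlation with a t-distribution p-value
#'
#' Product-moment correlation and its two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, n >= 3, each with non-zero variance.
#' @return A list: `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-group comparison with normality checks
#'
#' Wilcoxon-Mann-Whitney test between the two grade groups (exact for small
#' samples without ties, normal approximation with tie/continuity correction
#' otherwise), plus a Shapiro-Wilk normality check per group.
#'
#' @param values Numeric vector.
#' @param groups Factor-like vector with exactly 2 levels, same length.
#' @return A list: `u` (Mann-Whitney U), `p`, per-group `shapiro`
#'   (tibble: group, w, p, n), group sizes.
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  split_v <- split(values, groups)
  if (any(lengths(split_v) == 0)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(split_v[[1]], split_v[[2]],
                                            alternative = "two.sided"))
  shapiro <- purrr::map_dfr(names(split_v), function(g) {
    v <- split_v[[g]]
    if (length(v) >= 3 && stats::sd(v) > 0) {
      sw <- stats::shapiro.test(v)
      tibble::tibble(group = g, w = unname(sw$statistic), p = sw$p.value,
                     n = length(v))
    } else {
      tibble::tibble(group = g, w = NA_real_, p = NA_real_, n = length(v))
    }
  })
  list(u = unname(wt$statistic), p = wt$p.value, shapiro = shapiro,
       n1 = length(split_v[[1]]), n2 = length(split_v[[2]]))
}

#' Paired (or unpaired) t-test of the MRI-histology VSI difference
#'
#' @param vsi_mri,vsi_histo Numeric vectors of per-target VSI (um).
#' @param paired Logical; the targets are intrinsically paired, so TRUE by
#'   default (an unpaired variant is provided for comparison).
#' @return A list: `t`, `p`, `df`, `paired`; `p` is NA with
#'   `zero_variance = TRUE` when all paired differences are identical.
#' @export
vsi_difference_test <- function(vsi_mri, vsi_histo, paired = TRUE) {
  if (paired && length(vsi_mri) != length(vsi_histo)) {
    stop("paired test requires equal-length vectors")
  }
  if (paired && stats::sd(vsi_mri - vsi_histo) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, paired = TRUE,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(vsi_mri, vsi_histo, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), paired = paired, zero_variance = FALSE)
}

#' Full MRI-versus-histology agreement report for a biopsy cohort
#'
#' Computes, from a per-target table, the four Pearson correlations
#' (rCBV vs density, rCBV vs caliber, VSI_MRI vs density, VSI_MRI vs
#' caliber), the Bland-Altman agreement of the two VSI measures, per-grade
#' Mann-Whitney comparisons of every variable, Shapiro-Wilk normality of
#' each VSI distribution, and the t-test of the VSI difference. Targets
#' with missing required fields are excluded with a message.
#'
#' @param cohort Data frame with columns `rcbv`, `density`, `vsi_mri`,
#'   `vsi_histo`, and optionally `target` and `grade`; e.g. from
#'   [make_paired_cohort()] or assembled by the pipeline.
#' @param paired_t Logical, paired t-test (default TRUE).
#' @return An object of class `agreement_report`.
#' @export
build_report <- function(cohort, paired_t = TRUE) {
  req <- c("rcbv", "density", "vsi_mri", "vsi_histo")
  if (!all(req %in% names(cohort))) {
    stop("cohort must have columns: ", paste(req, collapse = ", "))
  }
  cohort <- tibble::as_tibble(cohort)
  if (!"target" %in% names(cohort)) cohort$target <- seq_len(nrow(cohort))
  complete <- stats::complete.cases(cohort[req])
  if (any(!complete)) {
    message("excluding ", sum(!complete), " target(s) with missing fields: ",
            paste(cohort$target[!complete], collapse = ", "))
    cohort <- cohort[complete, ]
  }
  if (nrow(cohort) < 3) stop("at least 3 complete targets are required")

  pairs <- list(
    rcbv_vs_density = c("rcbv", "density"),
    rcbv_vs_caliber = c("rcbv", "vsi_histo"),
    vsi_mri_vs_density = c("vsi_mri", "density"),
    vsi_mri_vs_caliber = c("vsi_mri", "vsi_histo")
  )
  correlations <- purrr::map_dfr(names(pairs), function(nm) {
    v <- pairs[[nm]]
    ct <- correlate(cohort[[v[1]]], cohort[[v[2]]])
    tibble::tibble(pair = nm, x = v[1], y = v[2],
                   r = ct$r, p = ct$p, n = ct$n)
  })

  ba <- bland_altman(cohort$vsi_mri, cohort$vsi_histo)
  tt <- vsi_difference_test(cohort$vsi_mri, cohort$vsi_histo, paired = paired_t)

  group_tests <- NULL
  if ("grade" %in% names(cohort) && length(unique(cohort$grade)) == 2) {
    group_tests <- purrr::map_dfr(req, function(v) {
      gc <- group_compare(cohort[[v]], cohort$grade)
      tibble::tibble(variable = v, u = gc$u, p = gc$p,
                     n1 = gc$n1, n2 = gc$n2)
    })
  }
  normality <- purrr::map_dfr(c("vsi_mri", "vsi_histo"), function(v) {
    sw <- stats::shapiro.test(cohort[[v]])
    tibble::tibble(variable = v, w = unname(sw$statistic), p = sw$p.value)
  })

  structure(list(n_targets = nrow(cohort), targets = cohort,
                 correlations = correlations, bland_altman = ba,
                 group_tests = group_tests, normality = normality,
                 t_test = tt),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("MRI-histology agreement report (", x$n_targets, " targets)\n", sep = "")
  cat(sprintf("  Bland-Altman VSI (MRI - histology): mean %.2f um, LoA [%.2f, %.2f]\n",
              x$bland_altman$mean_difference, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("  %-22s r = %5.2f, p = %.3f\n", x$correlations$pair[i],
                x$correlations$r[i], x$correlations$p[i]))
  }
  if (!is.null(x$t_test$p) && is.finite(x$t_test$p)) {
    cat(sprintf("  VSI difference t-test (%s): p = %.3f\n",
                if (x$t_test$paired) "paired" else "unpaired", x$t_test$p))
  }
  invisible(x)
}

#' Tidy the correlation table of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Tibble with one row per correlation pair (`pair`, `r`, `p`, `n`).
#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) x$correlations

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row tibble: target count, Bland-Altman mean difference and
#'   limits of agreement, caliber and density correlations.
#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  cc <- x$correlations
  tibble::tibble(
    n_targets = x$n_targets,
    mean_difference = x$bland_altman$mean_difference,
    loa_low = x$bland_altman$loa_low,
    loa_high = x$bland_altman$loa_high,
    r_caliber = cc$r[cc$pair == "vsi_mri_vs_caliber"],
    p_caliber = cc$p[cc$pair == "vsi_mri_vs_caliber"],
    r_density = cc$r[cc$pair == "rcbv_vs_density"],
    p_density = cc$p[cc$pair == "rcbv_vs_density"]
  )
}
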