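#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with the mean-difference
#' line (solid) and the 1.96-SD limits of agreement (dashed).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(shape = 21, size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_difference) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of VSI_MRI and VSI_Histology (µm)",
                  y = "VSI_MRI − VSI_Histology (µm)") +
    ggplot2::theme_classic()
}

#' Agreement-report plots
#'
#' `autoplot()` on an `agreement_report` returns its Bland-Altman plot;
#' [plot_correlations()] gives the four MRI-vs-histology scatter panels.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  p <- autoplot(object$bland_altman)
  if (!is.null(object$targets$grade)) {
    p <- p + ggplot2::aes(fill = object$targets$grade) +
      ggplot2::scale_fill_manual(values = c(III = "black", IV = "white"),
                                 name = "WHO grade")
  }
  p
}

#' Four-panel MRI-versus-histology correlation scatter
#'
#' @param report An `agreement_report`.
#' @return A ggplot object faceted by variable pair, annotated with r and p.
#' @export
plot_correlations <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  tg <- report$targets
  long <- dplyr::bind_rows(lapply(seq_len(nrow(report$correlations)), function(i) {
    row <- report$correlations[i, ]
    tibble::tibble(pair = row$pair, x = tg[[row$x]], y = tg[[row$y]],
                   label = sprintf("r = %.2f, p = %.3f", row$r, row$p))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 21, size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey30") +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       data = dplyr::distinct(long, .data$pair, .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = "MRI measure", y = "Histology measure") +
    ggplot2::theme_bw()
}

#' Display one slice of a VSI map
#'
#' @param object A `vsi_map` from [compute_vsi()].
#' @param slice Slice index along the third dimension (default: middle).
#' @param ... Unused.
#' @return A ggplot raster of the slice, invalid voxels blank.
#' @exportS3Method ggplot2::autoplot
autoplot.vsi_map <- function(object, slice = NULL, ...) {
  v <- object$vsi
  if (length(dim(v)) == 3) {
    if (is.null(slice)) slice <- ceiling(dim(v)[3] / 2)
    v <- v[, , slice]
  }
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$vsi <- as.numeric(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$vsi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "VSI (µm)") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
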