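# ggplot2 displays for sweep tables, CNR reports, volumes and profiles.

#' @exportS3Method ggplot2::autoplot
autoplot.cbct_sweep <- function(object, y = c("mean_total_norm", "spr"), ...) {
  y <- match.arg(y)
  lab <- if (y == "spr") "scatter-to-primary ratio"
         else "normalized ROI total intensity"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$slit_x_mm, y = .data[[y]],
                               colour = .data$layout)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~diameter_cm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "collimating slit (mm, log scale)", y = lab) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.recon_volume <- function(object, slice = NULL, ...) {
  sl <- volume_slice(object, slice)
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = object$units) +
    ggplot2::theme_void()
}

#' Plot per-insert contrast-to-noise ratios
#'
#' @param report A `cnr_report` (or several row-bound with an
#'   `acquisition` column) from [compute_cnr()].
#' @return A ggplot object.
#' @export
plot_cnr <- function(report) {
  has_acq <- "acquisition" %in% names(report)
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data$material, y = .data$cnr))
  p <- if (has_acq) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$acquisition),
                          position = "dodge")
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "CNR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a line profile
#' @param profile A tibble from [line_profile()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$s_px, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance along segment (px)", y = "value") +
    ggplot2::theme_minimal()
}
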