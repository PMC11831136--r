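#' Plot spatial protein profiles
#'
#' Line plot of selected proteins' values along the (aligned) relative
#' axis, one panel per protein, colored by replicate.
#'
#' @param profile Profile tibble.
#' @param annotation Annotation with `sample_id`, `replicate` and `perc`
#'   (uses `perc2` when present).
#' @param proteins Protein ids to show (default: first 6).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profile, annotation, proteins = NULL) {
  proteins <- proteins %||% utils::head(profile$protein_id, 6)
  long <- tidyr::pivot_longer(profile[profile$protein_id %in% proteins, ],
                              -"protein_id", names_to = "sample_id",
                              values_to = "value")
  pos_col <- if ("perc2" %in% names(annotation)) "perc2" else "perc"
  long <- dplyr::left_join(long, annotation, by = "sample_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[pos_col]], y = .data$value,
                                     color = .data$replicate)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~protein_id, scales = "free_y") +
    ggplot2::labs(x = "relative axis position", y = "normalized abundance",
                  color = "replicate") +
    ggplot2::theme_minimal()
}

#' @describeIn sam_quant_scores Histogram of observed d scores with the
#'   permutation-null 2.5/97.5% band.
#' @param object A `slicewise_trend` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.slicewise_trend <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey60") +
    ggplot2::labs(x = "trend score d", y = "proteins") +
    ggplot2::theme_minimal()
  null <- attr(object, "null")
  if (!is.null(null)) {
    q <- stats::quantile(null, c(0.025, 0.975), na.rm = TRUE)
    p <- p + ggplot2::geom_vline(xintercept = q, linetype = "dashed")
  }
  p
}

#' @describeIn delay_correlation Correlation-vs-delay curve plot.
#' @param object A `slicewise_delay_curve`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.slicewise_delay_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$delay, y = .data$corr)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "delay (grid units)", y = "correlation") +
    ggplot2::theme_minimal()
}

#' @describeIn median_shift_and_apply Per-marker shift distributions per
#'   replicate pair with the applied medians.
#' @param object A `slicewise_alignment`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.slicewise_alignment <- function(object, ...) {
  pp <- object$per_protein
  pp$pair <- paste(pp$rep_a, pp$rep_b, sep = " - ")
  med <- object$median_shifts
  med$pair <- paste(med$rep_a, med$rep_b, sep = " - ")
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$direction, y = .data$shift)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_point(data = med, color = "red", size = 3, shape = 18) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(y = "fractional axis shift") +
    ggplot2::theme_minimal()
}
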