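#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy methods for pipeline result objects
#'
#' `tidy()` returns the per-element table of a fitted object (per-protein
#' trend scores, per-marker shifts, network edges); `glance()` returns a
#' one-row summary.
#'
#' @param x A `slicewise_trend`, `slicewise_alignment` or
#'   `slicewise_network` object.
#' @param ... Ignored.
#' @name slicewise-tidiers
NULL

#' @rdname slicewise-tidiers
#' @exportS3Method generics::tidy
tidy.slicewise_trend <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "slicewise_trend")
  out
}

#' @rdname slicewise-tidiers
#' @exportS3Method generics::glance
glance.slicewise_trend <- function(x, ...) {
  null <- attr(x, "null")
  tibble::tibble(
    n_proteins = nrow(x),
    n_samples = length(attr(x, "response")),
    s0 = x$s0[1],
    nperms = if (is.null(null)) 0L else ncol(null),
    method = attr(x, "method") %||% "sam"
  )
}

#' @rdname slicewise-tidiers
#' @exportS3Method generics::tidy
tidy.slicewise_alignment <- function(x, ...) x$median_shifts

#' @rdname slicewise-tidiers
#' @exportS3Method generics::glance
glance.slicewise_alignment <- function(x, ...) {
  applied <- x$annotation[x$annotation$replicate != x$reference, , drop = FALSE]
  tibble::tibble(
    reference = x$reference,
    n_markers = length(unique(x$per_protein$protein_id)),
    n_pairs = nrow(unique(x$median_shifts[c("rep_a", "rep_b")])),
    max_applied_shift = if (nrow(applied)) {
      max(abs(applied$perc2 - applied$perc))
    } else 0
  )
}

#' @rdname slicewise-tidiers
#' @exportS3Method generics::tidy
tidy.slicewise_network <- function(x, ...) {
  e <- x$edges
  e$delay_inv <- 1 / (e$delay + 1)
  e
}

#' @rdname slicewise-tidiers
#' @exportS3Method generics::glance
glance.slicewise_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_pruned = x$n_pruned %||% NA_integer_,
    dpi_tolerance = x$dpi_tolerance,
    mean_delay = if (nrow(x$edges)) mean(x$edges$delay) else NA_real_,
    mean_corr = if (nrow(x$edges)) mean(x$edges$corr) else NA_real_
  )
}
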