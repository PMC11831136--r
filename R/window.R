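#' Sliding-window missing-value fractions
#'
#' Slides a forward-looking window of `after + 1` consecutive positions
#' over an ordered profile and reports the fraction of missing values in
#' each complete window. Positions whose window would run past the end of
#' the profile yield no value (complete windows only).
#'
#' @param x Numeric vector (one protein's values along the slice axis of
#'   one replicate, ordered by slice; may contain `NA`).
#' @param after Number of subsequent positions included; window length is
#'   `after + 1`.
#' @return Numeric vector of length `max(0, length(x) - after)` with the
#'   per-window missing fractions.
#' @export
sliding_na_fractions <- function(x, after = 10) {
  stopifnot(is.numeric(after), length(after) == 1, after >= 0)
  n <- length(x)
  w <- after + 1
  if (n < w) return(numeric(0))
  miss <- as.numeric(is.na(x))
  # cumulative-sum sliding count
  cs <- c(0, cumsum(miss))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

#' Per-protein sliding-window completeness scores
#'
#' For every protein and replicate, the score is the *minimum* missing
#' fraction over all complete sliding windows: a protein is locally dense
#' somewhere along the axis if at least one window is mostly observed.
#' Windows slide over the samples of a replicate in slice order.
#'
#' @param profile Profile tibble (`protein_id` + sample columns).
#' @param annotation Annotation tibble with `sample_id`, `replicate`,
#'   `slice`.
#' @param after Window length minus one (default 10: an 11-slice window,
#'   220 um at 20 um thickness).
#' @return Tibble `protein_id`, `replicate`, `min_na_fraction`
#'   (`NA` for replicates shorter than the window).
#' @export
window_scores <- function(profile, annotation, after = 10) {
  m <- profile_matrix(profile)
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  reps <- unique(ann$replicate)
  res <- lapply(reps, function(r) {
    cols <- which(ann$replicate == r)
    cols <- cols[order(ann$slice[cols])]
    sub <- m[, cols, drop = FALSE]
    mins <- apply(sub, 1, function(z) {
      fr <- sliding_na_fractions(z, after = after)
      if (length(fr) == 0) NA_real_ else min(fr)
    })
    tibble::tibble(protein_id = rownames(m), replicate = r,
                   min_na_fraction = unname(mins))
  })
  dplyr::bind_rows(res)
}

#' Select proteins with sufficient local data density
#'
#' A protein is retained when the mean (across replicates) of its
#' per-replicate minimum window missing-fraction is at most
#' `max_na_fraction` — by default 0.3, i.e. at least one ~200 um stretch
#' with a 70% data rate in the average replicate. The comparison is
#' inclusive. Replicates shorter than the window contribute no windows and
#' are excluded from the mean.
#'
#' @inheritParams window_scores
#' @param max_na_fraction Completeness threshold in `[0, 1]`.
#' @return Character vector of selected protein ids (in input row order).
#'   The full score table is attached as attribute `"scores"`.
#' @export
select_proteins <- function(profile, annotation, after = 10,
                            max_na_fraction = 0.3) {
  stopifnot(max_na_fraction >= 0, max_na_fraction <= 1)
  sc <- window_scores(profile, annotation, after = after)
  if (all(is.na(sc$min_na_fraction))) {
    stop("window too large for data: no replicate yields a complete window",
         call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(sc, .data$protein_id),
    score = mean(.data$min_na_fraction, na.rm = TRUE),
    .groups = "drop"
  )
  agg <- agg[match(profile$protein_id, agg$protein_id), , drop = FALSE]
  sel <- agg$protein_id[!is.na(agg$score) & agg$score <= max_na_fraction]
  attr(sel, "scores") <- sc
  sel
}
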