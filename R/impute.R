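#' Distance-based imputation with sliding-window linear models
#'
#' Imputes missing profile values from neighboring slices. Per replicate
#' and protein, the dense slice grid `min(slice):max(slice)` is built, and
#' for every missing sample the window
#' `[slice - width_backward, slice + width_forward]` on that grid is
#' examined; physical gaps (lost sections) therefore reduce the number of
#' available points. If the window holds strictly more than
#' `min_data_required` observed values, an ordinary least-squares line
#' `value ~ slice` is fitted on them and evaluated at the missing slice.
#' Predictions below the minimum observed value of the entire replicate
#' block (all proteins, all samples) are rejected and left missing — a
#' local line may not undershoot anything ever observed in that replicate.
#'
#' If the window is too sparse and `fallback = "impute"`, the cell is
#' drawn once from a downshifted normal
#' `N(mean(xm) - m_offset * sd(xm), sd_offset * sd(low tail of xm))`,
#' where `xm` is all replicate-block values lying strictly within this
#' protein's observed range and the low tail is the part of `xm` below its
#' `sel` quantile. With `fallback = "none"` such cells stay missing (the
#' pipeline default; a global downshift pass follows).
#'
#' Observed cells are never modified. Cells are visited in a fixed order
#' (replicate, protein, slice ascending), so results are reproducible for
#' a given RNG state; seed the session (or use the `seed` argument) for
#' bitwise repeatability.
#'
#' @param profile Normalized profile tibble.
#' @param annotation Annotation with `sample_id`, `replicate`, `slice`.
#' @param width_forward,width_backward Window half-widths in slices.
#' @param min_data_required Minimum observed points per window; the linear
#'   fit requires strictly more than this. Values below 5 trade robustness
#'   for coverage.
#' @param fallback `"none"` (default) or `"impute"`.
#' @param sel Low-tail quantile for the fallback draw.
#' @param m_offset Downshift of the fallback mean, in sd units.
#' @param sd_offset Shrink factor of the fallback sd.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before any fallback draw.
#' @return Profile tibble, stage `"imputed"`, with an `"impute_log"`
#'   attribute (tibble: per-replicate counts of linear, rejected and
#'   fallback imputations).
#' @export
impute_by_distance <- function(profile, annotation,
                               width_forward = 10, width_backward = 10,
                               min_data_required = 3,
                               fallback = c("none", "impute"),
                               sel = 0.05, m_offset = 1.6, sd_offset = 0.8,
                               seed = NULL) {
  fallback <- match.arg(fallback)
  stopifnot(width_forward >= 0, width_backward >= 0, min_data_required >= 1,
            sel > 0, sel < 1, m_offset >= 0, sd_offset > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- profile_matrix(profile)
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  logs <- list()
  for (r in unique(ann$replicate)) {
    cols <- which(ann$replicate == r)
    cols <- cols[order(ann$slice[cols])]
    slices <- ann$slice[cols]
    block <- m[, cols, drop = FALSE]
    block_min <- suppressWarnings(min(block, na.rm = TRUE))
    n_lin <- n_rej <- n_fb <- 0L
    for (i in seq_len(nrow(block))) {
      z <- block[i, ]
      nas <- which(is.na(z))
      if (length(nas) == 0) next
      obs_rng <- suppressWarnings(range(z, na.rm = TRUE))
      for (k in nas) {
        s <- slices[k]
        in_win <- which(slices >= s - width_backward &
                        slices <= s + width_forward & !is.na(z))
        if (length(in_win) > min_data_required) {
          fit <- stats::lm.fit(cbind(1, slices[in_win]), z[in_win])
          pred <- fit$coefficients[1] + fit$coefficients[2] * s
          if (is.finite(pred) && pred >= block_min) {
            block[i, k] <- pred
            n_lin <- n_lin + 1L
          } else {
            n_rej <- n_rej + 1L
          }
        } else if (fallback == "impute") {
          xm <- block[is.finite(block) & block > obs_rng[1] & block < obs_rng[2]]
          if (length(xm) >= 2) {
            low <- xm[xm < stats::quantile(xm, probs = sel)]
            sd_low <- stats::sd(low)
            if (!is.finite(sd_low)) sd_low <- stats::sd(xm)
            block[i, k] <- stats::rnorm(
              1, mean = mean(xm) - m_offset * stats::sd(xm),
              sd = sd_offset * sd_low)
            n_fb <- n_fb + 1L
          }
        }
      }
    }
    m[, cols] <- block
    logs[[r]] <- tibble::tibble(replicate = r, linear = n_lin,
                                rejected = n_rej, fallback = n_fb)
  }
  out <- tidy_matrix(m, stage = "imputed")
  attr(out, "impute_log") <- dplyr::bind_rows(logs)
  out
}

#' Global downshifted-normal imputation of remaining missing cells
#'
#' Whatever the distance-based pass could not impute is filled per sample
#' from the sample's own low-intensity tail: missing cells are drawn from
#' `N(mean(low), sd(low))` where `low` is the set of the sample's observed
#' values below its `sel` quantile. This mimics the downshifted-normal
#' imputation commonly used for left-censored (below detection) proteomics
#' data. If fewer than 2 values fall below the quantile, the tail widens
#' to the lowest `max(2, ceil(sel * n))` values (with a warning).
#'
#' @param profile Profile tibble (typically after [impute_by_distance()]).
#' @param sel Low-tail quantile (default 0.05).
#' @param seed Optional integer seed for reproducible draws.
#' @return Profile tibble with no missing cells, stage `"imputed"`.
#' @export
global_downshift_impute <- function(profile, sel = 0.05, seed = NULL) {
  stopifnot(sel > 0, sel < 1)
  if (!is.null(seed)) set.seed(seed)
  m <- profile_matrix(profile)
  for (j in seq_len(ncol(m))) {
    nas <- which(is.na(m[, j]))
    if (length(nas) == 0) next
    obs <- m[!is.na(m[, j]), j]
    if (length(obs) < 2) {
      stop("sample '", colnames(m)[j], "' has fewer than 2 observed values",
           call. = FALSE)
    }
    low <- obs[obs < stats::quantile(obs, probs = sel)]
    if (length(low) < 2) {
      k <- max(2, ceiling(sel * length(obs)))
      low <- sort(obs)[seq_len(min(k, length(obs)))]
      warning("sample '", colnames(m)[j], "': fewer than 2 values below the ",
              sel, " quantile; widening to the lowest ", length(low),
              " values", call. = FALSE)
    }
    m[nas, j] <- stats::rnorm(length(nas), mean = mean(low),
                              sd = stats::sd(low))
  }
  out <- tidy_matrix(m, stage = "imputed")
  attr(out, "impute_log") <- attr(profile, "impute_log")
  out
}
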