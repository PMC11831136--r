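#' Set low and non-finite intensities to missing
#'
#' Raw label-free intensities below the detection floor are unreliable and
#' are treated as missing (the dropout they represent is intensity
#' dependent, i.e. MNAR). Values strictly below `floor` and all non-finite
#' values become `NA`; everything else is untouched. Idempotent.
#'
#' @param quant Quant tibble (`protein_id` + sample columns).
#' @param floor Intensity threshold; values `< floor` are censored.
#' @return Quant tibble with stage `"raw-filtered"`.
#' @export
floor_filter <- function(quant, floor = 1e4) {
  stopifnot(is.numeric(floor), length(floor) == 1, floor > 0)
  m <- profile_matrix(quant)
  m[!is.finite(m)] <- NA_real_
  m[m < floor] <- NA_real_
  tidy_matrix(m, stage = "raw-filtered")
}

#' Drop samples without any retained intensity
#'
#' After floor filtering, a slice may carry no quantifiable protein at all
#' (lost or empty section). Such samples are removed from the matrix and
#' the annotation; `total_intensity` is recomputed from the floored matrix
#' (missing treated as 0) for all retained samples.
#'
#' @param quant Floored quant tibble.
#' @param annotation Annotation tibble with a `sample_id` column.
#' @return List with updated `quant` and `annotation`; relative sample
#'   order is preserved. Dropped samples are reported via `message()`.
#' @export
drop_empty_samples <- function(quant, annotation) {
  m <- profile_matrix(quant)
  stopifnot(all(colnames(m) %in% annotation$sample_id))
  totals <- colSums(m, na.rm = TRUE)
  keep <- totals > 0
  if (!any(keep)) {
    stop("no usable slices: every sample is empty after floor filtering",
         call. = FALSE)
  }
  if (any(!keep)) {
    message("dropping ", sum(!keep), " empty sample(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  ann$total_intensity <- unname(totals)
  ann <- ann[keep, , drop = FALSE]
  quant <- tidy_matrix(m[, keep, drop = FALSE], stage = profile_stage(quant))
  list(quant = quant, annotation = tibble::as_tibble(ann))
}

#' Variance-stabilizing normalization (robust affine calibration + glog)
#'
#' Per-sample calibration followed by a generalized-log transform reported
#' on the log2 scale. For each sample a positive scale factor `s_j` is
#' estimated by a least-trimmed-squares style iteration on the log2 ratios
#' to a reference profile of per-protein median intensities (each round
#' keeps the `1 - trim` fraction of proteins closest to the current
#' estimate) — this assumes most proteins are non-differential between
#' neighboring sections. No additive offset is estimated: protein-group
#' intensities carry no additive background, and fixing the offset at zero
#' keeps the calibration identifiable on heavy-tailed abundances.
#' Calibrated intensities `z = x/s_j` are then transformed with the
#' arsinh-based generalized log
#' \deqn{h(z) = \log_2\!\big((z + \sqrt{z^2 + c^2})/2\big),}
#' which is finite at low and negative values and converges to
#' `log2(z)` for `z >> c`, so high-intensity values keep their ordinary
#' log2 interpretation.
#'
#' @param quant Floored quant tibble.
#' @param trim Trimming fraction of the robust calibration (default 0.1).
#' @param glog_c Glog softening constant on the calibrated intensity
#'   scale; defaults to the default detection floor (`1e4`), where the
#'   transform bends from linear to logarithmic.
#' @param iterations Trimmed-refit iterations.
#' @return Profile tibble on the log2-like scale, stage `"normalized"`.
#'   Calibration parameters are attached as attribute `"calibration"`
#'   (tibble: `sample_id`, `offset`, `scale`).
#' @export
vst_normalize <- function(quant, trim = 0.1, glog_c = 1e4, iterations = 5) {
  m <- profile_matrix(quant)
  if (ncol(m) < 2) stop("need at least 2 samples to calibrate", call. = FALSE)
  if (nrow(m) < 42) {
    warning("fewer than 42 proteins; robust calibration may be unstable",
            call. = FALSE)
  }
  # geometric-mean reference profile (per-protein), so rescaling any one
  # sample perturbs every log-ratio by the same small uniform amount
  lm2 <- suppressWarnings(log2(m))
  lm2[!is.finite(lm2)] <- NA
  ref <- 2^rowMeans(lm2, na.rm = TRUE)
  cal <- lapply(seq_len(ncol(m)), function(j) {
    trimmed_scale_fit(x = m[, j], ref = ref, trim = trim,
                      iterations = iterations, sample_id = colnames(m)[j])
  })
  cal <- dplyr::bind_rows(cal)
  out <- m
  for (j in seq_len(ncol(m))) {
    z <- (m[, j] - cal$offset[j]) / cal$scale[j]
    out[, j] <- glog2(z, c = glog_c)
  }
  res <- tidy_matrix(out, stage = "normalized")
  attr(res, "calibration") <- cal
  res
}

#' Simple log2 normalization with median centering
#'
#' Fallback normalization: `log2(x)` with each sample shifted so its
#' median matches the grand median. Use when the robust glog calibration
#' is not wanted or fails to converge.
#'
#' @inheritParams vst_normalize
#' @return Profile tibble, stage `"normalized"`.
#' @export
log2_median_normalize <- function(quant) {
  m <- log2(profile_matrix(quant))
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  m <- sweep(m, 2, med - mean(med), "-")
  tidy_matrix(m, stage = "normalized")
}

#' Normalize a floored quant table
#'
#' Dispatcher over the two normalization strategies.
#'
#' @inheritParams vst_normalize
#' @param method `"vst"` (robust affine + glog) or `"log2-median"`.
#' @export
normalize_quant <- function(quant, method = c("vst", "log2-median"),
                            trim = 0.1, glog_c = 1e4) {
  method <- match.arg(method)
  switch(method,
         "vst" = vst_normalize(quant, trim = trim, glog_c = glog_c),
         "log2-median" = log2_median_normalize(quant))
}

#' Correct profiles for per-slice total protein input
#'
#' Serial sections shrink toward the tendon, so total protein input varies
#' several-fold along the axis; label-free normalization cannot absorb
#' this. Subtracting `log2(total_intensity)` per sample makes every profile
#' relative to the slice's total protein input.
#'
#' @param profile Normalized profile tibble.
#' @param annotation Annotation with `sample_id` and `total_intensity`
#'   (computed from the raw floored intensities, missing treated as 0).
#' @return Profile tibble, same stage, input-corrected.
#' @export
total_intensity_correct <- function(profile, annotation) {
  m <- profile_matrix(profile)
  idx <- match(colnames(m), annotation$sample_id)
  stopifnot(!anyNA(idx))
  totals <- annotation$total_intensity[idx]
  stopifnot(all(totals > 0))
  m <- sweep(m, 2, log2(totals), "-")
  out <- tidy_matrix(m, stage = profile_stage(profile))
  attr(out, "calibration") <- attr(profile, "calibration")
  out
}

# --- internals ---------------------------------------------------------------

# Deterministic least-trimmed-squares style scale fit on the log scale.
# The per-sample log2 ratios to the reference profile are summarized by the
# mean of their (1 - trim) fraction with the smallest squared deviation from
# the current estimate, iterated; a pure per-sample scaling of the raw data
# is therefore absorbed exactly. Protein abundances span orders of
# magnitude, so the fit lives on the log scale; no additive offset is
# estimated (protein-group intensities carry no additive background), which
# keeps the calibration identifiable on small data.
trimmed_scale_fit <- function(x, ref, trim, iterations, sample_id) {
  ok <- is.finite(x) & is.finite(ref) & x > 0 & ref > 0
  lr <- log2(x[ok]) - log2(ref[ok])
  n <- length(lr)
  if (n == 0) {
    stop("robust calibration has no shared finite values for sample '",
         sample_id, "'; consider normalize_quant(method = \"log2-median\")",
         call. = FALSE)
  }
  delta <- stats::median(lr)
  keep_n <- max(1, ceiling((1 - trim) * n))
  for (it in seq_len(iterations)) {
    keep <- order((lr - delta)^2)[seq_len(keep_n)]
    delta_new <- mean(lr[keep])
    if (!is.finite(delta_new)) break
    if (abs(delta_new - delta) < 1e-12) { delta <- delta_new; break }
    delta <- delta_new
  }
  if (!is.finite(delta)) {
    stop("robust calibration did not converge for sample '", sample_id,
         "'; consider normalize_quant(method = \"log2-median\")",
         call. = FALSE)
  }
  tibble::tibble(sample_id = sample_id, offset = 0, scale = 2^delta)
}

# arsinh-based generalized log on the log2 scale; h(z) -> log2(z) as z >> c
glog2 <- function(z, c) {
  log2((z + sqrt(z^2 + c^2)) / 2)
}
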