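#' Relative axis positions within each replicate
#'
#' Maps each replicate's slice indices onto `[0, 1]`:
#' `perc = (slice - min) / (max - min)`. Replicates of different physical
#' length thereby share a common relative axis; the aligned position
#' `perc2` is initialized to `perc` and later adjusted by
#' [median_shift_and_apply()].
#'
#' @param annotation Annotation tibble with `replicate` and `slice`.
#' @return Annotation tibble with `perc` and `perc2` columns added.
#' @export
relative_positions <- function(annotation) {
  ann <- dplyr::group_by(annotation, .data$replicate)
  ann <- dplyr::mutate(
    ann,
    perc = {
      rng <- range(.data$slice)
      if (diff(rng) == 0) {
        stop("replicate '", .data$replicate[1],
             "' has a single slice; cannot compute relative positions",
             call. = FALSE)
      }
      (.data$slice - rng[1]) / (rng[2] - rng[1])
    }
  )
  ann <- dplyr::ungroup(ann)
  ann$perc2 <- ann$perc
  ann
}

#' Smooth one profile onto a dense uniform grid
#'
#' Local polynomial regression (degree 2, tricube weights) of a protein's
#' values against relative axis position, evaluated on `grid_n` uniformly
#' spaced points in `[0, 1]`. Positions outside the observed data range
#' yield `NA` — no extrapolation.
#'
#' @param values Numeric profile values of one replicate.
#' @param positions Relative positions (`perc`) of the same samples.
#' @param grid_n Grid size (default 5000).
#' @param span Loess span (fraction of points per local fit, default
#'   0.75); smaller spans follow the data more closely.
#' @return Numeric vector of length `grid_n`.
#' @export
smooth_to_grid <- function(values, positions, grid_n = 5000, span = 0.75) {
  ok <- is.finite(values) & is.finite(positions)
  if (sum(ok) < 4) {
    stop("need at least 4 observed points to smooth", call. = FALSE)
  }
  df <- data.frame(x = positions[ok], y = values[ok])
  fit <- tryCatch(
    stats::loess(y ~ x, data = df, span = span, degree = 2,
                 family = "gaussian"),
    error = function(e) stop("loess failed (", conditionMessage(e),
                             "); increase span or add points", call. = FALSE))
  grid <- seq(0, 1, length.out = grid_n)
  as.numeric(stats::predict(fit, newdata = data.frame(x = grid)))
}

#' Best fractional shift between two smoothed profiles (lag scan)
#'
#' Scans negative lags `-floor(grid_n/2) ... -1`: at lag `-k` the trailing
#' `grid_n - k` points of one profile are correlated with the leading
#' `grid_n - k` points of the other, in both pairing directions. Direction
#' `"up"` slides `g2` leftward under `g1` (detects `g2` features occurring
#' *earlier* than in `g1`); direction `"lo"` slides `g1` under `g2`
#' (detects `g2` features occurring *later*). The reported shift for each
#' direction is the grid value at index `k*` of its best-correlating lag,
#' i.e. `(k* - 1)/(grid_n - 1)`, bounded by 0.5. Ties in correlation break
#' toward the smallest `|lag|` (least deformation). Lags whose overlap has
#' zero variance are skipped.
#'
#' @param g1,g2 Dense profiles on the common `[0, 1]` grid (equal length).
#' @return Tibble with one row per direction (`"lo"`, `"up"`): `shift`,
#'   `corr`, `lag`.
#' @export
pairwise_best_shift <- function(g1, g2) {
  n <- length(g1)
  stopifnot(length(g2) == n, n >= 8)
  kmax <- floor(n / 2)
  grid <- seq(0, 1, length.out = n)
  cor_up <- cor_lo <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    len <- n - k
    t1 <- g1[(k + 1):n]; t2 <- g2[1:len]       # up: g1 trailing vs g2 leading
    t3 <- g2[(k + 1):n]; t4 <- g1[1:len]       # lo: g2 trailing vs g1 leading
    cor_up[k] <- safe_cor(t1, t2)
    cor_lo[k] <- safe_cor(t3, t4)
  }
  best <- function(cv) {
    if (all(is.na(cv))) return(c(NA_integer_, NA_real_))
    k <- which.max(cv)    # k ascending = |lag| ascending: ties -> smallest
    c(k, cv[k])
  }
  b_lo <- best(cor_lo); b_up <- best(cor_up)
  tibble::tibble(
    direction = c("lo", "up"),
    shift = c(grid[b_lo[1]], grid[b_up[1]]),
    corr = c(b_lo[2], b_up[2]),
    lag = c(-b_lo[1], -b_up[1])
  )
}

#' Per-marker fractional shifts for all replicate pairs
#'
#' For every marker protein and every replicate pair (reference first),
#' smooths both replicate profiles onto the common grid and runs the lag
#' scan in both directions.
#'
#' @param profile Complete profile tibble (post-imputation).
#' @param annotation Annotation with `sample_id`, `replicate`, `perc`.
#' @param markers Character vector of marker protein ids (see
#'   [marker_proteins()]).
#' @param reference_replicate Replicate label anchoring the alignment.
#' @param grid_n,span Passed to [smooth_to_grid()].
#' @return Tibble `protein_id`, `rep_a`, `rep_b`, `direction`, `shift`,
#'   `corr` (`rep_a` is the reference in reference-anchored pairs).
#' @export
estimate_marker_shifts <- function(profile, annotation, markers,
                                   reference_replicate,
                                   grid_n = 5000, span = 0.75) {
  m <- profile_matrix(profile)
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  reps <- unique(ann$replicate)
  if (!reference_replicate %in% reps) {
    stop("reference replicate not found: '", reference_replicate, "'",
         call. = FALSE)
  }
  reps <- c(reference_replicate, setdiff(reps, reference_replicate))
  pairs <- utils::combn(reps, 2)
  markers <- intersect(markers, rownames(m))
  if (length(markers) < 3) {
    stop("need at least 3 marker proteins with profiles (got ",
         length(markers), ")", call. = FALSE)
  }
  res <- list()
  for (p in markers) {
    grids <- lapply(reps, function(r) {
      sel <- ann$replicate == r
      smooth_to_grid(m[p, sel], ann$perc[sel], grid_n = grid_n, span = span)
    })
    names(grids) <- reps
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      bs <- pairwise_best_shift(grids[[a]], grids[[b]])
      bs$protein_id <- p; bs$rep_a <- a; bs$rep_b <- b
      res[[length(res) + 1]] <- bs
    }
  }
  out <- dplyr::bind_rows(res)
  out[c("protein_id", "rep_a", "rep_b", "direction", "shift", "corr", "lag")]
}

#' Median shift per pair and application to the axis
#'
#' Takes the median of the per-marker shifts for each (pair, direction);
#' for every pair anchored at the reference, the direction with the larger
#' median shift wins, and the non-reference replicate's `perc` is moved by
#' `-shift` if `"lo"` wins (its features occur later than the reference's,
#' so it is pulled back) or `+shift` if `"up"` wins. The reference is
#' unchanged. The result is stored as `perc2`.
#'
#' @param shifts Output of [estimate_marker_shifts()].
#' @param annotation Annotation with `perc` (and `perc2`).
#' @param reference_replicate Reference replicate label.
#' @return An object of class `slicewise_alignment`: list with
#'   `annotation` (with updated `perc2`), `median_shifts` (tibble per
#'   pair/direction), `per_protein` (the input shifts), `reference`.
#' @export
median_shift_and_apply <- function(shifts, annotation, reference_replicate) {
  if (length(unique(shifts$protein_id)) < 3) {
    stop("need shifts from at least 3 marker proteins", call. = FALSE)
  }
  med <- dplyr::summarise(
    dplyr::group_by(shifts, .data$rep_a, .data$rep_b, .data$direction),
    shift = stats::median(.data$shift, na.rm = TRUE),
    corr = stats::median(.data$corr, na.rm = TRUE),
    .groups = "drop")
  ref_pairs <- med[med$rep_a == reference_replicate |
                   med$rep_b == reference_replicate, , drop = FALSE]
  if (nrow(ref_pairs) == 0) {
    stop("reference replicate not found in any pair", call. = FALSE)
  }
  ann <- annotation
  if (!"perc2" %in% names(ann)) ann$perc2 <- ann$perc
  for (key in unique(paste(ref_pairs$rep_a, ref_pairs$rep_b))) {
    sub <- ref_pairs[paste(ref_pairs$rep_a, ref_pairs$rep_b) == key, ,
                     drop = FALSE]
    other <- setdiff(c(sub$rep_a[1], sub$rep_b[1]), reference_replicate)
    win <- sub[which.max(sub$shift), , drop = FALSE]
    delta <- if (win$direction == "lo") -win$shift else win$shift
    sel <- ann$replicate == other
    ann$perc2[sel] <- ann$perc[sel] + delta
  }
  structure(list(annotation = ann, median_shifts = med,
                 per_protein = shifts, reference = reference_replicate),
            class = "slicewise_alignment")
}

#' Final z-scaled (and 0-1 ranged) profile matrices
#'
#' Produces the two final dataset variants used downstream: (1) each
#' protein centered and scaled to unit variance *within each replicate*
#' (so replicate-specific offsets and amplitudes drop out) and (2) the
#' same additionally mapped per protein to `[0, 1]` across all samples
#' (`(x - min)/(max - min)`). Columns are ordered by (replicate, perc2).
#' Proteins with zero variance within some replicate have an undefined
#' z-score and are dropped with a warning.
#'
#' @param profile Complete profile tibble.
#' @param annotation Annotation with `replicate` and `perc2` (control
#'   samples, if flagged via `is_control`, are removed first).
#' @return List with `z` (stage `"final-z"`), `zr` (stage
#'   `"final-z-range"`) and the column-ordered `annotation`.
#' @export
finalize_profiles <- function(profile, annotation) {
  ann <- annotation
  if ("is_control" %in% names(ann) && any(ann$is_control)) {
    ann <- ann[!ann$is_control, , drop = FALSE]
  }
  if (!"perc2" %in% names(ann)) ann$perc2 <- ann$perc
  ann <- ann[order(ann$replicate, ann$perc2), , drop = FALSE]
  m <- profile_matrix(profile)[, ann$sample_id, drop = FALSE]
  if (anyNA(m)) stop("finalize requires a complete matrix", call. = FALSE)

  z <- m
  for (r in unique(ann$replicate)) {
    sel <- ann$replicate == r
    block <- m[, sel, drop = FALSE]
    mu <- rowMeans(block)
    sdev <- apply(block, 1, stats::sd)
    z[, sel] <- (block - mu) / sdev
  }
  bad <- !stats::complete.cases(z) | apply(z, 1, function(x) any(!is.finite(x)))
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " protein(s) with zero variance within a replicate: ",
            paste(utils::head(rownames(z)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", call. = FALSE)
    z <- z[!bad, , drop = FALSE]
  }
  zr <- t(apply(z, 1, range01))
  dimnames(zr) <- dimnames(z)
  list(z = tidy_matrix(z, stage = "final-z"),
       zr = tidy_matrix(zr, stage = "final-z-range"),
       annotation = tibble::as_tibble(ann))
}

# --- internals ---------------------------------------------------------------

range01 <- function(x) (x - min(x)) / (max(x) - min(x))

safe_cor <- function(a, b, method = "pearson") {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}
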