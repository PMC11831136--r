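#' Simulate a serial-section proteomics experiment with known truth
#'
#' Generates a raw wide quantification table emulating what serial
#' cryosectioning of a muscle-tendon sample produces upstream:
#'
#' * smooth spatial abundance trends along the slice axis, drawn from four
#'   archetype families — a sigmoid crossing a junction position (the
#'   muscle-to-tendon transition), a gaussian bump, a linear ramp, and a
#'   flat profile;
#' * per-slice loading decay: the section area shrinks toward the tendon
#'   (from roughly 1.7 mm^2 down to ~0.2 mm^2), so total protein input
#'   falls along the axis for every protein alike;
#' * base abundances spanning ~4 orders of magnitude (log-normal), as in
#'   high-dynamic-range tissue;
#' * intensity-dependent (MNAR) dropout via a logistic in log-intensity,
#'   with its midpoint near the detection floor so the floor filter is
#'   exercised, plus uniform (MCAR) masking;
#' * replicate-specific axis offsets (biological stretch/compression) and
#'   lengths.
#'
#' Raw cell values are
#' `2^(archetype(perc + offset) + noise) * loading(perc) * base`.
#' Everything is reconstructable from the returned truth plus the seed.
#'
#' @param n_proteins Number of proteins (>= 10; default 120).
#' @param n_slices Integer vector, sections per replicate (each >= 12;
#'   default three replicates of 60 — three animals, desk-scale).
#' @param replicate_offsets Per-replicate axis shift on the relative scale
#'   (default `c(0, 0.05, -0.08)`; recycled/truncated to the number of
#'   replicates).
#' @param noise_sd Log2-scale measurement noise sd (default 0.25).
#' @param loading_decay Log2 drop of the loading curve from first to last
#'   slice (default 3, i.e. 8-fold, matching the ~1.7 -> 0.2 mm^2 area
#'   decline).
#' @param base_mean,base_sd Mean and sd of the log2 base abundance
#'   (defaults 20 and 3.3: ~4 orders of magnitude across +-2 sd).
#' @param amplitude Log2 amplitude of the non-flat archetypes (default 3).
#' @param mnar_mid,mnar_scale Midpoint (intensity units) and scale (log2
#'   units) of the logistic MNAR dropout (defaults 1.5e4 and 1).
#' @param mcar_rate Uniform random masking rate (default 0.02).
#' @param archetype_probs Probabilities of (sigmoid, bump, ramp, flat)
#'   (default `c(0.3, 0.2, 0.2, 0.3)`).
#' @param seed Integer seed; the run is deterministic given it.
#' @return List with `quant` (raw quant tibble, sample names
#'   `PG.Quant_R<r>_slice<k>`), `annotation`, and `truth` (list with the
#'   drawn archetype parameters, offsets, loading curve, masked cells and
#'   the seed; serializable with [write_truth()]).
#' @export
simulate_sections <- function(n_proteins = 120,
                              n_slices = c(60, 60, 60),
                              replicate_offsets = c(0, 0.05, -0.08),
                              noise_sd = 0.25,
                              loading_decay = 3,
                              base_mean = 20, base_sd = 3.3,
                              amplitude = 3,
                              mnar_mid = 1.5e4, mnar_scale = 1,
                              mcar_rate = 0.02,
                              archetype_probs = c(0.3, 0.2, 0.2, 0.3),
                              seed = 1L) {
  stopifnot(n_proteins >= 10, all(n_slices >= 12), noise_sd >= 0,
            mcar_rate >= 0, mcar_rate < 1, amplitude >= 0)
  set.seed(seed)
  n_rep <- length(n_slices)
  reps <- paste0("R", seq_len(n_rep))
  offsets <- rep_len(replicate_offsets, n_rep)

  kinds <- sample(c("sigmoid", "bump", "ramp", "flat"), n_proteins,
                  replace = TRUE, prob = archetype_probs)
  arch <- tibble::tibble(
    protein_id = sprintf("P%04d", seq_len(n_proteins)),
    kind = kinds,
    center = stats::runif(n_proteins, 0.25, 0.75),
    width = stats::runif(n_proteins, 0.05, 0.15),
    sign = sample(c(-1, 1), n_proteins, replace = TRUE),
    base_log2 = stats::rnorm(n_proteins, base_mean, base_sd)
  )

  cols <- list(); ann <- list(); truth_cells <- list()
  for (r in seq_len(n_rep)) {
    ns <- n_slices[r]
    slice <- seq_len(ns)
    perc <- (slice - 1) / (ns - 1)
    pos <- perc + offsets[r]
    loading_log2 <- -loading_decay * perc
    prof <- vapply(seq_len(n_proteins), function(i) {
      archetype_value(arch$kind[i], pos, arch$center[i], arch$width[i],
                      arch$sign[i], amplitude)
    }, numeric(ns))           # ns x n_proteins
    noise <- matrix(stats::rnorm(ns * n_proteins, 0, noise_sd),
                    nrow = ns)
    log2_int <- t(prof + noise) +
      matrix(arch$base_log2, n_proteins, ns) +
      matrix(loading_log2, n_proteins, ns, byrow = TRUE)
    intensity <- 2^log2_int
    # MNAR: logistic dropout in log2 intensity around the floor
    p_drop <- stats::plogis((log2(mnar_mid) - log2_int) / mnar_scale)
    mnar <- matrix(stats::runif(length(p_drop)) < p_drop, n_proteins, ns)
    mcar <- matrix(stats::runif(length(p_drop)) < mcar_rate, n_proteins, ns)
    masked <- mnar | mcar
    intensity[masked] <- NA_real_
    ids <- sprintf("PG.Quant_%s_slice%d", reps[r], slice)
    colnames(intensity) <- ids
    cols[[r]] <- intensity
    ann[[r]] <- tibble::tibble(sample_id = ids, replicate = reps[r],
                               slice = slice)
    truth_cells[[r]] <- which(masked, arr.ind = TRUE)
  }
  values <- do.call(cbind, cols)
  rownames(values) <- arch$protein_id
  annotation <- dplyr::bind_rows(ann)
  annotation$total_intensity <- colSums(values, na.rm = TRUE)
  annotation$is_control <- FALSE

  truth <- list(
    archetypes = arch,
    replicate_offsets = stats::setNames(as.list(offsets), reps),
    n_slices = stats::setNames(as.list(as.integer(n_slices)), reps),
    noise_sd = noise_sd, loading_decay = loading_decay,
    mnar_mid = mnar_mid, mnar_scale = mnar_scale, mcar_rate = mcar_rate,
    masked_cells = lapply(truth_cells, function(x)
      tibble::as_tibble(as.data.frame(x))),
    seed = seed
  )
  list(quant = tidy_matrix(values), annotation = annotation, truth = truth)
}

#' Plant a chain of delayed profile copies
#'
#' Builds shifted copies of a base profile with independent noise so that
#' delay-network recovery can be checked against known pairwise delays:
#' copy `k` is the base profile shifted right by `delays[k]` grid
#' positions (edge-held), so the true delay between copies `i` and `j` is
#' `delays[j] - delays[i]`. Shifts of order half the profile length leave
#' too little overlap for recovery and are not guaranteed.
#'
#' @param base_profile Numeric base profile.
#' @param delays Integer shifts, one per copy (0 = duplicate).
#' @param noise_sd Independent noise sd added per copy (default 0.02).
#' @param seed Optional seed.
#' @return Matrix (copies x positions) with rownames `D<shift>_<k>`; the
#'   true pairwise delays are attached as attribute `"true_delays"`
#'   (tibble `a`, `b`, `delay` with the [best_delays()] sign convention:
#'   negative when `b` trails `a`).
#' @export
plant_delay_chain <- function(base_profile, delays, noise_sd = 0.02,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(base_profile)
  stopifnot(all(abs(delays) < n))
  copies <- vapply(seq_along(delays), function(k) {
    shift_profile(base_profile, delays[k]) +
      stats::rnorm(n, 0, noise_sd)
  }, numeric(n))
  copies <- t(copies)
  rownames(copies) <- sprintf("D%d_%d", delays, seq_along(delays))
  colnames(copies) <- sprintf("g%03d", seq_len(n))
  cmb <- utils::combn(seq_along(delays), 2)
  attr(copies, "true_delays") <- tibble::tibble(
    a = rownames(copies)[cmb[1, ]],
    b = rownames(copies)[cmb[2, ]],
    delay = -(delays[cmb[2, ]] - delays[cmb[1, ]])
  )
  copies
}

#' Serialize simulation truth as JSON
#'
#' @param truth Truth list from [simulate_sections()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# --- internals ---------------------------------------------------------------

# log2 relative abundance of an archetype at relative positions `pos`
archetype_value <- function(kind, pos, center, width, sign, amplitude) {
  switch(kind,
    sigmoid = sign * amplitude * stats::plogis((pos - center) / width),
    bump = sign * amplitude * exp(-(pos - center)^2 / (2 * width^2)),
    ramp = sign * amplitude * pos,
    flat = rep(0, length(pos)),
    stop("unknown archetype: ", kind))
}

# shift right by d (d >= 0) or left (d < 0), holding the edge value
shift_profile <- function(x, d) {
  n <- length(x)
  if (d == 0) return(x)
  if (d > 0) c(rep(x[1], d), x[1:(n - d)])
  else c(x[(1 - d):n], rep(x[n], -d))
}
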