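#' Quantitative trend scores along the slice axis (SAM-style d statistic)
#'
#' Scores every protein's abundance trend against a quantitative response
#' (the slice index) within one replicate, using the regression form of
#' the significance-analysis-of-microarrays statistic: per protein the
#' least-squares slope score
#' \deqn{r_i = \sum_j x_{ij}(y_j - \bar y) / \sum_j (y_j - \bar y)^2,}
#' its standard error \eqn{se_i = \sqrt{(RSS_i/(n-2)) / \sum_j (y_j-\bar y)^2}},
#' and \eqn{d_i = r_i / (se_i + s_0)} with an exchangeability (fudge)
#' factor `s0` shared by all proteins of the replicate. `s0` is chosen by
#' scanning the percentiles 0, 5, ..., 100 of the `se` distribution and
#' picking the candidate that minimizes the coefficient of variation of
#' the median absolute deviation of `d` computed within (up to) 100
#' quantile bins of `se`; this keeps `|d|` comparable across the
#' intensity/variance range and guards the zero-residual case.
#'
#' A permutation null is built from `nperms` seeded permutations of the
#' response (with `se` and `s0` recomputed per permutation), available via
#' `attr(, "null")` and used by [autoplot.slicewise_trend()] and the
#' calibration checks.
#'
#' @param profile Profile tibble with no missing cells (post-imputation).
#' @param response Numeric response per sample column (e.g. slice index);
#'   must have at least two distinct values.
#' @param nperms Number of permutations (default 1000).
#' @param seed Optional integer seed for the permutations.
#' @param s0 Optional fixed fudge factor; when `NULL` it is estimated as
#'   described above. `s0 = 0` gives the plain moderated-free score.
#' @param method `"sam"` (default) or `"tslope"`, the ordinary
#'   t-statistic of the slope (`s0` forced to 0).
#' @return An object of class `slicewise_trend`: a tibble with
#'   `protein_id`, `d`, `slope`, `se`, `s0`, plus attributes `null`
#'   (proteins x nperms matrix of permuted d) and `response`.
#' @export
sam_quant_scores <- function(profile, response, nperms = 1000, seed = NULL,
                             s0 = NULL, method = c("sam", "tslope")) {
  method <- match.arg(method)
  m <- profile_matrix(profile)
  y <- as.numeric(response)
  stopifnot(ncol(m) == length(y))
  if (ncol(m) < 4) stop("need at least 4 samples", call. = FALSE)
  if (length(unique(y)) < 2) stop("response must have >= 2 distinct values",
                                  call. = FALSE)
  if (anyNA(m)) stop("profile must be complete (impute first)", call. = FALSE)

  base <- slope_and_se(m, y)
  if (method == "tslope") {
    s0_use <- 0
  } else if (!is.null(s0)) {
    stopifnot(s0 >= 0)
    s0_use <- s0
  } else {
    s0_use <- choose_s0(base$slope, base$se)
  }
  d <- base$slope / (base$se + s0_use)

  null_mat <- NULL
  if (nperms > 0) {
    if (!is.null(seed)) set.seed(seed)
    null_mat <- vapply(seq_len(nperms), function(p) {
      yp <- sample(y)
      b <- slope_and_se(m, yp)
      b$slope / (b$se + s0_use)
    }, numeric(nrow(m)))
    dimnames(null_mat) <- list(rownames(m), NULL)
  }

  out <- tibble::tibble(protein_id = rownames(m), d = unname(d),
                        slope = unname(base$slope), se = unname(base$se),
                        s0 = s0_use)
  class(out) <- c("slicewise_trend", class(out))
  attr(out, "null") <- null_mat
  attr(out, "response") <- y
  attr(out, "method") <- method
  out
}

#' Combine per-replicate trend scores and pick alignment markers
#'
#' Proteins useful for aligning replicates must trend strongly *and*
#' consistently. For each protein scored in every replicate: `mean` is the
#' mean of the per-replicate d scores; `absdiff` is the absolute value of
#' the summed successive differences of d along `replicate_order` (which
#' telescopes to `|d_last - d_first|`); `fscore = mean / absdiff` ranks
#' strong consistent trends first. Proteins with `absdiff = 0` have an
#' undefined fscore and sort last. The marker set is `|mean| > 5`
#' (strict).
#'
#' @param scores A list of `slicewise_trend` objects (or tibbles with
#'   `protein_id` and `d`), one per replicate, or a single tibble with a
#'   `replicate` column.
#' @param replicate_order Order in which replicates enter the successive
#'   differences; defaults to the list names / order of appearance.
#' @param min_abs_mean Marker threshold on `|mean|` (default 5, strict).
#' @return Tibble `protein_id`, per-replicate d columns, `mean`,
#'   `absdiff`, `fscore`, `is_marker`, ordered by `|fscore|` decreasing
#'   (undefined fscores last).
#' @export
combine_scores <- function(scores, replicate_order = NULL, min_abs_mean = 5) {
  if (is.data.frame(scores)) {
    stopifnot("replicate" %in% names(scores))
    scores <- split(scores[c("protein_id", "d")], scores$replicate)
  }
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- paste0("rep", seq_along(scores))
  }
  replicate_order <- replicate_order %||% names(scores)
  stopifnot(setequal(replicate_order, names(scores)))
  scores <- scores[replicate_order]

  shared <- sort(Reduce(intersect, lapply(scores, function(s) s$protein_id)))
  dmat <- vapply(scores, function(s) s$d[match(shared, s$protein_id)],
                 numeric(length(shared)))
  dmat <- matrix(dmat, nrow = length(shared),
                 dimnames = list(shared, replicate_order))

  if (ncol(dmat) == 1) {
    warning("single replicate: absdiff undefined; markers fall back to |d| > ",
            min_abs_mean, call. = FALSE)
    out <- tibble::tibble(protein_id = shared, mean = dmat[, 1],
                          absdiff = NA_real_, fscore = NA_real_)
  } else {
    mean_d <- unname(rowMeans(dmat))
    absdiff <- unname(abs(apply(dmat, 1, function(x) sum(diff(x)))))
    fscore <- ifelse(absdiff == 0, NA_real_, mean_d / absdiff)
    out <- tibble::tibble(protein_id = shared, mean = mean_d,
                          absdiff = absdiff, fscore = fscore)
  }
  dcols <- tibble::as_tibble(as.data.frame(dmat))
  names(dcols) <- paste0("d_", replicate_order)
  out <- dplyr::bind_cols(out[1], dcols, out[-1])
  out$is_marker <- abs(out$mean) > min_abs_mean
  out[order(-abs(out$fscore), na.last = TRUE), , drop = FALSE]
}

#' Marker proteins from a combined score table
#'
#' @param combined Output of [combine_scores()].
#' @return Character vector of marker protein ids (|mean| strictly above
#'   the threshold used in [combine_scores()]).
#' @export
marker_proteins <- function(combined) {
  combined$protein_id[combined$is_marker]
}

# --- statistic internals -----------------------------------------------------

# Vectorized per-row least-squares slope and standard error of x ~ y.
slope_and_se <- function(m, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  slope <- as.numeric(m %*% yc) / syy
  rowmu <- rowMeans(m)
  sxx <- rowSums(m^2) - n * rowmu^2
  rss <- pmax(0, sxx - slope^2 * syy)
  se <- sqrt(rss / (n - 2) / syy)
  list(slope = stats::setNames(slope, rownames(m)),
       se = stats::setNames(se, rownames(m)))
}

# Fudge-factor selection: candidates are the 0,5,...,100 percentiles of se;
# the winner minimizes the CV of within-bin MADs of d over (<=100) quantile
# bins of se. Ties break toward the smaller s0.
choose_s0 <- function(slope, se, n_bins = 100) {
  cand <- unique(stats::quantile(se, probs = seq(0, 1, by = 0.05),
                                 names = FALSE))
  n_bins <- min(n_bins, max(1, length(se) %/% 2))
  breaks <- unique(stats::quantile(se, probs = seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 2) return(cand[1])
  bins <- cut(se, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- slope / (se + s0)
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[is.finite(mads)]
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(Inf)
    stats::sd(mads) / mu
  }, numeric(1))
  cand[which.min(cv)]
}
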