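#' Delay cross-correlation curve between two profiles
#'
#' Slides one profile against the other and correlates the overlapping
#' stretches: for every overlap `i` from `delayt` to `n`, the leading `i`
#' points of `x` are correlated with the trailing `i` points of `y`, and
#' vice versa. The two half-curves are concatenated (second reversed), the
#' duplicated zero-delay entry removed, and the result indexed by delay
#' `-D ... +D` with `D = n - delayt`. The `delayt` floor guards against
#' the spurious correlation -> 1 that occurs when the overlap shrinks
#' toward nothing. A *negative* delay at the maximum means `y`'s features
#' occur later (further along the axis) than `x`'s.
#'
#' @param x,y Equal-length complete numeric profiles (n >= 4).
#' @param delayt Minimum overlap; default `floor(0.45 * length(x))`.
#' @param method Correlation method, `"spearman"` (rank-based, default) or
#'   `"pearson"`.
#' @return An object of class `slicewise_delay_curve`: tibble with
#'   `delay` (integer) and `corr` (`NA` where an overlap had zero
#'   variance).
#' @export
delay_correlation <- function(x, y, delayt = floor(0.45 * length(x)),
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  delayt <- floor(delayt)
  if (delayt < 3) stop("delayt must be >= 3", call. = FALSE)
  if (delayt > n) stop("delayt cannot exceed the profile length", call. = FALSE)
  if (all(is.na(x)) || all(is.na(y))) stop("all-missing profile", call. = FALSE)
  overlaps <- delayt:n
  cor1 <- vapply(overlaps, function(i)
    safe_cor(x[1:i], y[(n - i + 1):n], method = method), numeric(1))
  cor2 <- vapply(overlaps, function(i)
    safe_cor(y[1:i], x[(n - i + 1):n], method = method), numeric(1))
  # cor1 runs delays -D..0, rev(cor2) runs 0..D; drop cor1's zero entry
  corr <- c(cor1[-length(cor1)], rev(cor2))
  D <- n - delayt
  out <- tibble::tibble(delay = seq.int(-D, D), corr = corr)
  class(out) <- c("slicewise_delay_curve", class(out))
  out
}

#' Best delay for every protein pair
#'
#' Enumerates all unordered protein pairs of the finalized profile matrix
#' and records, per pair, the delay at which the delay-correlation curve
#' is maximal (first maximum on ties, i.e. the most negative delay) and
#' that maximal correlation. Pairs whose whole curve is undefined are
#' dropped with a message. Results are independent of enumeration order
#' and worker count.
#'
#' @param profile Finalized profile tibble, columns ordered by
#'   (replicate, perc2).
#' @param delayt_fraction Minimum-overlap fraction of the profile length
#'   (default 0.45).
#' @param method Correlation method (see [delay_correlation()]).
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return Tibble `a`, `b`, `delay`, `corr` with one row per unordered
#'   pair.
#' @export
best_delays <- function(profile, delayt_fraction = 0.45,
                        method = c("spearman", "pearson"), workers = 1) {
  method <- match.arg(method)
  m <- profile_matrix(profile)
  if (nrow(m) < 2) stop("need at least 2 proteins", call. = FALSE)
  n <- ncol(m)
  delayt <- floor(delayt_fraction * n)
  cmb <- utils::combn(rownames(m), 2)
  one <- function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    cur <- delay_correlation(m[a, ], m[b, ], delayt = delayt, method = method)
    if (all(is.na(cur$corr))) {
      return(tibble::tibble(a = a, b = b, delay = NA_integer_,
                            corr = NA_real_))
    }
    k <- which.max(cur$corr)
    tibble::tibble(a = a, b = b, delay = cur$delay[k], corr = cur$corr[k])
  }
  idx <- seq_len(ncol(cmb))
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = workers)
  } else {
    lapply(idx, one)
  }
  res <- dplyr::bind_rows(res)
  dropped <- is.na(res$delay)
  if (any(dropped)) {
    message("dropping ", sum(dropped), " pair(s) with undefined delay curves")
    res <- res[!dropped, , drop = FALSE]
  }
  res
}

#' Build the directed delay network from best-delay pairs
#'
#' Keeps pairs with `-delay_limit < delay < delay_limit` (strict on both
#' sides), adds the reversed pair with negated delay, and retains only
#' edges with `delay >= 0`: an edge `A -> B` with delay `d` says A's
#' profile trails B's by `d` grid columns (A's features sit further along
#' the axis). Zero-delay pairs appear in both directions.
#'
#' @param pairs Tibble from [best_delays()].
#' @param delay_limit Strict upper bound on `|delay|` (default 20).
#' @param dpi_tolerance Default tolerance carried to [dpi_prune()].
#' @return An object of class `slicewise_network`: list with `edges`
#'   (tibble `source`, `target`, `delay`, `corr`), `nodes`,
#'   `dpi_tolerance`.
#' @export
build_directed_edges <- function(pairs, delay_limit = 20,
                                 dpi_tolerance = 0.1) {
  stopifnot(delay_limit > 0)
  nodes <- sort(unique(c(pairs$a, pairs$b)))
  keep <- pairs$delay > -delay_limit & pairs$delay < delay_limit
  kept <- pairs[keep, , drop = FALSE]
  both <- dplyr::bind_rows(
    tibble::tibble(source = kept$a, target = kept$b, delay = kept$delay,
                   corr = kept$corr),
    tibble::tibble(source = kept$b, target = kept$a, delay = -kept$delay,
                   corr = kept$corr))
  edges <- both[both$delay >= 0, , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  structure(list(edges = edges, nodes = nodes,
                 dpi_tolerance = dpi_tolerance),
            class = "slicewise_network")
}

#' Data-processing-inequality pruning of redundant edges
#'
#' A direct edge `x -> y` (delay `d`, correlation `c`) is redundant when
#' some intermediate `i` — an out-neighbor of `x` that is also an
#' in-neighbor of `y` in the *unpruned* graph — explains it: both leg
#' delays strictly positive, leg-delay sum `< d * (1 + tolerance)`, and
#' `|mean(leg correlations)| >= |c| - tolerance`. All edges are evaluated
#' against the original graph and removals applied once (single pass), so
#' the result does not depend on evaluation order. Nodes are never
#' removed. A negative current delay cannot occur after
#' [build_directed_edges()]; if encountered, the edge is kept and the
#' anomaly logged.
#'
#' @param net `slicewise_network` from [build_directed_edges()].
#' @param tolerance DPI tolerance fraction (default the network's
#'   `dpi_tolerance`).
#' @return A `slicewise_network` with the pruned edge set (subset of the
#'   input edges) and an added `n_pruned` field.
#' @export
dpi_prune <- function(net, tolerance = NULL) {
  stopifnot(inherits(net, "slicewise_network"))
  tolerance <- tolerance %||% net$dpi_tolerance
  e <- net$edges
  if (nrow(e) == 0) {
    net$n_pruned <- 0L
    return(net)
  }
  key <- paste(e$source, e$target, sep = "\r")
  delay_of <- stats::setNames(e$delay, key)
  corr_of <- stats::setNames(e$corr, key)
  out_nb <- split(e$target, e$source)
  in_nb <- split(e$source, e$target)
  redundant <- vapply(seq_len(nrow(e)), function(j) {
    x <- e$source[j]; y <- e$target[j]
    d <- e$delay[j]; cc <- e$corr[j]
    if (d < 0) {
      message("anomalous negative delay on edge ", x, "->", y, "; kept")
      return(FALSE)
    }
    inter <- setdiff(intersect(out_nb[[x]], in_nb[[y]]), c(x, y))
    if (length(inter) == 0) return(FALSE)
    d1 <- delay_of[paste(x, inter, sep = "\r")]
    d2 <- delay_of[paste(inter, y, sep = "\r")]
    c1 <- corr_of[paste(x, inter, sep = "\r")]
    c2 <- corr_of[paste(inter, y, sep = "\r")]
    any(d1 > 0 & d2 > 0 & (d1 + d2) < d * (1 + tolerance) &
          abs((c1 + c2) / 2) >= abs(cc) - tolerance, na.rm = TRUE)
  }, logical(1))
  net$edges <- e[!redundant, , drop = FALSE]
  net$n_pruned <- sum(redundant)
  net
}

#' Export a delay network for Cytoscape
#'
#' Writes the (pruned) edge list via [write_edge_list()], adding
#' `delay_inv = 1/(delay + 1)` so short delays plot as strong links.
#'
#' @param net `slicewise_network`.
#' @param path Output CSV path.
#' @param slice_thickness_um Optional section thickness; when given, a
#'   `delay_um` column (`delay * thickness`) is included.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, slice_thickness_um = NULL) {
  stopifnot(inherits(net, "slicewise_network"))
  edges <- net$edges
  if (!is.null(slice_thickness_um)) {
    edges$delay_um <- edges$delay * slice_thickness_um
  }
  write_edge_list(edges, path)
}

#' @export
print.slicewise_network <- function(x, ...) {
  cat("<slicewise_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges", sep = "")
  if (!is.null(x$n_pruned)) cat(" (", x$n_pruned, " pruned by DPI)", sep = "")
  cat("\n")
  invisible(x)
}
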