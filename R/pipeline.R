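#' Pipeline configuration
#'
#' Bundles and validates every tunable of the profile pipeline. Defaults
#' reproduce the reference analysis settings: 1e4 intensity floor, glog
#' normalization, an 11-slice window at a 70% data rate, 10/10 imputation
#' widths with `min_data_required = 3` and the global downshift pass, SAM
#' trend scores with 1000 permutations and a |mean| > 5 marker cut, a
#' 5000-point alignment grid at span 0.75, and a delay network with
#' minimum overlap 0.45, delay limit 20 and DPI tolerance 0.1.
#'
#' @param floor Intensity floor (see [floor_filter()]).
#' @param normalization `"vst"` or `"log2-median"`.
#' @param trim_fraction Robust calibration trimming fraction.
#' @param window_after,window_max_na_fraction Sliding-window filter
#'   settings (see [select_proteins()]); `window_after` is typically
#'   4-19 (5-20 sections).
#' @param impute_width_forward,impute_width_backward,impute_min_data,impute_fallback,impute_sel,impute_m_offset,impute_sd_offset
#'   Imputation settings (see [impute_by_distance()]).
#' @param downshift_sel Low-tail quantile of the global downshift pass.
#' @param sam_nperms,trend_method,marker_min_abs_mean Trend/marker
#'   settings (see [sam_quant_scores()], [combine_scores()]).
#' @param align_grid_n,align_span,reference_replicate Alignment settings
#'   (see [estimate_marker_shifts()]); `reference_replicate = NULL` means
#'   the first replicate.
#' @param delayt_fraction,delay_limit,dpi_tolerance,network_method,workers
#'   Network settings (see [best_delays()], [build_directed_edges()],
#'   [dpi_prune()]).
#' @param slice_thickness_um Optional physical thickness for reporting
#'   delays in micrometres.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated list of class `slicewise_config`.
#' @export
slicewise_config <- function(floor = 1e4,
                             normalization = c("vst", "log2-median"),
                             trim_fraction = 0.1,
                             window_after = 10,
                             window_max_na_fraction = 0.3,
                             impute_width_forward = 10,
                             impute_width_backward = 10,
                             impute_min_data = 3,
                             impute_fallback = c("none", "impute"),
                             impute_sel = 0.05,
                             impute_m_offset = 1.6,
                             impute_sd_offset = 0.8,
                             downshift_sel = 0.05,
                             sam_nperms = 1000,
                             trend_method = c("sam", "tslope"),
                             marker_min_abs_mean = 5,
                             align_grid_n = 5000,
                             align_span = 0.75,
                             reference_replicate = NULL,
                             delayt_fraction = 0.45,
                             delay_limit = 20,
                             dpi_tolerance = 0.1,
                             network_method = c("spearman", "pearson"),
                             workers = 1,
                             slice_thickness_um = NULL,
                             seed = 1L) {
  cfg <- list(
    floor = floor,
    normalization = match.arg(normalization),
    trim_fraction = trim_fraction,
    window_after = window_after,
    window_max_na_fraction = window_max_na_fraction,
    impute_width_forward = impute_width_forward,
    impute_width_backward = impute_width_backward,
    impute_min_data = impute_min_data,
    impute_fallback = match.arg(impute_fallback),
    impute_sel = impute_sel,
    impute_m_offset = impute_m_offset,
    impute_sd_offset = impute_sd_offset,
    downshift_sel = downshift_sel,
    sam_nperms = sam_nperms,
    trend_method = match.arg(trend_method),
    marker_min_abs_mean = marker_min_abs_mean,
    align_grid_n = align_grid_n,
    align_span = align_span,
    reference_replicate = reference_replicate,
    delayt_fraction = delayt_fraction,
    delay_limit = delay_limit,
    dpi_tolerance = dpi_tolerance,
    network_method = match.arg(network_method),
    workers = workers,
    slice_thickness_um = slice_thickness_um,
    seed = as.integer(seed)
  )
  stopifnot(cfg$floor > 0, cfg$trim_fraction >= 0, cfg$trim_fraction < 0.5,
            cfg$window_after >= 0,
            cfg$window_max_na_fraction >= 0, cfg$window_max_na_fraction <= 1,
            cfg$impute_min_data >= 1, cfg$impute_sel > 0, cfg$impute_sel < 1,
            cfg$sam_nperms >= 0, cfg$align_grid_n >= 100,
            cfg$align_span > 0, cfg$delayt_fraction > 0,
            cfg$delayt_fraction <= 1, cfg$delay_limit > 0,
            cfg$dpi_tolerance >= 0, cfg$workers >= 1)
  structure(cfg, class = "slicewise_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [slicewise_config()]; `overrides` (e.g.
#' command-line flags) win over file values.
#'
#' @param path YAML file path (`NULL` for defaults only).
#' @param overrides Named list of overriding values.
#' @return A `slicewise_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(slicewise_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(slicewise_config, vals)
}

#' Run the full profile-and-network pipeline
#'
#' Executes, in order: floor filter, empty-sample drop, normalization,
#' per-slice input correction (`preprocess`); sliding-window protein
#' selection (`filter`); distance-based + global downshift imputation
#' (`impute`); per-replicate trend scores and marker selection
#' (`markers`); relative positions, marker-shift estimation, median shift
#' application and finalization (`align`); delay correlation, directed
#' edges, DPI pruning (`network`). Each stage's output is kept in the
#' returned state, every stochastic stage uses a seed derived from the
#' master seed (so a run is bit-reproducible and a resumed run equals an
#' uninterrupted one), and a run log records parameters and per-stage
#' counts.
#'
#' @param quant Raw quant tibble (see [read_quant_table()] or
#'   [simulate_sections()]).
#' @param annotation Matching annotation tibble.
#' @param config A [slicewise_config()].
#' @param output_dir Optional directory; when given, intermediate and
#'   final artifacts are written there (TSV/CSV + JSON run log).
#' @param stop_after Optional stage name (`"preprocess"`, `"filter"`,
#'   `"impute"`, `"markers"`, `"align"`, `"network"`); the returned state
#'   can be passed back via `state` to resume.
#' @param state A previously returned (partial) state to resume from.
#' @return A list of class `slicewise_run` with the stage artifacts
#'   (`quant`, `annotation`, `normalized`, `selected`, `imputed`,
#'   `scores`, `combined`, `markers`, `alignment`, `final`, `pairs`,
#'   `network`, `pruned`, `edges`, `log`).
#' @export
run_pipeline <- function(quant, annotation, config = slicewise_config(),
                         output_dir = NULL, stop_after = NULL,
                         state = NULL) {
  stages <- c("preprocess", "filter", "impute", "markers", "align", "network")
  if (!is.null(stop_after)) stop_after <- match.arg(stop_after, stages)
  st <- state %||% list(quant = quant, annotation = annotation,
                        done = character(0), log = list(config = unclass(config)))
  seed_for <- function(stage) config$seed * 97L + match(stage, stages)

  run_stage <- function(name, fun) {
    if (name %in% st$done) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(ok),
           call. = FALSE)
    }
    st$done <<- c(st$done, name)
  }

  run_stage("preprocess", function() {
    q <- floor_filter(st$quant, floor = config$floor)
    de <- drop_empty_samples(q, st$annotation)
    keep <- !de$annotation$is_control
    if (!all(keep)) {
      de$quant <- de$quant[c(TRUE, keep)]
      de$annotation <- de$annotation[keep, , drop = FALSE]
    }
    norm <- normalize_quant(de$quant, method = config$normalization,
                            trim = config$trim_fraction)
    norm <- total_intensity_correct(norm, de$annotation)
    st$annotation <<- de$annotation
    st$normalized <<- norm
    st$log$n_samples <<- nrow(de$annotation)
    st$log$n_proteins_in <<- nrow(norm)
  })
  if (identical(stop_after, "preprocess")) return(finish_run(st, output_dir))

  run_stage("filter", function() {
    sel <- select_proteins(st$normalized, st$annotation,
                           after = config$window_after,
                           max_na_fraction = config$window_max_na_fraction)
    st$selected <<- sel
    st$log$n_proteins_selected <<- length(sel)
  })
  if (identical(stop_after, "filter")) return(finish_run(st, output_dir))

  run_stage("impute", function() {
    prof <- st$normalized[st$normalized$protein_id %in% st$selected, ]
    imp <- impute_by_distance(
      prof, st$annotation,
      width_forward = config$impute_width_forward,
      width_backward = config$impute_width_backward,
      min_data_required = config$impute_min_data,
      fallback = config$impute_fallback,
      sel = config$impute_sel, m_offset = config$impute_m_offset,
      sd_offset = config$impute_sd_offset,
      seed = seed_for("impute"))
    imp <- global_downshift_impute(imp, sel = config$downshift_sel,
                                   seed = seed_for("impute") + 1L)
    st$imputed <<- imp
    st$log$impute_counts <<- attr(imp, "impute_log")
  })
  if (identical(stop_after, "impute")) return(finish_run(st, output_dir))

  run_stage("markers", function() {
    ann <- st$annotation
    scores <- lapply(unique(ann$replicate), function(r) {
      sel <- ann$replicate == r
      cols <- c("protein_id", ann$sample_id[sel])
      sam_quant_scores(st$imputed[cols], response = ann$slice[sel],
                       nperms = config$sam_nperms,
                       seed = seed_for("markers"),
                       method = config$trend_method)
    })
    names(scores) <- unique(ann$replicate)
    comb <- combine_scores(scores, min_abs_mean = config$marker_min_abs_mean)
    st$scores <<- scores
    st$combined <<- comb
    st$markers <<- marker_proteins(comb)
    st$log$n_markers <<- length(st$markers)
  })
  if (identical(stop_after, "markers")) return(finish_run(st, output_dir))

  run_stage("align", function() {
    ref <- config$reference_replicate %||% unique(st$annotation$replicate)[1]
    ann <- relative_positions(st$annotation)
    shifts <- estimate_marker_shifts(st$imputed, ann, st$markers, ref,
                                     grid_n = config$align_grid_n,
                                     span = config$align_span)
    al <- median_shift_and_apply(shifts, ann, ref)
    st$alignment <<- al
    st$final <<- finalize_profiles(st$imputed, al$annotation)
    st$annotation <<- st$final$annotation
    st$log$median_shifts <<- al$median_shifts
  })
  if (identical(stop_after, "align")) return(finish_run(st, output_dir))

  run_stage("network", function() {
    pairs <- best_delays(st$final$zr,
                         delayt_fraction = config$delayt_fraction,
                         method = config$network_method,
                         workers = config$workers)
    net <- build_directed_edges(pairs, delay_limit = config$delay_limit,
                                dpi_tolerance = config$dpi_tolerance)
    pruned <- dpi_prune(net)
    st$pairs <<- pairs
    st$network <<- net
    st$pruned <<- pruned
    st$edges <<- pruned$edges
    st$log$n_edges_before <<- nrow(net$edges)
    st$log$n_edges_after <<- nrow(pruned$edges)
  })
  finish_run(st, output_dir)
}

finish_run <- function(st, output_dir) {
  class(st) <- "slicewise_run"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) readr::write_tsv(x, file.path(output_dir, name))
    if (!is.null(st$normalized)) wr(st$normalized, "normalized.tsv")
    if (!is.null(st$selected)) {
      wr(attr(st$selected, "scores"), "window_scores.tsv")
      writeLines(st$selected, file.path(output_dir, "selected_proteins.txt"))
    }
    if (!is.null(st$imputed)) wr(st$imputed, "imputed.tsv")
    if (!is.null(st$combined)) wr(st$combined, "trend_scores.tsv")
    if (!is.null(st$alignment)) {
      wr(st$alignment$per_protein, "alignment_shifts.tsv")
      wr(st$alignment$median_shifts, "alignment_median.tsv")
    }
    if (!is.null(st$final)) {
      wr(st$final$z, "final_z.tsv")
      wr(st$final$zr, "final_zr.tsv")
      wr(st$final$annotation, "annotation.tsv")
    }
    if (!is.null(st$pruned)) {
      export_network(st$pruned, file.path(output_dir, "network_edges.csv"))
    }
    log <- st$log
    log$r_version <- as.character(getRversion())
    log$package_version <- as.character(utils::packageVersion("slicewise"))
    log$stages_done <- st$done
    jsonlite::write_json(log, file.path(output_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  st
}

#' @export
print.slicewise_run <- function(x, ...) {
  cat("<slicewise_run> stages done:", paste(x$done, collapse = ", "), "\n")
  if (!is.null(x$log$n_proteins_selected)) {
    cat("  proteins selected:", x$log$n_proteins_selected, "of",
        x$log$n_proteins_in, "\n")
  }
  if (!is.null(x$markers)) cat("  alignment markers:", length(x$markers), "\n")
  if (!is.null(x$edges)) {
    cat("  network edges:", x$log$n_edges_before, "->", x$log$n_edges_after,
        "after DPI pruning\n")
  }
  invisible(x)
}
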