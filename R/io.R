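#' Read a wide protein-group quantification table
#'
#' Reads a quantification matrix as produced by DIA-NN post-processing
#' (one row per protein group, one column per section/slice sample) and
#' parses replicate and slice identity out of the sample column names.
#' Only the columns belonging to one quantity block (by default
#' `"PG.Quant"`) are retained.
#'
#' Sample-name parsing is regex-configurable. The defaults follow the
#' common `<block>_<replicate>_..slice<k>` convention: the replicate label
#' is the second underscore-separated token and the slice index is the
#' number following the last occurrence of `"slice"`.
#'
#' @param path Path to a delimited text file (`.csv`/`.tsv`/`.txt`) or an
#'   `.xlsx` workbook.
#' @param quant_prefix Prefix selecting the quantity block, e.g.
#'   `"PG.Quant"`. A column belongs to the block when its name starts with
#'   this prefix followed by a separator.
#' @param protein_col Candidate name(s) of the column holding protein-group
#'   identifiers; the first one present is used.
#' @param replicate_regex Regular expression with one capture group
#'   extracting the replicate label from a sample column name.
#' @param slice_regex Regular expression with one capture group extracting
#'   the (numeric) slice index from a sample column name.
#' @param sheet Sheet name or index for xlsx input (default first sheet).
#' @param control_regex Optional regular expression; matching sample columns
#'   are flagged as control/QC wells (`is_control = TRUE`) so downstream
#'   steps can exclude them (e.g. HEK digestion controls, blanks).
#'
#' @return A list with elements `quant` (a tibble: `protein_id` plus one
#'   column per sample, ordered by replicate then slice) and `annotation`
#'   (a tibble with `sample_id`, `replicate`, `slice`, `total_intensity`,
#'   `is_control`).
#' @export
read_quant_table <- function(path,
                             quant_prefix = "PG.Quant",
                             protein_col = c("Protein.Group", "protein_id"),
                             replicate_regex = "^[^_]+_([^_]+)_",
                             slice_regex = "slice([0-9]+(\\.[0-9]+)?)[^0-9]*$",
                             sheet = NULL,
                             control_regex = NULL) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read_table_any(path, sheet = sheet)
  protein_col <- intersect(protein_col, names(raw))[1]
  if (is.na(protein_col)) {
    stop("protein identifier column not found", call. = FALSE)
  }
  quant_cols <- grep(paste0("^", escape_regex(quant_prefix), "[._-]"),
                     names(raw), value = TRUE)
  if (length(quant_cols) == 0) {
    # the block name may be the full prefix of the column without separator
    quant_cols <- grep(paste0("^", escape_regex(quant_prefix)), names(raw),
                       value = TRUE)
  }
  if (length(quant_cols) == 0) {
    stop("no columns match quantity block '", quant_prefix, "'", call. = FALSE)
  }

  protein_ids <- as.character(raw[[protein_col]])
  if (anyDuplicated(protein_ids)) {
    stop("duplicate protein identifiers in '", protein_col, "'", call. = FALSE)
  }

  values <- as.matrix(raw[quant_cols])
  storage.mode(values) <- "double"
  if (any(values[is.finite(values)] < 0)) {
    stop("negative intensities found; raw quantification must be >= 0",
         call. = FALSE)
  }

  ann <- parse_sample_names(quant_cols, replicate_regex, slice_regex)
  ann$total_intensity <- unname(colSums(values, na.rm = TRUE))
  ann$is_control <- if (is.null(control_regex)) {
    FALSE
  } else {
    grepl(control_regex, ann$sample_id)
  }

  dup <- duplicated(ann[c("replicate", "slice")])
  if (any(dup)) {
    stop("duplicate (replicate, slice) pair for sample(s): ",
         paste(ann$sample_id[dup], collapse = ", "), call. = FALSE)
  }

  ord <- order(ann$replicate, ann$slice)
  ann <- ann[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]

  quant <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  quant <- dplyr::bind_cols(tibble::tibble(protein_id = protein_ids), quant)

  list(quant = quant, annotation = tibble::as_tibble(ann))
}

#' Write / read a quantification tibble as delimited text
#'
#' Plain CSV with `protein_id` in the first column; missing cells are
#' empty fields. `read(write(x))` round-trips finite values bit-identically
#' and preserves missingness.
#'
#' @param quant Tibble as returned in `read_quant_table()$quant`.
#' @param path Output path.
#' @return `path`, invisibly (`write_quant_table`); a tibble
#'   (`read_quant_matrix`).
#' @export
write_quant_table <- function(quant, path) {
  stopifnot(names(quant)[1] == "protein_id")
  readr::write_csv(quant, path, na = "")
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_matrix <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a directed delay edge list for Cytoscape import
#'
#' Writes the network edge table as an unquoted CSV whose first column is
#' the `"source-target"` edge identifier, followed by `source`, `target`,
#' `delay`, `corr` and `delay_inv` columns; this is the layout Cytoscape's
#' table import expects. `delay_inv = 1/(delay + 1)` is (re)computed on
#' write so it is always consistent with `delay`.
#'
#' @param edges Data frame with columns `source`, `target`, `delay`, `corr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.frame(edges)
  required <- c("source", "target", "delay", "corr")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_edges(edges)
  extra <- setdiff(names(edges), c(required, "delay_inv"))
  out <- edges[required]
  out$delay_inv <- 1 / (out$delay + 1)
  out <- cbind(out, edges[extra])
  rownames(out) <- paste(out$source, out$target, sep = "-")
  ok <- tryCatch({
    utils::write.csv(out, path, quote = FALSE, row.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write edge list to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param check Validate invariants after reading.
#' @return `read_edge_list()` returns a tibble with columns `edge_id`,
#'   `source`, `target`, `delay`, `corr`, `delay_inv`.
#' @export
read_edge_list <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1] <- "edge_id"
  df <- tibble::as_tibble(df)
  if (check && nrow(df)) {
    validate_edges(df)
    stopifnot(all(abs(df$delay_inv - 1 / (df$delay + 1)) < 1e-12))
  }
  df
}

validate_edges <- function(edges) {
  if (!nrow(edges)) return(invisible(edges))
  if (any(edges$delay < 0)) stop("edge delays must be >= 0", call. = FALSE)
  if (any(abs(edges$corr) > 1 + 1e-12, na.rm = TRUE)) {
    stop("edge correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  invisible(edges)
}

# --- internals ---------------------------------------------------------------

read_table_any <- function(path, sheet = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    return(readxl::read_xlsx(path, sheet = sheet %||% 1))
  }
  delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
  readr::read_delim(path, delim = delim, na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE)
}

parse_sample_names <- function(sample_ids, replicate_regex, slice_regex) {
  rep_m <- regmatches(sample_ids, regexec(replicate_regex, sample_ids))
  slice_m <- regmatches(sample_ids, regexec(slice_regex, sample_ids))
  replicate <- vapply(rep_m, function(m) if (length(m) >= 2) m[2] else NA_character_,
                      character(1))
  slice_chr <- vapply(slice_m, function(m) if (length(m) >= 2) m[2] else NA_character_,
                      character(1))
  bad_rep <- is.na(replicate)
  if (any(bad_rep)) {
    stop("cannot parse replicate from column(s): ",
         paste(sample_ids[bad_rep], collapse = ", "), call. = FALSE)
  }
  slice <- suppressWarnings(as.numeric(slice_chr))
  bad_slice <- is.na(slice)
  if (any(bad_slice)) {
    stop("cannot parse a numeric slice index from column(s): ",
         paste(sample_ids[bad_slice], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(sample_id = sample_ids, replicate = replicate, slice = slice)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert a quant/profile tibble (protein_id + sample columns) to a matrix
# with protein rownames; inverse of tidy_matrix().
profile_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), names(tbl)[1] == "protein_id")
  m <- as.matrix(tbl[-1])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$protein_id
  m
}

tidy_matrix <- function(m, stage = NULL) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)), out)
  if (!is.null(stage)) attr(out, "stage") <- stage
  out
}

#' Processing stage of a profile table
#'
#' Profile tibbles carry a `stage` attribute recording how far along the
#' pipeline they are (`"raw-filtered"`, `"normalized"`, `"imputed"`,
#' `"final-z"`, `"final-z-range"`).
#'
#' @param x A profile tibble.
#' @return The stage tag, or `NA` if none set.
#' @export
profile_stage <- function(x) attr(x, "stage") %||% NA_character_
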