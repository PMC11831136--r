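# Build a profile/quant tibble from a named matrix (proteins x samples).
tbl_profile <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)), out)
}

# Annotation for replicates with consecutive slices.
make_annotation <- function(n_slices, reps = paste0("R", seq_along(n_slices))) {
  dplyr::bind_rows(lapply(seq_along(n_slices), function(r) {
    tibble::tibble(
      sample_id = sprintf("PG.Quant_%s_slice%d", reps[r], seq_len(n_slices[r])),
      replicate = reps[r],
      slice = seq_len(n_slices[r])
    )
  }))
}

# Matrix with sample names matching make_annotation().
named_matrix <- function(values, n_proteins, annotation) {
  m <- matrix(values, nrow = n_proteins, ncol = nrow(annotation))
  rownames(m) <- sprintf("P%03d", seq_len(n_proteins))
  colnames(m) <- annotation$sample_id
  m
}

# Sharp sigmoid on [0, 1] (muscle-tendon junction archetype).
sigmoid01 <- function(x, center = 0.5, width = 0.08) {
  stats::plogis((x - center) / width)
}
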