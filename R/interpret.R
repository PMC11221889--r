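# Residue-level interpretability: min-max normalize the wild-type and
# mutant antigen x antibody mutual-attention maps, difference them, and
# renormalize; the result highlights amino-acid pairs whose attention
# changed upon mutation.

#' Whole-matrix min-max normalization
#'
#' `(x - min) / (max - min)` over all entries; a constant matrix maps to
#' all zeros (declared policy, so degenerate maps still render).
#'
#' @param W Non-empty finite numeric matrix.
#' @return Matrix of the same shape with values in [0, 1].
#' @export
minmax_norm <- function(W) {
  stopifnot(is.matrix(W), length(W) > 0L)
  if (!all(is.finite(W))) stop("non-finite entries", call. = FALSE)
  rng <- range(W)
  if (rng[1] == rng[2]) return(W * 0)
  (W - rng[1]) / (rng[2] - rng[1])
}

#' Attention-difference map between wild-type and mutant complexes
#'
#' Both maps are min-max normalized, the wild-type map is subtracted
#' from the mutant map, and the difference is min-max normalized again.
#' Because min-max normalization absorbs affine rescalings, the result
#' is invariant to any common positive affine transform of both inputs.
#'
#' @param W_wt,W_mt Equal-shape antigen x antibody attention maps
#'   (rows = antigen residues, columns = antibody residues).
#' @param row_labels,col_labels Optional residue labels (e.g. "Y32").
#' @param source Optional `(complex_id, mutation string)` provenance.
#' @return A `delta_map` with `values` in [0, 1] plus labels.
#' @export
attention_delta <- function(W_wt, W_mt, row_labels = NULL,
                            col_labels = NULL, source = NULL) {
  stopifnot(is.matrix(W_wt), is.matrix(W_mt))
  if (!all(dim(W_wt) == dim(W_mt)))
    stop("wild-type and mutant maps have different shapes", call. = FALSE)
  values <- minmax_norm(minmax_norm(W_mt) - minmax_norm(W_wt))
  if (is.null(row_labels)) row_labels <- as.character(seq_len(nrow(values)))
  if (is.null(col_labels)) col_labels <- as.character(seq_len(ncol(values)))
  stopifnot(length(row_labels) == nrow(values),
            length(col_labels) == ncol(values))
  structure(list(values = values, row_labels = row_labels,
                 col_labels = col_labels, source = source),
            class = "delta_map")
}

#' Residue labels ("Y32" style) for a sequence
#' @param seq Amino-acid string.
#' @return Character vector `letter + 1-based index` per residue.
#' @export
residue_labels <- function(seq) {
  chars <- assert_sequence(seq, "seq")
  paste0(chars, seq_along(chars))
}

#' Compute the attention-difference map for one mutation record
#'
#' Runs [predict_ddg()] on the record and applies [attention_delta()] to
#' the wild-type and mutant antigen x antibody maps.
#'
#' @param model A trained `ddg_model` (with `use_attention = TRUE`).
#' @param record A record from [dataset_record()].
#' @return A `delta_map` labeled with antigen (rows) and antibody
#'   (columns) residues.
#' @export
interpret_record <- function(model, record) {
  if (!model$config$use_attention)
    stop("the ablation variant has no attention maps", call. = FALSE)
  pr <- predict_ddg(model, featurize_record(record))
  attention_delta(
    pr$maps$wt, pr$maps$mt,
    row_labels = residue_labels(paste(record$ag_chains, collapse = "")),
    col_labels = residue_labels(paste(record$ab_chains, collapse = "")),
    source = c(record$complex_id, format_mutations(record$mutations)))
}

#' Export a delta map as TSV and heatmap image
#'
#' Writes `<path>.tsv` (rows = antigen residues with a leading label
#' column, columns = antibody residues) and `<path>.png`, drawn with the
#' antigen sequence on the x-axis and the antibody sequence on the
#' y-axis.
#'
#' @param map A `delta_map`.
#' @param path Output path prefix (extensions are appended).
#' @return Character vector of the two file paths, invisibly.
#' @export
export_heatmap <- function(map, path) {
  stopifnot(inherits(map, "delta_map"))
  tsv <- paste0(path, ".tsv")
  png_file <- paste0(path, ".png")
  df <- data.frame(residue = map$row_labels, map$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("residue", map$col_labels)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  # transpose so antigen runs along x and antibody along y
  m <- t(map$values)
  dimnames(m) <- list(map$col_labels, map$row_labels)
  grDevices::png(png_file, width = 200 + 12 * ncol(m),
                 height = 200 + 12 * nrow(m))
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     main = paste(map$source, collapse = " "))
  grDevices::dev.off()
  invisible(c(tsv = tsv, png = png_file))
}
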