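#' Per-cell periodic component of the reconstruction
#'
#' The part of each cell's reconstruction driven by the circular embedding:
#' `V_circular [cos x_n; sin x_n]`. Under the additive model this is the
#' estimated periodic (cell-cycle) effect on the standardized expression.
#'
#' @param model A `fitted_ca`.
#' @param m Standardized `expr_matrix` with matching genes.
#' @return N x G numeric matrix.
#' @export
circular_component <- function(model, m) {
  assert_standardized(m)
  assert_same_genes(model$gene_ids, m$gene_ids)
  emb <- encode_cells(m$values, model$encoder)
  decode_embedding(emb$circular, emb$linear, model$decoder,
                   parts = TRUE)$circular
}

#' Remove the periodic component from an expression matrix
#'
#' Subtracts [circular_component()] from the data. The operation consumes a
#' fitted model and does not refit, so it is a pure subtraction: the output
#' plus the component reproduces the input to machine precision. Linear
#' components of the model are deliberately not subtracted — they describe
#' non-periodic structure that should be preserved.
#'
#' @param m Standardized `expr_matrix`.
#' @param model A `fitted_ca` trained on the same gene universe.
#' @param destandardize Map the corrected values back to the log scale using
#'   the per-gene centers/scales stored by [standardize_genes()]?
#' @return An `expr_matrix` with `scale == "corrected"` (or `"log"` when
#'   `destandardize = TRUE`).
#' @export
remove_circular <- function(m, model, destandardize = FALSE) {
  comp <- circular_component(model, m)
  vals <- m$values - comp
  if (destandardize) {
    if (is.null(m$gene_center) || is.null(m$gene_scale))
      stop("matrix carries no gene_center/gene_scale; cannot destandardize")
    vals <- sweep(sweep(vals, 2, m$gene_scale, "*"), 2, m$gene_center, "+")
    expression_matrix(vals, m$cell_ids, m$gene_ids, scale = "log")
  } else {
    expression_matrix(vals, m$cell_ids, m$gene_ids, scale = "corrected",
                      gene_center = m$gene_center, gene_scale = m$gene_scale)
  }
}

#' Subtract designated principal components (linear baseline)
#'
#' The linear analogue of [remove_circular()]: back-transfers the selected
#' principal components to expression space and subtracts them. Uses the SVD
#' of the matrix as-is (standardized data is already column-centered).
#'
#' @param m Standardized `expr_matrix`.
#' @param pc_indices Integer indices of the components to remove.
#' @return An `expr_matrix` with `scale == "corrected"`.
#' @export
remove_pcs <- function(m, pc_indices) {
  assert_standardized(m)
  Y <- m$values
  r <- min(dim(Y))
  pc_indices <- as.integer(pc_indices)
  if (any(pc_indices < 1 | pc_indices > r))
    stop("pc_indices must be in [1, ", r, "]")
  s <- svd(Y)
  idx <- unique(pc_indices)
  comp <- s$u[, idx, drop = FALSE] %*%
    (s$d[idx] * t(s$v[, idx, drop = FALSE]))
  expression_matrix(Y - comp, m$cell_ids, m$gene_ids, scale = "corrected",
                    gene_center = m$gene_center, gene_scale = m$gene_scale)
}
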