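#' Construct a cell-by-gene expression matrix
#'
#' The central container of the package: a dense numeric matrix with cells in
#' rows and genes in columns, annotated with the transformation state of its
#' values. All model-facing functions require `scale == "standardized"`; the
#' preprocessing functions move a matrix through
#' `counts/tpm -> log -> standardized`.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers (row names).
#' @param gene_ids Character vector of unique gene identifiers (column names).
#' @param scale One of `"counts"`, `"tpm"`, `"log"`, `"standardized"`,
#'   `"corrected"` describing what the values are.
#' @param gene_center,gene_scale Optional per-gene centering/scaling vectors
#'   recorded by [standardize_genes()] so a corrected matrix can be mapped
#'   back to the log scale.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`, `scale` (and, after standardization,
#'   `gene_center`, `gene_scale`, `constant_genes`).
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              scale = c("counts", "tpm", "log",
                                        "standardized", "corrected"),
                              gene_center = NULL, gene_scale = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ", cell_ids[duplicated(cell_ids)][1])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ", gene_ids[duplicated(gene_ids)][1])
  if (any(!is.finite(values)))
    stop("values contain NA/NaN/Inf entries")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         scale = scale, gene_center = gene_center, gene_scale = gene_scale),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Number of cells / genes in an expression matrix
#' @param m An `expr_matrix`.
#' @return Integer count.
#' @export
n_cells <- function(m) nrow(m$values)

#' @rdname n_cells
#' @export
n_genes <- function(m) ncol(m$values)

# internal: coerce expr_matrix or bare matrix to a numeric matrix
as_values <- function(m) {
  if (inherits(m, "expr_matrix")) m$values else as.matrix(m)
}

# internal: check that a matrix is on the scale the model consumes
assert_standardized <- function(m) {
  if (!inherits(m, "expr_matrix"))
    stop("expected an expr_matrix")
  if (m$scale != "standardized")
    stop("matrix must be standardized (scale == 'standardized'); got '",
         m$scale, "'. Run log_transform() and standardize_genes() first.")
  invisible(m)
}

# internal: check that model and matrix agree on the gene universe
assert_same_genes <- function(model_genes, m_genes) {
  if (length(model_genes) != length(m_genes))
    stop("gene sets differ in size: model has ", length(model_genes),
         " genes, matrix has ", length(m_genes))
  bad <- which(model_genes != m_genes)
  if (length(bad))
    stop("gene_ids disagree at position ", bad[1], ": model '",
         model_genes[bad[1]], "' vs matrix '", m_genes[bad[1]], "'")
  invisible(TRUE)
}
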