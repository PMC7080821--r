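#' Log-transform an expression matrix
#'
#' Applies `log2(x + pseudocount)` elementwise to a counts or TPM matrix.
#' A pseudocount of 1 gives the usual `log2(x + 1)` transform.
#'
#' @param m An `expr_matrix` on the `counts` or `tpm` scale.
#' @param pseudocount Positive value added before taking logs. Default 1.
#' @return An `expr_matrix` on the `log` scale, same shape and IDs.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$scale %in% c("counts", "tpm"))
    stop("log_transform expects scale 'counts' or 'tpm'; got '", m$scale, "'")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  neg <- which(m$values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative expression value at cell '", m$cell_ids[neg[1, 1]],
         "', gene '", m$gene_ids[neg[1, 2]], "'")
  expression_matrix(log2(m$values + pseudocount), m$cell_ids, m$gene_ids,
                    scale = "log")
}

#' Standardize each gene to mean 0 and standard deviation 1
#'
#' Z-scores every gene column using the population standard deviation
#' (divisor N) so that all genes contribute equally to the model loss.
#' Constant genes cannot be scaled and are mapped to all-zero columns;
#' their IDs are recorded in the `constant_genes` field and reported via
#' a message.
#'
#' @param m An `expr_matrix` on the `log` scale.
#' @return An `expr_matrix` with `scale == "standardized"`; the per-gene
#'   centers and scales used are stored in `gene_center` / `gene_scale`
#'   (scale 1 for constant genes).
#' @export
standardize_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log")
    stop("standardize_genes expects scale 'log'; got '", m$scale, "'")
  n <- nrow(m$values)
  if (n < 2) stop("standardization needs at least 2 cells")
  ctr <- colMeans(m$values)
  centered <- sweep(m$values, 2, ctr, "-")
  sds <- sqrt(colMeans(centered^2))            # population sd, divisor N
  const <- sds <= 1e-12 * (abs(ctr) + 1)
  scl <- ifelse(const, 1, sds)
  out <- sweep(centered, 2, scl, "/")
  out[, const] <- 0
  if (any(const))
    message(sum(const), " constant gene(s) set to zero: ",
            paste(utils::head(m$gene_ids[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
  res <- expression_matrix(out, m$cell_ids, m$gene_ids,
                           scale = "standardized",
                           gene_center = ctr, gene_scale = scl)
  res$constant_genes <- m$gene_ids[const]
  res
}

#' Quality-control filter on cells
#'
#' Removes cells with a low total signal or a high mitochondrial fraction
#' (droplet-data hygiene). Genes are never filtered: stochastically
#' expressed genes are down-weighted automatically by their poor fit to the
#' periodic model.
#'
#' @param m An `expr_matrix` on the `counts` or `tpm` scale.
#' @param min_total Minimum total (row sum) a cell must reach to be kept.
#' @param max_mito_fraction Maximum tolerated fraction of signal coming from
#'   mitochondrial genes, in `[0, 1]`.
#' @param mito_prefix Gene-ID prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return The filtered `expr_matrix`. A data frame describing removed cells
#'   (id, total, mito fraction, reason) is attached as attribute
#'   `"qc_removed"`.
#' @export
qc_filter_cells <- function(m, min_total = 0, max_mito_fraction = 1,
                            mito_prefix = "MT-") {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$scale %in% c("counts", "tpm"))
    stop("qc_filter_cells expects scale 'counts' or 'tpm'; got '", m$scale, "'")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]")
  totals <- rowSums(m$values)
  mito_cols <- startsWith(m$gene_ids, mito_prefix)
  mito_frac <- if (any(mito_cols)) {
    mt <- rowSums(m$values[, mito_cols, drop = FALSE])
    ifelse(totals > 0, mt / totals, 0)
  } else rep(0, length(totals))
  low <- totals < min_total
  hi_mito <- mito_frac > max_mito_fraction
  drop <- low | hi_mito
  if (all(drop)) stop("qc_filter_cells would remove all cells")
  removed <- data.frame(
    cell_id = m$cell_ids[drop],
    total = totals[drop],
    mito_fraction = mito_frac[drop],
    reason = ifelse(low[drop] & hi_mito[drop], "low_total;high_mito",
                    ifelse(low[drop], "low_total", "high_mito")),
    stringsAsFactors = FALSE)
  out <- expression_matrix(m$values[!drop, , drop = FALSE],
                           m$cell_ids[!drop], m$gene_ids, scale = m$scale)
  attr(out, "qc_removed") <- removed
  out
}
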