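#' Per-gene amplitude and peak phase from the decoder
#'
#' By the identity `a cos x + b sin x = A cos(x - phi)`, the two circular
#' decoder weights of gene `g` define an amplitude `A_g = sqrt(a^2 + b^2)`
#' (the prominence of the periodic pattern in that gene; comparable across
#' datasets because inputs are standardized per gene) and a peak phase
#' `phi_g = atan2(b, a)` mapped to `[0, 2*pi)` (the pseudo-time at which the
#' gene peaks). A zero weight row maps to `(0, 0)` by convention.
#'
#' @param x A `fitted_ca` model, or a decoder parameter list.
#' @param gene_ids Gene identifiers; taken from the model when `x` is a
#'   `fitted_ca`.
#' @return An object of class `gene_periodicity`: list with `gene_ids`,
#'   `amplitude`, `phase`.
#' @export
gene_periodicity <- function(x, gene_ids = NULL) {
  dec <- if (inherits(x, "fitted_ca")) x$decoder else x
  if (is.null(gene_ids) && inherits(x, "fitted_ca")) gene_ids <- x$gene_ids
  V <- dec$V_circular
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(nrow(V)))
  amp <- sqrt(V[, 1]^2 + V[, 2]^2)
  phase <- atan2(V[, 2], V[, 1]) %% (2 * pi)
  phase[amp == 0] <- 0
  names(amp) <- names(phase) <- gene_ids
  structure(list(gene_ids = gene_ids, amplitude = amp, phase = phase),
            class = "gene_periodicity")
}

#' @export
print.gene_periodicity <- function(x, ...) {
  cat(sprintf("<gene_periodicity> %d genes, amplitude range [%.4g, %.4g]\n",
              length(x$gene_ids), min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' Rank candidate periodic marker genes by amplitude
#'
#' Genes with a high amplitude follow the inferred circular process most
#' strongly and are nominated as markers. Ties are broken by gene ID so the
#' ranking is deterministic.
#'
#' @param p A [gene_periodicity()] object.
#' @param top_n How many genes to return; truncated to the number of genes
#'   with a warning when larger.
#' @return A data frame with columns `gene_id`, `amplitude`, `phase`,
#'   `rank`, sorted by amplitude descending.
#' @export
rank_markers <- function(p, top_n = 50L) {
  stopifnot(inherits(p, "gene_periodicity"), top_n >= 1)
  G <- length(p$gene_ids)
  if (top_n > G) {
    warning("top_n (", top_n, ") exceeds number of genes (", G,
            "); truncated")
    top_n <- G
  }
  ord <- order(-p$amplitude, p$gene_ids)
  sel <- ord[seq_len(top_n)]
  data.frame(gene_id = p$gene_ids[sel],
             amplitude = unname(p$amplitude[sel]),
             phase = unname(p$phase[sel]),
             rank = seq_len(top_n),
             stringsAsFactors = FALSE)
}

#' Compare gene periodicity between two conditions
#'
#' For two models fitted separately (e.g. treated vs control) on the same
#' gene universe, reports the per-gene amplitude difference and the wrapped
#' phase difference. Because inputs are standardized per gene, amplitudes
#' are directly comparable across fits. Gene sets are intersected with a
#' message when they differ.
#'
#' @param p_a,p_b [gene_periodicity()] objects for the two conditions.
#' @return Data frame with `gene_id`, `amplitude_a`, `amplitude_b`,
#'   `delta_amplitude` (`A_a - A_b`), `delta_phase` (in `(-pi, pi]`,
#'   positive = peaks later in condition a), sorted by `|delta_amplitude|`
#'   descending.
#' @export
compare_conditions <- function(p_a, p_b) {
  stopifnot(inherits(p_a, "gene_periodicity"),
            inherits(p_b, "gene_periodicity"))
  common <- intersect(p_a$gene_ids, p_b$gene_ids)
  if (length(common) == 0) stop("gene sets do not overlap")
  if (length(common) < length(p_a$gene_ids) ||
      length(common) < length(p_b$gene_ids))
    message("comparing ", length(common), " shared genes (a: ",
            length(p_a$gene_ids), ", b: ", length(p_b$gene_ids), ")")
  ia <- match(common, p_a$gene_ids)
  ib <- match(common, p_b$gene_ids)
  d_amp <- unname(p_a$amplitude[ia] - p_b$amplitude[ib])
  d_phase <- unname(p_a$phase[ia] - p_b$phase[ib])
  d_phase <- ((d_phase + pi) %% (2 * pi)) - pi     # wrap to (-pi, pi]
  d_phase[d_phase == -pi] <- pi
  out <- data.frame(gene_id = common,
                    amplitude_a = unname(p_a$amplitude[ia]),
                    amplitude_b = unname(p_b$amplitude[ib]),
                    delta_amplitude = d_amp,
                    delta_phase = d_phase,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta_amplitude), out$gene_id), , drop = FALSE]
}
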