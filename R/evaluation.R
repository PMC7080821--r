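#' Discretize pseudo-time into stages with a Gaussian mixture
#'
#' Fits a one-dimensional Gaussian mixture (unequal variances) to the
#' pseudo-time values and assigns each cell to its maximum-responsibility
#' component — the standard way of turning a continuous cell-cycle
#' pseudo-time into discrete stage calls. Because EM can land in local
#' optima, the fit is repeated from `n_restarts` seeded random
#' initializations (plus a deterministic hierarchical initialization) and
#' the highest-likelihood solution is kept.
#'
#' @param pseudotime Numeric N-vector (typically in `[0, 2*pi)`).
#' @param n_components Number of mixture components / stages (default 3:
#'   G0/G1, S, G2/M).
#' @param n_restarts Number of random EM restarts (default 5).
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @param truth Optional true stage labels; when supplied, best-match
#'   accuracy and the component-to-stage mapping are filled in.
#' @return Object of class `stage_assignment`: `labels` (integer components
#'   `1..n_components`), `loglik`, and — when truth is given — `accuracy`
#'   and `mapping`.
#' @import mclust
#' @export
gmm_stage_assign <- function(pseudotime, n_components = 3L, n_restarts = 5L,
                             seed = 0L, truth = NULL) {
  x <- as.numeric(pseudotime)
  N <- length(x)
  if (N < n_components) stop("need at least n_components cells")
  if (diff(range(x)) < 1e-12)
    stop("degenerate pseudo-time: all values equal")
  set.seed(seed)
  best <- NULL
  consider <- function(z, ll) {
    if (is.null(best) || (is.finite(ll) && ll > best$ll))
      best <<- list(z = z, ll = ll)
  }
  if (n_components == 1L) {
    best <- list(z = matrix(1, N, 1), ll = sum(stats::dnorm(
      x, mean(x), stats::sd(x), log = TRUE)))
  } else {
    fit0 <- tryCatch(
      mclust::Mclust(x, G = n_components, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit0) && !is.null(fit0$z)) consider(fit0$z, fit0$loglik)
    for (r in seq_len(n_restarts)) {
      cl <- tryCatch(stats::kmeans(x, centers = n_components, nstart = 1),
                     error = function(e) NULL)
      init <- if (is.null(cl)) sample.int(n_components, N, replace = TRUE)
              else cl$cluster
      fit <- tryCatch(
        mclust::me(data = x, modelName = "V", z = mclust::unmap(
          init, groups = seq_len(n_components))),
        error = function(e) NULL)
      if (!is.null(fit) && !is.null(fit$z) && is.finite(fit$loglik))
        consider(fit$z, fit$loglik)
    }
    if (is.null(best)) stop("GMM fitting failed on all initializations")
  }
  labels <- max.col(best$z, ties.method = "first")
  out <- list(labels = labels, loglik = best$ll, n_components = n_components,
              accuracy = NA_real_, mapping = NULL)
  if (!is.null(truth)) {
    acc <- best_match_accuracy(labels, truth, return_mapping = TRUE)
    out$accuracy <- acc$accuracy
    out$mapping <- acc$mapping
  }
  structure(out, class = "stage_assignment")
}

# internal: all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Best-match classification accuracy
#'
#' Fraction of cells whose predicted component agrees with the true label
#' under the best bijective matching of components to labels (exhaustive
#' over permutations; components/labels beyond the smaller cardinality stay
#' unmatched and count as wrong). Invariant to any relabeling of either
#' argument.
#'
#' @param pred Predicted component labels (any type coercible to factor).
#' @param truth True labels, same length.
#' @param return_mapping Also return the component-to-label mapping used?
#' @return Number in `[0, 1]`, or a list with `accuracy` and `mapping`.
#' @export
best_match_accuracy <- function(pred, truth, return_mapping = FALSE) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  pf <- factor(pred); tf <- factor(truth)
  tab <- table(pf, tf)
  np <- nrow(tab); nt <- ncol(tab)
  big <- max(np, nt)
  if (big > 8) stop("too many distinct labels for exhaustive matching (> 8)")
  # pad the confusion matrix to square; padded rows/cols match nothing
  sq <- matrix(0, big, big)
  sq[seq_len(np), seq_len(nt)] <- tab
  pm <- perms(big)
  scores <- apply(pm, 1, function(p) sum(sq[cbind(seq_len(big), p)]))
  bi <- which.max(scores)
  acc <- scores[bi] / length(pred)
  if (!return_mapping) return(acc)
  map <- stats::setNames(
    c(levels(tf), rep(NA_character_, big - nt))[pm[bi, ]][seq_len(np)],
    levels(pf))
  list(accuracy = acc, mapping = map)
}

#' Align an inferred circular pseudo-time to a reference
#'
#' The circular embedding is identifiable only up to a global rotation and
#' a reflection, so inferred and true pseudo-times are compared after
#' finding the best aligning transform. The score is the modulus of the
#' complex correlation between the unit-circle embeddings
#' `exp(i * s * inferred)` and `exp(i * truth)` maximized over the
#' reflection `s` — a closed form whose argument also yields the optimal
#' rotation offset. 1 means perfect agreement up to rotation/reflection;
#' independent angles give a score near 0.
#'
#' @param inferred,truth Numeric vectors of angles (radians), same length,
#'   at least 3 values.
#' @return List of class `circular_alignment`: `score` in `[0, 1]`,
#'   `offset` (radians), `reflected` (logical). Applying
#'   [apply_alignment()] with these to `inferred` best matches `truth`.
#' @export
circular_alignment_score <- function(inferred, truth) {
  a <- as.numeric(inferred); b <- as.numeric(truth)
  if (length(a) != length(b)) stop("lengths differ")
  if (length(a) < 3) stop("need at least 3 cells")
  score_one <- function(s) {
    u <- exp(1i * s * a); v <- exp(1i * b)
    uc <- u - mean(u); vc <- v - mean(v)
    denom <- sqrt(sum(Mod(uc)^2) * sum(Mod(vc)^2))
    if (denom < 1e-12) stop("constant angle vector; alignment undefined")
    r <- sum(Conj(uc) * vc)
    list(score = Mod(r) / denom, offset = Arg(r) %% (2 * pi))
  }
  fwd <- score_one(1); rev <- score_one(-1)
  if (fwd$score >= rev$score)
    structure(list(score = fwd$score, offset = fwd$offset, reflected = FALSE),
              class = "circular_alignment")
  else
    structure(list(score = rev$score, offset = rev$offset, reflected = TRUE),
              class = "circular_alignment")
}

#' Apply a circular alignment transform
#'
#' @param x Angles in radians.
#' @param alignment A `circular_alignment` from [circular_alignment_score()]
#'   (or a list with `offset` and `reflected`).
#' @return `(s * x + offset) mod 2*pi` with `s = -1` when reflected.
#' @export
apply_alignment <- function(x, alignment) {
  s <- if (isTRUE(alignment$reflected)) -1 else 1
  (s * as.numeric(x) + alignment$offset) %% (2 * pi)
}

#' Subclone separability on a t-SNE embedding
#'
#' Embeds the cells in 2-D with t-SNE, fits a two-component Gaussian
#' mixture on the embedding, and scores the best-match accuracy of the
#' mixture assignment against the known clone labels. High values mean the
#' two clones occupy distinct regions of the embedding; 0.5 is chance.
#'
#' @param m `expr_matrix` (any scale) or bare matrix, cells in rows.
#' @param clone_truth Vector with exactly two distinct labels.
#' @param seed Integer seed (t-SNE and GMM restarts).
#' @param perplexity t-SNE perplexity (reduced automatically when N is
#'   small).
#' @param n_restarts Repeat the embed+fit cycle this many times and keep
#'   the best accuracy, mirroring best-of-k evaluation practice.
#' @return Number in `[0, 1]` with attributes `seed` and `perplexity`.
#' @export
subclone_separability <- function(m, clone_truth, seed = 0L,
                                  perplexity = 30, n_restarts = 1L) {
  X <- as_values(m)
  N <- nrow(X)
  if (N < 10) stop("need at least 10 cells for a stable embedding")
  if (length(clone_truth) != N)
    stop("clone_truth must have one label per cell")
  if (nlevels(factor(clone_truth)) != 2)
    stop("clone_truth must contain exactly two distinct labels")
  perp <- min(perplexity, floor((N - 2) / 3))
  accs <- vapply(seq_len(n_restarts), function(r) {
    set.seed(seed + r - 1L)
    emb <- Rtsne::Rtsne(X, dims = 2, perplexity = perp,
                        check_duplicates = FALSE, pca = TRUE,
                        verbose = FALSE)$Y
    g <- tryCatch(
      mclust::Mclust(emb, G = 2, verbose = FALSE),
      error = function(e) NULL)
    if (is.null(g)) return(NA_real_)
    best_match_accuracy(g$classification, clone_truth)
  }, numeric(1))
  if (all(is.na(accs))) stop("GMM on the embedding failed")
  out <- max(accs, na.rm = TRUE)
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perp
  out
}

#' Fraction of cells engaged in the periodic process
#'
#' A population in which only part of the cells cycle shows a pseudo-time
#' density with one dominant arc (the resting cells piled up) separated by
#' low-density gaps from the rest of the circle. This estimator computes a
#' von Mises kernel density on the circle, marks arcs whose density falls
#' below `gap_threshold` times the mean density as gaps, and reports the
#' fraction of cells lying outside the densest contiguous non-gap arc.
#' When no gap qualifies (e.g. uniform occupancy) the whole population is
#' reported as cycling (fraction 1). The rule and its two parameters are
#' heuristics; treat the output as a rough estimate.
#'
#' @param pseudotime Angles in `[0, 2*pi)`, at least 20 cells.
#' @param bandwidth Kernel bandwidth as a circular sd in radians
#'   (concentration `kappa = 1 / bandwidth^2`). Default 0.3.
#' @param gap_threshold Multiple of the mean density below which an arc
#'   counts as a gap. Default 0.2.
#' @param n_grid Density grid resolution.
#' @return Number in `[0, 1]` with attribute `gaps`: a matrix of gap arc
#'   bounds (radians).
#' @export
cycling_fraction <- function(pseudotime, bandwidth = 0.3,
                             gap_threshold = 0.2, n_grid = 512L) {
  x <- as.numeric(pseudotime) %% (2 * pi)
  N <- length(x)
  if (N < 20) stop("need at least 20 cells")
  stopifnot(bandwidth > 0, gap_threshold >= 0)
  kappa <- 1 / bandwidth^2
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  # von Mises KDE; normalizing constant cancels against the mean density
  dens <- vapply(grid, function(g) mean(exp(kappa * (cos(g - x) - 1))),
                 numeric(1))
  is_gap <- dens < gap_threshold * mean(dens)
  if (!any(is_gap)) {
    out <- 1
    attr(out, "gaps") <- matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("start", "end")))
    return(out)
  }
  if (all(is_gap)) {
    out <- 0
    attr(out, "gaps") <- matrix(c(0, 2 * pi), 1, 2,
                                dimnames = list(NULL, c("start", "end")))
    return(out)
  }
  # contiguous runs on the circle: rotate so position 1 starts a run
  brk <- which(is_gap != c(is_gap[n_grid], is_gap[-n_grid]))
  first <- brk[1]
  ord <- c(first:n_grid, seq_len(first - 1L))
  gap_r <- is_gap[ord]
  run_id <- cumsum(c(TRUE, gap_r[-1] != gap_r[-n_grid]))
  runs <- split(ord, run_id)
  step <- 2 * pi / n_grid
  arc_of <- function(idx) c(grid[idx[1]], grid[idx[length(idx)]] + step)
  dense_runs <- runs[!vapply(runs, function(i) gap_r[match(i[1], ord)], TRUE)]
  gap_runs <- runs[vapply(runs, function(i) gap_r[match(i[1], ord)], TRUE)]
  in_arc <- function(arc) {
    if (arc[2] <= 2 * pi) x >= arc[1] & x < arc[2]
    else x >= arc[1] | x < (arc[2] - 2 * pi)
  }
  counts <- vapply(dense_runs, function(i) sum(in_arc(arc_of(i))), numeric(1))
  densest <- dense_runs[[which.max(counts)]]
  out <- 1 - max(counts) / N
  attr(out, "gaps") <- do.call(rbind, lapply(gap_runs, arc_of))
  colnames(attr(out, "gaps")) <- c("start", "end")
  out
}

#' Average expression score of a gene set
#'
#' Per-cell mean expression over the genes of a set (e.g. the AXL or MITF
#' program), the standard program-activity score for contrasting cell
#' states.
#'
#' @param m `expr_matrix`.
#' @param gene_set Character vector of gene IDs; intersected with the
#'   matrix's genes (message when some are absent, error when none match).
#' @return Named N-vector of scores with attribute `genes_used`.
#' @export
gene_set_score <- function(m, gene_set) {
  stopifnot(inherits(m, "expr_matrix"))
  found <- intersect(gene_set, m$gene_ids)
  if (length(found) == 0) stop("no genes of the set are in the matrix")
  if (length(found) < length(gene_set))
    message(length(gene_set) - length(found),
            " gene(s) of the set not present; using ", length(found))
  out <- rowMeans(m$values[, found, drop = FALSE])
  names(out) <- m$cell_ids
  attr(out, "genes_used") <- found
  out
}
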