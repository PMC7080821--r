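#' Specification of a synthetic circular trajectory
#'
#' Describes a population of cells on a closed trajectory in gene space:
#' each periodic gene follows `A_g cos(t - phi_g)` over the circular
#' pseudo-time `t`, with additive Gaussian noise; the remaining genes are
#' pure noise. Discrete stage labels are assigned from contiguous arcs of
#' the circle, mimicking cell-cycle stages (G0/G1, S, G2/M). The defaults
#' are the study conditions used throughout the package's tests: 500 cells,
#' 200 genes of which 150 are periodic, amplitudes uniform on [0.5, 2],
#' noise sd 0.3, uniform pseudo-time, and stage arcs of widths
#' (pi, pi/2, pi/2).
#'
#' @param n_cells,n_genes,n_periodic_genes Population dimensions.
#' @param amplitude_range Length-2 positive range amplitudes are drawn from.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param stage_arcs Data frame with columns `label`, `start`, `end`
#'   describing disjoint arcs covering `[0, 2*pi)`.
#' @param pseudotime_distribution `"uniform"` or `"von_mises_mixture"`
#'   (an uneven occupancy of the circle, closer to real stage proportions).
#' @param vm_kappa Concentration of the von Mises mixture components
#'   (centered on the stage-arc midpoints, equal weights).
#' @param seed Integer seed.
#' @return List of class `circular_sim_spec`.
#' @export
circular_sim_spec <- function(n_cells = 500L, n_genes = 200L,
                              n_periodic_genes = 150L,
                              amplitude_range = c(0.5, 2),
                              noise_sd = 0.3,
                              stage_arcs = data.frame(
                                label = c("G1", "S", "G2M"),
                                start = c(0, pi, 3 * pi / 2),
                                end = c(pi, 3 * pi / 2, 2 * pi)),
                              pseudotime_distribution = c("uniform",
                                                          "von_mises_mixture"),
                              vm_kappa = 4,
                              seed = 0L) {
  pseudotime_distribution <- match.arg(pseudotime_distribution)
  stopifnot(n_periodic_genes <= n_genes, n_cells >= 1,
            length(amplitude_range) == 2, all(amplitude_range > 0),
            noise_sd >= 0)
  arcs <- as.data.frame(stage_arcs)
  if (!all(c("label", "start", "end") %in% names(arcs)))
    stop("stage_arcs needs columns label, start, end")
  arcs <- arcs[order(arcs$start), , drop = FALSE]
  if (abs(arcs$start[1]) > 1e-9 ||
      abs(arcs$end[nrow(arcs)] - 2 * pi) > 1e-9 ||
      (nrow(arcs) > 1 &&
       any(abs(arcs$end[-nrow(arcs)] - arcs$start[-1]) > 1e-9)))
    stop("stage_arcs must be disjoint and cover [0, 2*pi)")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_periodic_genes = as.integer(n_periodic_genes),
                 amplitude_range = amplitude_range, noise_sd = noise_sd,
                 stage_arcs = arcs,
                 pseudotime_distribution = pseudotime_distribution,
                 vm_kappa = vm_kappa, seed = as.integer(seed)),
            class = "circular_sim_spec")
}

# internal: von Mises sampler (Best & Fisher rejection scheme)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Simulate cells on a circular trajectory with ground truth
#'
#' Draws pseudo-times, builds per-gene sinusoidal programs for the periodic
#' genes, adds Gaussian noise, and labels each cell by the stage arc its
#' pseudo-time falls in. The matrix is returned on the `log` scale (the
#' values are treated as already log-transformed expression), ready for
#' [standardize_genes()].
#'
#' @param spec A [circular_sim_spec()].
#' @return List with `matrix` (an `expr_matrix`) and `truth`: a list holding
#'   `pseudotime`, `amplitude` (0 for non-periodic genes), `phase`,
#'   `periodic` (logical per gene), and `stage` (factor per cell).
#' @export
simulate_circular <- function(spec = circular_sim_spec()) {
  stopifnot(inherits(spec, "circular_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; G <- spec$n_genes; P <- spec$n_periodic_genes
  t_n <- switch(spec$pseudotime_distribution,
    uniform = stats::runif(n, 0, 2 * pi),
    von_mises_mixture = {
      mids <- (spec$stage_arcs$start + spec$stage_arcs$end) / 2
      comp <- sample.int(length(mids), n, replace = TRUE)
      vapply(comp, function(j) rvonmises(1, mids[j], spec$vm_kappa),
             numeric(1))
    })
  amp <- c(stats::runif(P, spec$amplitude_range[1], spec$amplitude_range[2]),
           rep(0, G - P))
  phase <- c(stats::runif(P, 0, 2 * pi), rep(0, G - P))
  signal <- outer(t_n, phase[seq_len(P)], "-")
  Y <- matrix(stats::rnorm(n * G, sd = spec$noise_sd), n, G)
  if (P > 0)
    Y[, seq_len(P)] <- Y[, seq_len(P)] +
      sweep(cos(signal), 2, amp[seq_len(P)], "*")
  arcs <- spec$stage_arcs
  stage_idx <- vapply(t_n, function(tt)
    which(tt >= arcs$start & tt < arcs$end)[1], integer(1))
  stage <- factor(arcs$label[stage_idx], levels = arcs$label)
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  m <- expression_matrix(Y, cell_ids, gene_ids, scale = "log")
  list(matrix = m,
       truth = list(pseudotime = stats::setNames(t_n, cell_ids),
                    amplitude = stats::setNames(amp, gene_ids),
                    phase = stats::setNames(phase, gene_ids),
                    periodic = stats::setNames(seq_len(G) <= P, gene_ids),
                    stage = stats::setNames(stage, cell_ids)))
}

#' Specification of a two-clone virtual-tumor mixture
#'
#' Parameters of the perturbation that creates a second clone from a base
#' population: a random subset of "known cell-cycle" genes plus a random
#' subset of other genes have their expression doubled (by default) in the
#' clone-2 cells. The canonical construction perturbs 600 cell-cycle and
#' 1000 other genes in equal clones of 288 cells.
#'
#' @param n_cells_clone2 Number of cells sampled into clone 2.
#' @param n_cc_genes_perturbed Number of cell-cycle genes to perturb.
#' @param n_other_genes_perturbed Number of non-cell-cycle genes to perturb.
#' @param cc_gene_list Character vector of gene IDs regarded as known
#'   cell-cycle genes.
#' @param fold_change Linear-scale fold change applied to perturbed genes
#'   (2 = doubling, i.e. +1 on the log2 scale).
#' @param seed Integer seed.
#' @return List of class `virtual_tumor_spec`.
#' @export
virtual_tumor_spec <- function(n_cells_clone2 = 288L,
                               n_cc_genes_perturbed = 600L,
                               n_other_genes_perturbed = 1000L,
                               cc_gene_list, fold_change = 2, seed = 0L) {
  stopifnot(n_cells_clone2 >= 1, n_cc_genes_perturbed >= 0,
            n_other_genes_perturbed >= 0, fold_change > 0)
  structure(list(n_cells_clone2 = as.integer(n_cells_clone2),
                 n_cc_genes_perturbed = as.integer(n_cc_genes_perturbed),
                 n_other_genes_perturbed = as.integer(n_other_genes_perturbed),
                 cc_gene_list = as.character(cc_gene_list),
                 fold_change = fold_change, seed = as.integer(seed)),
            class = "virtual_tumor_spec")
}

#' Build a virtual tumor: two clones differing by doubled gene sets
#'
#' Clone 1 is the base population unchanged. Clone 2 is a random sample of
#' base cells (with replacement if more cells are requested than exist) in
#' which the selected genes are perturbed by `+log2(fold_change)` on the
#' log scale — doubling on the linear scale for the default fold change
#' of 2. The result is the row-concatenation of both clones, together with
#' clone labels and the exact perturbed gene set, enabling evaluation of
#' how well a correction method restores clone separability.
#'
#' @param base `expr_matrix` on the `log` scale.
#' @param spec A [virtual_tumor_spec()].
#' @return List with `matrix` (`expr_matrix`, clone-2 cell IDs suffixed
#'   `"_c2"`), `clone_labels` (factor `clone1`/`clone2`),
#'   `perturbed_gene_ids`, and `clone2_source` (base-row index of each
#'   clone-2 cell).
#' @export
make_virtual_tumor <- function(base, spec) {
  stopifnot(inherits(base, "expr_matrix"), inherits(spec, "virtual_tumor_spec"))
  if (base$scale != "log")
    stop("make_virtual_tumor expects a log-scale base matrix")
  cc_avail <- intersect(spec$cc_gene_list, base$gene_ids)
  other_avail <- setdiff(base$gene_ids, spec$cc_gene_list)
  if (length(cc_avail) < spec$n_cc_genes_perturbed)
    stop("only ", length(cc_avail), " cell-cycle genes available; ",
         spec$n_cc_genes_perturbed, " requested")
  if (length(other_avail) < spec$n_other_genes_perturbed)
    stop("only ", length(other_avail), " non-cell-cycle genes available; ",
         spec$n_other_genes_perturbed, " requested")
  set.seed(spec$seed)
  genes <- c(sample(cc_avail, spec$n_cc_genes_perturbed),
             sample(other_avail, spec$n_other_genes_perturbed))
  N <- nrow(base$values)
  n2 <- spec$n_cells_clone2
  src <- sample.int(N, n2, replace = n2 > N)
  clone2 <- base$values[src, , drop = FALSE]
  shift <- log2(spec$fold_change)
  clone2[, genes] <- clone2[, genes] + shift
  vals <- rbind(base$values, clone2)
  cell_ids <- c(base$cell_ids, paste0(base$cell_ids[src], "_c2_",
                                      seq_len(n2)))
  labels <- factor(rep(c("clone1", "clone2"), c(N, n2)))
  m <- expression_matrix(vals, cell_ids, base$gene_ids, scale = "log")
  list(matrix = m, clone_labels = stats::setNames(labels, cell_ids),
       perturbed_gene_ids = genes, clone2_source = src)
}
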