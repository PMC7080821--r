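# scperiodic

Circular pseudo-time inference and periodic-effect removal for single-cell
expression data.

Cells traversing a periodic program such as the cell cycle form a *closed*
trajectory in gene-expression space. `scperiodic` embeds each cell onto a
single circular coordinate with an autoencoder whose decoder uses sine and
cosine activations:

    x_n = W3 · tanh(W2 · tanh(W1 · y_n + b1) + b2)          (encoder)
    ŷ_n = V_circ · [cos x_n ; sin x_n] + V_lin · x_lin       (decoder)

trained by minibatch Adam on the L2-regularized least-squares
reconstruction loss. The two circular decoder weights of each gene g are
equivalent to an amplitude and peak phase, A_g·cos(x − φ_g), so the fitted
model simultaneously provides

* **pseudo-time**: the circular coordinate wrapped to [0, 2π) per cell;
* **periodic marker genes**: genes ranked by amplitude A_g, with peak
  phase φ_g, comparable across datasets because genes are standardized;
* **confounder removal**: the circular part of the reconstruction is the
  estimated periodic effect and is subtracted from the data, after which
  subpopulations hidden behind cell-cycle variation become separable.

The package also ships a synthetic circular-trajectory generator with
ground truth, a two-clone "virtual tumor" simulator (doubling selected
gene sets in one clone), and evaluation metrics: Gaussian-mixture stage
classification accuracy, two-component-GMM subclone separability on a
t-SNE embedding, circular alignment scores, and a cycling-fraction
estimate from the circular pseudo-time density.

## Worked example

```r
library(scperiodic)

sim <- simulate_circular(circular_sim_spec(seed = 0))   # 500 cells, 200 genes
std <- standardize_genes(sim$matrix)
fit <- fit_circular_ae(std, model_config(seed = 0))

pt <- pseudotime(fit, std)
circular_alignment_score(pt$circular, sim$truth$pseudotime)$score
#> [1] 0.9989625

head(rank_markers(gene_periodicity(fit), top_n = 3))
#>     gene_id amplitude    phase rank
#> 1 gene_0107  1.410692 5.906842    1
#> 2 gene_0142  1.403065 5.796239    2
#> 3 gene_0055  1.399729 2.667525    3

corrected <- remove_circular(std, fit)   # periodic component subtracted
```

The alignment score compares inferred and true angles after the best
rotation/reflection (the model is identifiable only up to that transform);
0.999 means the ordering of cells around the circle is recovered almost
exactly. The top-ranked genes are simulated periodic genes; their
standardized amplitudes approach sqrt(2), the amplitude of a pure
standardized sinusoid.

A command-line interface over the same functions is installed at
`inst/scripts/scperiodic` (subcommands `fit`, `pseudotime`, `remove`,
`markers`, `compare`, `select-dim`, `simulate`, `evaluate`, `score`;
dense CSV/TSV or 10x-style MatrixMarket input).

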