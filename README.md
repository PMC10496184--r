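# zinbmix

Model-based clustering of single-cell RNA-seq raw counts with simultaneous
batch-effect adjustment, dropout modelling and cluster-specific gene
selection.

## The problem and the model

scRNA-seq count matrices confound three things at once: biological
heterogeneity between cell types, technical dropout (transcripts present in
the cell but not captured, producing excess zeros), and batch effects
(systematic shifts shared by cells processed together). Most pipelines
handle these in separate preprocessing stages; `zinbmix` instead fits one
generative model to the raw counts.

The count X<sub>ij</sub> of gene *j* in cell *i* follows a K-component
mixture of zero-inflated negative binomials:

> f(X<sub>ij</sub>) = Σ<sub>k</sub> p<sub>k</sub> [ π<sub>jk</sub> I(X<sub>ij</sub>=0) + (1−π<sub>jk</sub>) NB(X<sub>ij</sub>; μ<sub>ijk</sub>, φ<sub>j</sub>) ],  log μ<sub>ijk</sub> = β<sub>jk</sub> + B<sub>i</sub>′γ

with cluster-specific dropout probabilities π<sub>jk</sub>, gene-wise
dispersions φ<sub>j</sub> (Var = μ + μ²/φ) and an additive batch shift
B<sub>i</sub>′γ on the log mean. Fitting maximizes a penalized likelihood

> l(θ) − λ Σ<sub>jk</sub> | β<sub>jk</sub> − β*<sub>j</sub> |

where β*<sub>j</sub> is a pre-estimated global (no-cluster) log-mean. The L1
pull shrinks uninformative genes' cluster means *exactly* onto β*<sub>j</sub>,
so the set of genes with at least one β<sub>jk</sub> ≠ β*<sub>j</sub> is an
automatic selection of cluster-discriminatory genes. A generalized EM
algorithm (soft cluster responsibilities and posterior dropout indicators in
the E-step; closed-form, quasi-Newton and soft-thresholded IRLS sub-updates
in the M-step) maximizes the objective; λ and K are chosen by a BIC whose
effective dimension, d = (K−1) + J + S + 2KJ − q, credits the q coefficients
shrunk to the global mean.

The package also ships generators for the layered simulation designs used to
validate the method (ZINB with cluster-specific dropout and batch shifts; an
NB mixture without dropout; zero-inflated Poisson variants; cluster-
independent dropout), with full ground truth, plus evaluation metrics
(adjusted Rand index; selection recall/precision/F1).

## Worked example

```r
library(zinbmix)

# a small simulated dataset: 2 cell types, 2 batches, 20% informative genes
sim <- simulate_main(sim_config(n = 90, J = 60, K = 2, frac_informative = 0.2,
                                dropout_level = "low", Delta = 1.6, seed = 3,
                                delta_patterns = list(c(-1, 1), c(1, 0))))
sim
#> Simulated dataset: 90 cells x 60 genes, K = 2, 12 informative gene(s)
#>   realized dropout-event fraction: 15.9%; overall zero fraction: 38.8%

fit <- zinbmix_fit(sim$X, sim$B, K = 2, lambda = 1)
fit
#> Penalized ZINB mixture fit: n = 90 cells, J = 60 genes, K = 2, lambda = 1
#>   log-likelihood -11043.00 | 94 iterations | converged: TRUE
#>   57 selected gene(s); cluster sizes: 45 45

ari(sim$labels, fit$labels)
#> [1] 1
```

The fitted labels recover the simulated cell types exactly (adjusted Rand
index 1). At λ = 1 the penalty is mild, so 57 of 60 genes keep at least one
cluster-specific mean; `select_lambda()` walks the standard ten-point grid
(0.01 to 20) and picks the penalty with the lowest BIC, trimming the
selection toward genes with real cluster differences:

```r
sel <- select_lambda(sim$X, sim$B, K = 2)
sel$lambda                    # BIC-selected penalty
length(selected_genes(sel$fit))
selection_prf(sim$informative, selected_genes(sel$fit),
              universe = colnames(sim$X))
```

Broom-style accessors and plots are available: `tidy(fit)` (one row per gene
and cluster with `beta`, `beta_star`, `pi`, `selected`), `glance(fit)`
(log-likelihood, BIC, iterations), `autoplot(fit)` (objective trace) and
`plot_bic_path(sel$records)`.

A command-line interface over the same functions lives at
`inst/cli/zinbmix.R` with subcommands `simulate`, `fit`, `select-k`,
`benchmark` and `metrics`; every run writes a JSON manifest so outputs are
exactly reproducible from the recorded flags and seed.

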