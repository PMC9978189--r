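# ampcnet

Functional brain networks estimated from resting-state fMRI are weighted
graphs over atlas regions of interest (ROIs), and much of their clinically
useful signal sits in their *modular* organization — groups of regions
densely connected inside and sparsely connected across. Plain Pearson
correlation gives dense networks with no explicit modules; sparsity
(ℓ1) and low-rank (trace-norm) penalties encourage modular structure but
cannot fix the number of modules. `ampcnet` implements an estimator that
makes the module count exact, for researchers who analyze or classify
connectomes from already-extracted ROI time series.

## The model

For a column-standardized time-series matrix X (m time points × n ROIs,
each ROI signal centered and unit-norm, so A = XᵀX is the Pearson
correlation matrix), the core estimator solves

    min_{W ≥ 0}  ‖W − XᵀX‖²_F + λ Σᵢⱼ Wᵢⱼ   s.t.  rank(L_W) = n − k,

where L_W = D − W is the graph Laplacian. Because the multiplicity of the
zero Laplacian eigenvalue equals the number of connected components, the
rank constraint forces the estimated nonnegative network to have exactly
k modules. The constraint is relaxed to a penalty α Σᵢ₌₁ᵏ σᵢ(L_W) on the k
smallest eigenvalues and, via Ky Fan's theorem, solved by alternating a
spectral step (k bottom eigenvectors of L_W) with a closed-form weight step

    Wᵢⱼ = max(0, aᵢⱼ − (α/4)‖fᵢ − fⱼ‖² − λ/2),

while α is doubled/halved until the component count hits k exactly.
Baselines (`pearson_network()`, `sparse_pc_network()`, `mpc_network()` and
their nonnegative "+" variants), a subject-level cross-validated
classification protocol (t-test edge selection + linear SVM, C = 1), and a
synthetic modular-cohort generator with exact ground truth round out the
package. See the vignette in `vignettes/module-constrained-networks.Rmd`
for the full methods account.

## Worked example

```r
library(ampcnet)

# a synthetic two-class cohort: 116 ROIs, 137 time points, 8 planted
# modules, 20 weakened within-module edges in the patient class
spec <- modular_cohort_spec(n_subjects_per_class = c(10, 10),
                            scans_per_subject = 1, seed = 1)
cohort <- generate_cohort(spec, seed = 1)

fit <- ampc_estimate(cohort$manifest$data[[1]], k = 8)
fit
#> AM-PC network fit
#>   nodes: 116, target modules k = 8, observed modules = 8
#>   converged: TRUE after 14 iterations (alpha = 204.8, lambda = 0.007812)
#>   nonzero edges: 784 of 6670
table(fit$partition$labels)
#>  0  1  2  3  4  5  6  7
#> 15 15 15 15 14 14 14 14
```

The fit converged with exactly the 8 requested modules (a guarantee, not a
tendency: `k_observed == k` whenever `converged` is `TRUE`), keeping 784 of
the 6,670 possible edges; the recovered module sizes match the planted
partition exactly. The cross-validated pipeline on the same cohort:

```r
report <- run_cv(cohort$manifest, method = "am-pc", k = 8,
                 folds = 5, repeats = 5, seed = 1)
report
#> Cross-validated classification (am-pc, 5-fold x 5 repeats)
#>   ACC: 1.0000 +/- 0.0000
#>   SEN: 1.0000 +/- 0.0000
#>   SPE: 1.0000 +/- 0.0000
#>   AUC: 1.0000 +/- 0.0000
```

At this high signal-to-noise (within-module correlation 0.7, effect size
0.3 on 20 edges) the classes separate perfectly; permuting labels drops
accuracy to chance, which the test suite checks.

A command-line interface with `simulate`, `estimate`, `classify`,
`rank-edges` and `k-sweep` subcommands ships at
`system.file("cli", "ampcnet.R", package = "ampcnet")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","ampcnet.R",package="ampcnet"))') \
  estimate --method am-pc --k 8 --input scan.tsv --output net.tsv
```

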