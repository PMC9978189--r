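---
title: "Module-constrained functional brain network estimation with ampcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-constrained functional brain network estimation with ampcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

A functional brain network summarizes a resting-state fMRI scan as a weighted
graph: nodes are atlas regions of interest (ROIs), and the edge between two
ROIs quantifies the statistical dependence of their mean signals. With each
ROI signal centered and scaled to unit norm, the data matrix $X \in
\mathbb{R}^{m \times n}$ ($m$ time points, $n$ ROIs) has the property that
$A = X^\top X$ is the matrix of pairwise Pearson correlations, the default
connectivity estimate in the field.

Correlation networks are dense, while real functional networks are believed
to be sparse and organized into *modules* — groups of ROIs densely connected
inside and weakly connected across. Convex surrogates (an $\ell_1$ penalty
for sparsity, a trace-norm penalty for low rank, as in `sparse_pc_network()`
and `mpc_network()`) encourage modular structure but cannot fix the number
of modules. The estimator at the core of this package makes the module count
exact, using a classical spectral fact: the multiplicity of the zero
eigenvalue of a graph Laplacian $L_W = D - W$ equals the number of connected
components of the graph. `ampc_estimate()` solves

$$
\min_{W \ge 0} \; \lVert W - X^\top X \rVert_F^2
  + \lambda \textstyle\sum_{ij} W_{ij}
  \quad \text{s.t.} \quad \operatorname{rank}(L_W) = n - k,
$$

so that the returned nonnegative network has exactly $k$ connected
components. Self-loops are excluded throughout: the diagonal of every
estimator output is zero, since the self-correlation $a_{ii} = 1$ carries no
information and would distort node degrees.

# The alternating solver

The rank constraint is relaxed to a penalty $\alpha \sum_{i=1}^{k}
\sigma_i(L_W)$ on the $k$ smallest Laplacian eigenvalues, which is zero
precisely when the constraint holds. By Ky Fan's theorem the eigenvalue sum
equals $\min_{F^\top F = I} \operatorname{Tr}(F^\top L_W F)$ over $n \times
k$ orthonormal embeddings, giving a biconvex problem solved by alternating:

* **Spectral step** (`ampc_update_F()`): with $W$ fixed, the optimal $F$ is
  the $k$ eigenvectors of $L_W$ with smallest eigenvalues.
* **Weight step** (`ampc_update_W()`): with $F$ fixed, the problem separates
  per edge. Writing $f_{ij} = \lVert f_i - f_j \rVert_2^2$ for the squared
  distance between embedding rows, each weight has the closed form
  $W_{ij} = \max\!\left(0,\; a_{ij} - \tfrac{\alpha}{4} f_{ij} -
  \tfrac{\lambda}{2}\right)$: the correlation, soft-clipped by the spectral
  distance (edges between nodes far apart in the embedding are cut) and by
  the sparsity penalty.

$\alpha$ is adapted rather than tuned: after each weight step the solver
counts (numerically) zero Laplacian eigenvalues; $\alpha$ doubles while
there are fewer than $k$ and halves while there are more, stopping once the
count is exactly $k$ and the relative objective change falls below
`obj_rtol`. When the iteration cap is hit first, the fit is returned with
`converged = FALSE` and its full diagnostic trace instead of raising.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | target module count; resting-state studies usually place it below 10 |
| `lam` | $2^{-7}$ | sparsity weight (dimensionless); midpoint of the $2^{-11}..2^{-1}$ grid used for classification |
| `alpha0` | 0.1 | initial rank-penalty weight; only the starting point, since the doubling/halving schedule finds the right scale geometrically |
| `max_outer_iters` | 50 | iteration cap; the schedule typically reaches $k$ components within ~15 iterations |
| `obj_rtol` | $10^{-6}$ | relative objective-change stopping tolerance |
| `normalized_laplacian` | `TRUE` | see below |
| `zero_tol` | $10^{-8}$ | absolute zero-eigenvalue tolerance, chosen for the normalized Laplacian whose spectrum lies in $[0, 2]$ (scale-free) |

## Numerical choices

**Normalized Laplacian and lagged degrees.** With the combinatorial
Laplacian, the rank penalty tends to split off single weakly connected ROIs
as their own "modules"; the symmetric normalized Laplacian $I - D^{-1/2} W
D^{-1/2}$ balances cut cost by degree and avoids this. The identity
$\operatorname{Tr}(F^\top L_{sym} F) = \tfrac{1}{2} \sum_{ij} W_{ij}
\lVert f_i/\sqrt{d_i} - f_j/\sqrt{d_j} \rVert^2$ couples the weight step to
the degrees, which would destroy its separability. The solver therefore
*lags* the degrees: the distance term uses embedding rows rescaled by the
degrees of the current iterate, keeping the weight step in closed form.
Each weight step is then an exact minimization of the criterion recorded in
`step_trace`, and the recorded objective never increases within an
iteration; in combinatorial mode, where no lagging is needed, the whole
trace is monotone at fixed $\alpha$ (both properties are asserted in the
test suite on every run).

**Isolated nodes.** Zero-degree nodes use the convention $d^{-1/2} = 0$, so
in normalized form an isolated node contributes a diagonal 1 — and hence an
eigenvalue of 1, not 0. The raw zero-eigenvalue count would miss it, so the
package's spectral component counter (`spectral_component_count()`, used by
the $\alpha$ schedule) adds the number of zero-degree nodes in normalized
mode. This restores the components-equal-zero-eigenvalues identity for both
Laplacian variants, which the suite cross-checks against union-find on
random sparse graphs.

**Warm start.** $W^{(0)} = \max(X^\top X, 0)$ with zero diagonal — the
nonnegative correlation network, which is the exact solution in the
$\lambda \to 0$, $\alpha \to 0$ limit.

**Degenerate eigenvalues.** When $\sigma_k = \sigma_{k+1}$ the embedding is
not unique; any orthonormal basis of the invariant subspace is accepted,
and tests compare subspaces or traces, never individual eigenvectors.

**Baseline solvers.** The $\ell_1$-penalized regression network is solved
column-wise by coordinate descent (glmnet) with the zero-diagonal
constraint enforced by excluding the response ROI from its own predictors;
without that constraint $W = I$ is a trivial near-minimizer. The
sparse-plus-low-rank baseline is solved by ADMM with two splitting
variables (elementwise soft-threshold for $\ell_1$, singular-value
soft-threshold for the trace norm) and an exact linear solve, via one
eigendecomposition of $X^\top X$, for the coupling block. Both regression
forms are asymmetric by construction and are symmetrized as
$(W + W^\top)/2$ post-solve. The test suite checks both solvers against
independent algorithms on the same objectives: proximal-gradient (ISTA) for
the $\ell_1$ problem and a product-space Douglas–Rachford splitting for the
composite problem.

# The evaluation protocol

For two-class cohorts (patient = class 1), `run_cv()` implements the
standard connectome-classification pipeline: each scan's network is
flattened to its $n(n-1)/2$ strict-upper-triangle edge weights (6,670
features for 116 ROIs), edges are screened by a two-sided pooled-variance
t-test at $p < 0.05$ on training data only, and a linear SVM with fixed
$C = 1$ classifies the held-out scans. Cross-validation is *subject-level*:
folds partition subjects, stratified by class, so repeated scans of one
person never straddle the train/test boundary. When a hyperparameter grid
is supplied, the value for each outer fold is chosen by an inner
subject-level CV on that fold's training portion alone. The fold
randomization is repeated (100 times at study scale) and metrics are
reported as mean ± sd of per-repeat means. If no edge passes the
selection threshold the single smallest-p edge is kept, with a message, so
a model can always be fitted.

Degenerate t-test features follow explicit conventions: zero pooled
variance with equal means gives $t = 0$, $p = 1$ (never selected); zero
variance with unequal means is infinitely significant. P-values are
uncorrected by default — selection is a screening step, not an inference —
with Welch's form available as an option. AUC uses the rank (Mann–Whitney)
construction with ties counted half.

# What the synthetic cohorts do and do not show

`modular_cohort_spec()` describes a Gaussian block model: unit-variance
signals correlating at `within_corr` (default 0.7) inside each of `k_true`
(default 8) planted modules and `between_corr` (default 0) across, with
shapes mirroring a typical study (116 ROIs, 137 time points, 48 control
and 95 patient subjects, 2 scans each). A covariance-specified generator
was chosen over a haemodynamic simulation deliberately: the estimators
consume only second-order structure, so ground truth is exact by
construction.

Two design points deserve emphasis:

* **Class differences live on within-module edges.** The patient class
  weakens `n_discriminative_edges` (default 20) within-module correlations
  by `effect_size` (default 0.3, constrained below
  `within_corr - between_corr`). Between-module pairs would be a useless
  place for class signal: a module-constrained estimator cuts those edges
  to reach $k$ components, in both classes, erasing the contrast before the
  classifier sees it.
* **Subjects are real entities.** Each subject draws one covariance (the
  class covariance plus a small symmetric jitter, re-projected to positive
  definite), shared by that subject's scans. Scans therefore cluster by
  subject, which is what makes subject-level CV meaningfully stricter than
  scan-level CV.

Passing tests on these cohorts demonstrate that the optimization, the
module-count guarantee, and the protocol plumbing are correct, and that the
pipeline recovers planted structure at high signal-to-noise. They do not
demonstrate performance on real fMRI, whose noise is autocorrelated,
nonstationary and confounded by motion and physiology; none of that is
modeled here.

# Problem sizes used by the tests and the acceptance script

Full-size checks (116 ROIs, 137 time points) are used where the quantities
themselves are size-specific: the 6,670-feature identity, the exact-8-module
fit, and planted-partition recovery (3 scans). Solver-vs-oracle comparisons
run on batches of random instances at $n \le 10$ (weight-step QP, 20
instances) and 5–6 ROIs (convex-solver objectives), the spectral-theorem
cross-oracle on 100 random graphs at $n \le 30$, and the cross-validation
protocol checks on cohorts of 16–20 subjects with 5 folds and 2–5 repeats —
sizes at which each check is decisive for correctness while the whole suite
stays fast. The permutation null is averaged over several label
permutations: at 16 subjects a single random relabeling can align with the
true classes by chance and retain genuine signal.

# Known limitations

* The module-count guarantee applies to the estimated network, not to the
  truth; with weak modular structure the solver still returns $k$
  components, found wherever the spectral cut is cheapest.
* Between-module edges are by construction absent from a converged AM-PC
  network, so analyses of cross-module connectivity need one of the
  baseline estimators.
* The normalized-mode objective trace is a per-iteration surrogate (lagged
  degrees); only the combinatorial mode has a globally monotone trace.
* Hyperparameter selection optimizes inner-CV accuracy; with heavily
  imbalanced cohorts an AUC-based choice may be preferable.
* `mpc_network()` scales as one SVD per ADMM iteration and is the slowest
  estimator here; it is a baseline, not the recommended tool.

# A minimal session

```{r, eval = FALSE}
library(ampcnet)

spec <- modular_cohort_spec(n_subjects_per_class = c(10, 10),
                            scans_per_subject = 1, seed = 1)
cohort <- generate_cohort(spec, seed = 1)

fit <- ampc_estimate(cohort$manifest$data[[1]], k = 8)
fit$k_observed            # 8, guaranteed at convergence
table(fit$partition$labels)

report <- run_cv(cohort$manifest, method = "am-pc", k = 8,
                 folds = 5, repeats = 5, seed = 1)
report$summary
```
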