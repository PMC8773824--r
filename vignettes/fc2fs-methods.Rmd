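---
title: "Multi-modal feature selection with correlation and structure fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal feature selection with correlation and structure fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fc2fs)
```

## The problem

Region-of-interest (ROI) studies of neurodegenerative disease typically
measure the same brain parcellation with several imaging modalities — for
example average gray-matter density per AAL region from structural MRI and
average glucose metabolism per region from FDG-PET. Each modality gives one
subjects-by-ROIs table, aligned on both axes. The scientific question is
which ROIs jointly discriminate two diagnostic groups, and the statistical
difficulty is that ROI features are strongly correlated with each other,
the number of subjects is comparable to the number of ROIs, and the
modalities carry complementary but overlapping information.

`fc2fs` implements a joint feature-selection model for this setting. One
least-squares task per modality is fit simultaneously, with three coupling
penalties, and the fitted weight matrix ranks the ROIs.

## The model

Let $X_i \in \mathbb{R}^{N\times p}$ be the standardized feature matrix of
modality $i$ ($i = 1,\dots,m$), $Y \in \{-1,+1\}^N$ the class labels used
as regression targets, and $W = [w_1,\dots,w_m] \in \mathbb{R}^{p\times m}$
the weight matrix, one column per modality. The objective is

$$
\min_W \; \sum_{i=1}^m \lVert Y - X_i w_i \rVert_2^2
\;+\; \alpha\, \mathrm{tr}(W^\top R\, W)
\;+\; \beta\, \mathrm{tr}(W^\top L\, W)
\;+\; \gamma\, \lVert W \rVert_*
$$

with three ingredients:

* **Feature-correlation penalty.** $R$ is the weighted average (uniform
  $1/m$ by default) of the per-modality feature–feature correlation
  matrices. The quadratic form discourages concentrating weight on clusters
  of mutually correlated features.
* **Feature-structure penalty.** $L = S - H$ is the graph Laplacian of a
  feature similarity graph: $H_{jk}$ is the cosine similarity between
  columns $j$ and $k$ of the $\tau$-blended feature matrix
  $\tau X_1 + (1-\tau) X_2$ when either column is among the other's $k$
  nearest neighbours by cosine similarity, and $0$ otherwise; $S$ is the
  diagonal degree matrix. Since
  $\mathrm{tr}(W^\top L W) = \tfrac12 \sum_{j,k} H_{jk}
  \lVert W_{j\cdot} - W_{k\cdot}\rVert^2$, geometrically close features are
  pushed toward similar weight rows.
* **Trace-norm penalty.** $\lVert W\rVert_*$, the sum of singular values,
  is the convex surrogate for $\mathrm{rank}(W)$; it couples the modality
  columns through a shared low-dimensional structure.

After the fit, ROI $j$ is scored by $\lVert W_{j\cdot}\rVert_2$ — its
weight across all modalities — and the top-$k$ ROIs are kept. The selected
columns of the two modalities are blended with the same $\tau$
(`mode = "blend"`; side-by-side concatenation is available as
`mode = "concat"`) and passed to a linear SVM for classification.

## Solver

The smooth part $\eta(W)$ (everything except the trace norm) has gradient
$$
\nabla \eta(W)_{\cdot i} = 2X_i^\top (X_i w_i - Y) + 2\alpha (R W)_{\cdot i}
 + 2\beta (L W)_{\cdot i},
$$
and the trace norm is handled by its proximal operator, singular-value
soft-thresholding: if $Z = U D V^\top$ then
$\mathrm{prox}_{t\lVert\cdot\rVert_*}(Z) = U \max(D - t, 0) V^\top$. The
iteration is

$$
W_k = \mathrm{prox}_{(\gamma/s)\lVert\cdot\rVert_*}
      \left(W_{k-1} - \tfrac1s \nabla\eta(W_{k-1})\right).
$$

Design choices worth spelling out:

* **Prox threshold $\gamma/s$, not $\gamma$.** The quadratic majorizer with
  curvature $s$ rescales the non-smooth term's effective threshold by the
  step; thresholding by a bare $\gamma$ would not minimize the majorizer
  and can overshoot badly for large $s$. This is a deliberate correction of
  a common notational shortcut.
* **Step length.** $s$ starts at the Lipschitz estimate
  $2(\max_i \sigma_{\max}(X_i)^2 + \alpha\sigma_{\max}(R) +
  \beta\sigma_{\max}(L))$, computed by power iteration, and is doubled
  whenever the smooth part exceeds its majorizer (backtracking). With this
  rule every accepted step decreases the objective, so the recorded loss
  history is non-increasing by construction and the standard
  $O(1/k)$ bound $\varphi(W_k)-\varphi^* \le s\lVert W_0 - W^*\rVert_F^2/(2k)$
  applies. We deliberately do not use momentum acceleration or
  Barzilai–Borwein steps: they are out of the method's scope, and the plain
  scheme keeps the descent property exact.
* **Initialization.** $W_0 = 0$: deterministic, and the first iteration
  already decreases the loss from the all-zero baseline $m\cdot N$.
* **Convergence.** Stop when the relative loss change
  $|\ell_k - \ell_{k-1}| / \max(1, \ell_{k-1})$ falls below `tol`
  (default $10^{-6}$) or after `max_iter` (default 1000) iterations.
* **Convexity.** $R$ is an average of correlation matrices; Pearson and
  Spearman correlation matrices are positive semidefinite, so the loss is
  convex. Kendall's $\tau_b$ matrix can have slightly negative eigenvalues;
  the solver proceeds but warns with $\lambda_{\min}(R)$.

## Regularizer construction details

* **"Adjacent" features.** The similarity graph uses $k$-nearest-neighbour
  selection by cosine similarity with union symmetrization
  ($j \sim k$ if either is in the other's neighbour list), the standard
  manifold-learning construction; default $k = 5$.
* **Negative similarities** are clipped to zero in $H$ (configurable).
  Clipping guarantees $H \ge 0$, hence a positive semidefinite Laplacian
  and a convex structure penalty.
* **Signed correlations.** $R$ uses signed correlations as they come;
  an absolute-value variant is available (`absolute_correlation = TRUE`)
  but off by default, because flipping signs changes which weight patterns
  the penalty rewards.
* **Ties and ranks.** Spearman uses average ranks; Kendall is $\tau_b$.
  $R$ is symmetrized as $(R + R^\top)/2$ to absorb floating-point
  asymmetry.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | $2^{-2}$ | weight of the correlation penalty |
| `beta` | $2^{-2}$ | weight of the structure penalty |
| `gamma` | $2^{-1}$ | weight of the trace norm |
| `tau` | 0.3 | blend weight of modality 1 (modality 2 gets $1-\tau$) |
| `corr_method` | pearson | correlation type for $R$ |
| `knn_k` | 5 | neighbours in the feature graph |
| `top_k` | 15 | number of selected ROIs |
| `max_iter`, `tol` | 1000, $10^{-6}$ | solver stopping rule |

All are unitless. The defaults for `alpha`, `beta`, `gamma` sit in the
middle of the sensitivity grids the method is normally swept over
($\alpha,\beta \in \{2^{-1},\dots,2^{-5}\}$, $\tau \in \{0,0.1,\dots,1\}$),
which `grid_search()` reproduces on any dataset.

## Evaluation layer

`cross_validate()` runs repeated stratified $k$-fold cross-validation
(default $10\times 10$). Within each fold, **everything data-dependent is
refit on training rows only**: z-score statistics (sample convention,
denominator $N-1$), per-modality correlation matrices, the feature graph,
the weight matrix, the ranking, and the selection. Test rows are
standardized with the training statistics and scored by a linear SVM
(cost 1) trained on the fused selected training features; its decision
values feed a rank-based (Mann–Whitney) AUC with ties credited 0.5. This
leakage discipline is verifiable: corrupting test-fold rows leaves the
fitted per-fold weight matrices bit-identical, which the test suite
asserts.

Metrics are ACC, AUC, SEN, SPE, GMean and F1 from the fold confusion
counts, aggregated as mean ± sd over all folds × repeats (the two
aggregation axes are not distinguished). Zero-denominator ratios return 0
and are flagged rather than returned as NaN. GMean is
$\sqrt{\mathrm{SEN}\cdot\mathrm{SPE}}$; a variant that instead returns the
plain sum SEN + SPE exists behind `gmean_as_printed = TRUE` for
comparability with sources that define it that way, but the sum exceeds 1
for any decent classifier and is not recommended. The positive class is
the disease group by convention; labels are coded $-1/+1$ so they can
serve directly as symmetric regression targets.

`grid_search()` evaluates every grid point with a shared fold seed and
ranks by mean ACC, breaking ties toward larger `alpha`, `beta`, `gamma`
and then smaller `tau`, so sweeps are reproducible.

## The synthetic generator

`generate_dataset()` draws datasets with planted ground truth so that every
stage is testable without any image data:

* features are block-equicorrelated Gaussians (blocks of `block_size`,
  pairwise correlation `within_block_rho`, independent across blocks) —
  the minimal model in which both the correlation penalty and the feature
  graph are non-trivial;
* modality 2 is `mixing_tau` times modality 1 plus an independent draw,
  giving controllable cross-modal correlation
  $\tau_{\mathrm{mix}}/\sqrt{\tau_{\mathrm{mix}}^2+(1-\tau_{\mathrm{mix}})^2}$;
* the planted weight matrix is $W^{\mathrm{true}} = AB^\top$ with $A$ zero
  outside `support_size` uniformly chosen rows and Gaussian inside, so
  $W^{\mathrm{true}}$ is exactly row-sparse with exactly `weight_rank`
  nonzero singular values;
* labels are $\mathrm{sign}(\frac1m\sum_i X_i w_i^{\mathrm{true}} +
  \varepsilon)$ with $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$, ties at
  exactly zero resolved to $+1$ — a sign-threshold model matching the
  least-squares-on-labels fit.

Defaults (120 subjects, 90 features, two modalities, 15 informative
features, $\rho = 0.5$, rank 2, noise sd 0.5, mixing 0.5) mirror the scale
of ROI-level studies of cognitive impairment.

**What the generator does not emulate**: site and scanner effects,
non-Gaussian marginals, modality-specific missingness, atlas
misregistration, and realistic effect sizes. Passing tests on synthetic
data show the machinery is correct and leakage-free, not that any
particular accuracy will transfer to a clinical cohort.

**A deliberate difficulty.** The default regime is statistically hard:
labels pass through a sign function, which caps the label–feature linear
correlation at $\sqrt{2/\pi}$ of its latent value and makes ranking
scale-invariant in the planted weights, and $p = 90$ features against
$N = 120$ subjects inflates least-squares variance roughly fourfold. In
this regime no linear procedure — including exact per-modality least
squares or oracle marginal screening, which we measured alongside the
model — recovers the full planted support in its top 15; roughly half is
typical at the default penalty weights, and the cross-validated accuracy
sits well below the noiseless ceiling. The acceptance script reports
exactly what the pipeline achieves here (`recovery_top15_pct`,
`cv_acc_pct`, `null_acc_pct`, `best_tau`) rather than an idealized figure.
Raising `n_subjects` or lowering `support_size` moves the regime toward
easy recovery if a benign benchmark is wanted.

## Numerical conventions and degenerate inputs

* Sample standard deviation (denominator $N-1$) everywhere, matching the
  correlation conventions.
* Zero-variance columns are an error naming the offending feature, both in
  normalization and in correlation construction; missing values are
  rejected at construction, never imputed.
* Ranking ties break toward the smaller feature index; fold assignment and
  label permutation are the only random elements of evaluation and are
  fully determined by the supplied seed.
* Exact-zero latent scores in the generator become $+1$; degenerate
  single-class draws are an error rather than a silent imbalance.
* Problem sizes in the test suite: unit tests run at $N \le 60$,
  $p \le 20$; end-to-end property tests use the default 120 × 90 study
  shape with 10-fold cross-validation at 1–2 repeats, which keeps the full
  suite in the low minutes while exercising realistic dimensions.

## Known limitations

* The empirical error is the printed sum over modalities of squared
  residuals (not averaged over subjects); with very different modality
  scales after normalization this is harmless, but unnormalized inputs
  would implicitly weight modalities by variance.
* The trace-norm prox requires a full SVD of a $p \times m$ matrix per
  iteration — cheap for $m \le 3$, the intended regime.
* Hypergraph or subject-space (row-space) graphs are out of scope, as are
  momentum-accelerated solvers and exact rank constraints.
* With `corr_method = "kendall"` the loss can be locally nonconvex (see
  above); results remain usable but the monotone-descent guarantee is the
  only one that survives.
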