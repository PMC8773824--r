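# fc2fs

Joint feature selection for aligned multi-modal region-of-interest (ROI)
data — e.g. per-region gray-matter density from structural MRI together
with per-region glucose metabolism from PET measured on the same subjects
and the same atlas — aimed at finding the brain regions that discriminate
two diagnostic groups (such as normal controls vs. Alzheimer's disease or
stages of mild cognitive impairment).

## The model

With $X_i \in \mathbb{R}^{N\times p}$ the standardized feature matrix of
modality $i$, $Y \in \{-1,+1\}^N$ the labels, and
$W = [w_1,\dots,w_m] \in \mathbb{R}^{p\times m}$ the per-modality weight
columns, `fc2fs` minimizes

$$
\sum_{i=1}^m \lVert Y - X_i w_i \rVert_2^2
+ \alpha\,\mathrm{tr}(W^\top R W)
+ \beta\,\mathrm{tr}(W^\top L W)
+ \gamma\,\lVert W \rVert_*
$$

where $R$ is the fused (weighted-average) feature–feature correlation
matrix, $L = S - H$ is the Laplacian of a cosine k-nearest-neighbour graph
built on the $\tau$-blended feature matrix $\tau X_1 + (1-\tau)X_2$, and
$\lVert W\rVert_*$ is the trace (nuclear) norm, the convex surrogate for
rank. The problem is solved by proximal gradient descent with
backtracking; the trace-norm proximal step is singular-value
soft-thresholding. ROIs are ranked by the row norms
$\lVert W_{j\cdot}\rVert_2$, the top-k are selected and blended across
modalities, and a linear SVM evaluated by repeated stratified 10-fold
cross-validation reports ACC, AUC, SEN, SPE, GMean and F1.

See `vignettes/fc2fs-methods.Rmd` for the full model, solver and design
discussion.

## Worked example

Everything below runs on synthetic data with planted ground truth; no
downloads are needed.

```r
library(fc2fs)

## two-modality dataset: 120 subjects, 90 ROI features, 15 informative
sim <- generate_dataset(synthetic_spec(seed = 42))

## normalize, build regularizers, fit, rank — one call
res <- fc2fs(sim$dataset)
res$model
#> <fc2fs_model> W: 90 x 2; 815 iterations (converged); final loss 36.9379

region_report(select_top_k(res$selection, 5))
#>   rank feature_label score weight_sMRI weight_PET region_name
#> 1    1        ROI071 0.625      0.3103     0.5429
#> 2    2        ROI024 0.535     -0.4404    -0.3041
#> 3    3        ROI048 0.483      0.4761    -0.0812
#> 4    4        ROI062 0.463     -0.3834    -0.2587
#> 5    5        ROI040 0.417      0.0574    -0.4128

## cross-validated classification of the selected, fused features
cross_validate(sim$dataset, n_folds = 10, n_repeats = 2, seed = 1)
#> <fc2fs_eval> 10 folds x 2 repeats
#>   ACC   0.8038 +/- 0.0962
#>   AUC   0.8819 +/- 0.0991
#>   SEN   0.7617 +/- 0.1395
#>   SPE   0.8440 +/- 0.1452
#>   GMean 0.7951 +/- 0.0982
#>   F1    0.7897 +/- 0.1019
```

The model converges in a few hundred proximal-gradient iterations; the
region report lists the top-ranked ROIs with their per-modality weights
(anatomical names appear when an ROI map is supplied); the evaluation
block is mean ± sd over all folds × repeats, with every data-dependent
step (normalization, correlation matrices, feature graph, fit, selection)
refit inside each training fold. Hyperparameter sweeps over
$\tau \in \{0, 0.1, \dots, 1\}$ and
$\alpha, \beta \in \{2^{-1},\dots,2^{-5}\}$ are available through
`grid_search()`.

Real data enter through delimited tables — one CSV per modality (header =
feature labels, first column = subject id), a two-column labels CSV, and an
optional ROI-name map — via `read_modality_matrix()`, `read_labels()` and
`read_roi_map()`. A thin command-line wrapper with `simulate` / `fit` /
`select` / `evaluate` / `gridsearch` subcommands lives at
`inst/cli/fc2fs.R`.

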