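---
title: "Floating-window data trimming for SVM classifiers: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating-window data trimming for SVM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowps)
```

## The problem

Clinical response classifiers built from gene expression typically have tens
of patients and (after marker selection) tens of features. In that regime a
support vector machine is routinely asked to predict at points that lie
*outside* the cloud of training samples along many feature axes — it
extrapolates, and soft-margin SVMs are notoriously brittle under
extrapolation. This package implements a per-test-sample data-trimming
meta-algorithm around the SVM that converts extrapolation into
interpolation, together with the marker-gene selection pipeline, the
classifier-quality metrics, and two baselines (classical SVM and
PCA-assisted SVM) needed to evaluate it.

## The method

For each validation sample $i$ (in leave-one-out, each patient in turn), the
training set of the remaining $N-1$ samples is adapted to $i$ in two steps:

1. **m-condition (feature trimming).** A feature $f_j$ is kept only if at
   least $m$ training projections lie strictly below *and* at least $m$
   strictly above the validation value $f_j(i)$. Values exactly equal to
   $f_j(i)$ count as neither (this makes the rule well defined on tied
   data). $m = 0$ keeps every feature; a feature on which the validation
   point falls outside the training cloud survives only at $m = 0$.
2. **k-window (sample trimming).** In the surviving feature space, only the
   $k$ nearest training samples (Euclidean distance, on the data's given
   scale) are kept to fit the SVM. The default uses no re-standardization —
   quantile-normalized expression is fed to the SVM unscaled, so the window
   uses the same geometry; `scale_features = TRUE` optionally z-scores each
   surviving feature by its training-fold standard deviation for the
   distance only (zero-variance features then drop out of the distance).

Neither $(m, k)$ is fixed globally. For every validation sample the pair is
scored on the training data alone: an *inner* leave-one-out within the
$N-1$ training samples yields predictions per cell of the $(m, k)$ lattice,
and each cell is scored by the ROC AUC of those inner predictions — the AUC
*topogram*. All valid cells whose AUC reaches
$\theta = p \cdot \max(\mathrm{AUC})$ form the *prediction-accountable set*
$S_i$; the final prediction is the average of the per-cell SVM outputs,
$P_F = \mathrm{mean}_{S_i} P(m,k)$, on a 0–100 scale (responder = 100).
The cell $(m = 0,\; k = N-1)$ is exactly the classical SVM, so the method
can never be *structurally* worse than its baseline: if no trimming helps,
the corner dominates the topogram.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kernel` | linear | SVM kernel; polynomial uses degree 3, `coef0 = 0`, `gamma = 1/d` over the surviving features (the usual libsvm-style defaults) |
| `C` | 1 | soft-margin cost; the interesting sweeps are 0.1–1000 |
| `p` | 0.95 | accountable-set confidence; 0.90 admits more cells and more averaging |
| `k_min` | 20 | smallest window; below ~20 samples an SVM fit is too unstable to score |
| `m_max` | auto | per-sample cap: the largest m at which the validation point keeps any feature, bounded by $\lfloor (N-1)/2 \rfloor$ |
| `prediction_mode` | label | per-cell hard 0/100 votes (bounded $P_F$); `decision` averages signed margins instead |

The k grid runs over every integer from `k_min` to $N-1$. For tiny datasets
($N - 1 < 20$, synthetic fixtures mostly) the grid falls back to
$\max(3, N-11) \dots N-1$ so the machinery stays exercisable. The m range is
not prescribed by the method itself; the auto cap is the natural upper end
because beyond it the validation sample has no surviving feature at all.

## Numerical and algorithmic choices

* **SVM solver.** No SVM library is available in the target environment, so
  the package carries a small deterministic SMO (sequential minimal
  optimization) solver in C++ (KKT tolerance $10^{-3}$, fixed working-set
  heuristics, no randomization). The test suite pins it against an
  independent quadprog dual-QP solution: dual objectives agree to
  $10^{-4}$ relative, decision values to a few $10^{-3}$.
* **Inner resampling.** The topogram is computed by leave-one-out *within*
  the $N-1$ training samples (nested LOO). Resubstitution would be
  optimistic; the nested scheme mirrors the outer evaluation.
* **Caching.** For a fixed inner point, the feature mask changes only at
  the distinct per-feature flanking caps, so masks, distance rankings and
  kernel matrices are cached per (point, distinct mask) and reused across
  the m grid and the k sweep. This is an exact optimization: a dedicated
  test verifies the fast path equals the naive composition of
  `trim()` + `svm_cell_predict()` cell by cell.
* **Degenerate cells.** A cell where any inner point loses all features is
  invalid as a whole (conservative; keeps cell AUCs comparable) and can
  never enter the accountable set. Single-class neighborhoods return the
  common label without fitting. The threshold comparison is
  `AUC >= theta`, so the argmax cell always qualifies and $S_i$ is never
  empty; with the strict form an all-tied topogram would make $S_i$ empty.
  The comparison carries a $10^{-9}$ slack so that a cell whose AUC equals
  the threshold exactly is not lost to floating-point rounding of
  $p \cdot \max(\mathrm{AUC})$.
* **Ties.** Distance ties resolve to the lower training index; equal
  ranking AUCs resolve lexicographically by gene id; the discrimination
  threshold resolves to the smallest candidate. All three rules exist only
  to make results reproducible.
* **Predictions at decision zero** are called non-responder (the call rule
  is strictly `score > tau`, and a decision value of exactly 0 maps to the
  0 label).

## Feature selection

Markers are ranked by single-gene ROC AUC (Mann–Whitney with 0.5 credit per
tied pair — identical code to the classifier-level AUC). By default genes
are ranked on the *oriented* AUC $\max(A, 1-A)$, so down-regulated markers
compete equally with up-regulated ones; the raw ranking is available via
`rank_by = "raw"` because the original recipe does not state the
orientation. The *core* marker set intersects the top-30 lists of all $N$
leave-one-out subdatasets, keeping only markers whose selection survives
the removal of any single patient.

A caveat on interpreting core sets: the $N$ leave-one-out subdatasets share
all but one sample, so per-gene AUCs move by $O(1/N)$ between them and the
top-30 lists are strongly correlated. Simulation on null data (no
informative genes, 2000 candidates, $N = 50$) shows the intersection
settles around 15–18 of 30 — the procedure prunes boundary churn but a
sizeable core set is *not* by itself evidence of signal. Core-set
*membership stability* is what the step buys, not a null-calibrated
significance filter.

## Metrics

`metrics_report()` reports AUC plus the thresholded panel at the
discrimination threshold $\tau$ chosen to minimize $FP + FN$ (candidates:
midpoints between distinct scores plus sentinels beyond both extremes).
FDR is the per-classifier false-discovery fraction $FP/(FP+TP)$ at $\tau$ —
a single number per classifier, not a multiple-testing procedure. MCC and
FDR are defined as 0 when their denominators vanish. One $\tau$ is used for
all thresholded metrics.

## Baselines

The classical SVM is literally the corner cell run for every sample; a test
asserts byte-identical prediction vectors between the two code paths. The
PCA-assisted SVM fits principal components on each outer training fold
(covariance PCA on training-mean-centered data, no variance scaling —
matching the fact that expression values are fed to the SVM unscaled
elsewhere), selects the number of components by inner leave-one-out AUC on
the training scores (candidates default to $1..\min(10, N-2, s)$, smallest
wins ties), and predicts the held-out sample projected with the training
loadings. The selection is nested per fold; a global selection would leak
the held-out sample into the component choice.

## What the synthetic generators emulate — and what they do not

* `make_global_linear()`: two Gaussian classes split by `effect_size` along
  a few coordinates — the positive control where every method should work.
* `make_checkerboard()`: tight clusters on a 4×4 grid with alternating
  class, cluster sd 0.1 of the cell width — *local* order with no global
  linear order. The default keeps exactly the two informative dimensions
  (the regime is intrinsically planar; extra noise features are available
  via `n_features`). This is the structure on which a global SVM should
  fail and a windowed method should not.
* `make_expression_like()`: log-scale values, gene baselines drawn over a
  10-log-unit range, sample-specific offsets (so quantile normalization is
  exercised), and a small panel of informative genes shifted by
  `effect_size` (default 1.5 log units, 20 genes among 2000, N = 60 —
  desk-scale versions of real cohort geometry).

None of the generators emulate platform-specific artifacts, count
overdispersion, batch effects or censoring-derived label noise. A green
test on them establishes algorithmic correctness and the qualitative
local-vs-global contrast, *not* clinical performance; the published
cohort-level AUC/FDR tables require the original patient matrices and
multi-hour sweeps (see `scripts/reproduce_tables.R`, which runs the full
pipeline on user-supplied matrix and label files).

One empirical caveat surfaced by the checkerboard control: with *exactly*
balanced classes, leave-one-out makes the training majority always the
class opposite to the held-out sample. A globally degenerate SVM (which the
checkerboard forces by construction) then predicts that majority and scores
an LOO AUC near 0 — systematically inverted, not merely uninformative.
This is a known artifact of LOO on balanced data with majority-like
classifiers; the windowed classifier, whose accountable cells are chosen by
the inner AUC, sits near or above chance on the same data. The qualitative
superiority claim therefore holds with a wide margin, but the classical-SVM
AUC on this generator should be read as "fails", not "coin flip".

## Known limitations

* Binary classification only; labels are a hard 0/100 coding.
* The nested LOO costs $O(N^2 \cdot |\text{grid}| )$ SVM fits per dataset;
  the compiled solver and mask-level caching keep desk-scale runs
  (N ≤ 100, s ≤ 30 markers) in seconds-to-minutes, but thousands of raw
  features without marker pre-selection are out of reach by design — the
  pipeline expects the top-30 / core-gene step first.
* Missing values are rejected, never imputed: imputation would corrupt the
  order statistics the m-condition counts.
* Whether expression values are log-transformed is the caller's decision;
  the package treats the matrix as given (quantile normalization is
  provided but optional).
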