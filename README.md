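# flowps

Per-test-sample data trimming for SVM classification of clinical response
from gene expression.

Drug-response cohorts are small (tens of patients) and, even after marker
selection, a support vector machine trained on them is routinely forced to
*extrapolate*: the patient being classified lies outside the training cloud
along many feature axes. This package implements a floating-window
meta-algorithm that adapts the training data to every test sample before
the SVM sees it:

1. **m-condition.** For validation sample $i$, keep feature $f_j$ only if at
   least $m$ training projections lie strictly below and at least $m$
   strictly above $f_j(i)$ on that axis.
2. **k-window.** In the surviving feature space, keep only the $k$ nearest
   training samples (Euclidean).
3. **Topogram.** Score every $(m, k)$ cell by the ROC AUC of an inner
   leave-one-out within the $N-1$ training samples.
4. **Accountable set.** Keep all cells with
   $\mathrm{AUC} \ge \theta = p\cdot\max(\mathrm{AUC})$ (confidence
   $p \in \{0.95, 0.90\}$ typically) and average their SVM outputs:
   $P_F = \mathrm{mean}_S\, P(m,k)$ on a 0–100 scale (responder = 100).

The cell $(m{=}0, k{=}N{-}1)$ *is* the classical SVM, so the classical
baseline is a corner of the same lattice. The package also provides the
marker pipeline (single-gene Mann–Whitney AUC ranking, top-30 panels, the
leave-one-out *core gene* intersection), quantile normalization, class
equalization, the metrics panel (AUC, FDR, Sn, Sp, ACC, MCC at the
FP+FN-minimizing threshold τ), a PCA-assisted SVM baseline, and seeded
synthetic-data generators. The SVM itself is a small deterministic SMO
solver compiled with the package (linear and degree-3 polynomial kernels,
libsvm-style defaults), cross-checked in the tests against an independent
quadprog dual solution.

## Worked example

Locally ordered, globally disordered data (alternating clusters on a 4×4
grid) is exactly the regime where a global SVM fails and the floating
window does not:

```r
library(flowps)

ds  <- make_checkerboard(n_samples = 64, grid_dim = 4, seed = 1)
cfg <- flowps_config(kernel = "linear", C = 1, p = 0.90)

fit  <- flowps_loo(ds, cfg)
base <- classical_svm_loo(ds, cfg)

fit
#> <flowps LOO> N=64  AUC=0.5  FDR=0.429  ACC=0.578  (linear-C1-p0.9-kmin20-mauto-label)
base
#> <classical_svm LOO> N=64  AUC=0  FDR=0.5  ACC=0.5  (linear-C1-p0.9-kmin20-mauto-label)
```

The classical SVM is not merely at chance here — under leave-one-out on
exactly balanced classes a globally degenerate SVM predicts the training
majority, which is always the opposite class, so its AUC collapses to 0
(a known LOO artifact; see the vignette). The windowed classifier, whose
cells are selected by the inner AUC, stays at or above chance; over 10
seeds its median LOO AUC strictly exceeds the classical median.

On separable data both agree perfectly, and `glance()`/`tidy()` give the
tabular views:

```r
ds2 <- make_global_linear(n_samples = 40, n_features = 5, effect_size = 6, seed = 30)
glance(flowps_loo(ds2, cfg))
#> # A tibble: 1 x 14
#>     auc   tau   fdr    sn    sp   acc   mcc     n    tp    fp    tn    fn classifier config
#> 1     1    45     0     1     1     1     1    40    20     0    20     0 flowps    linear-C1-p0.9-kmin20-mauto-label
```

A typical cohort run chains the marker pipeline in front:

```r
ds |>
  quantile_normalize() |>
  equalize_classes(seed = 1) |>
  (\(d) select_genes(d, core_genes(d, 30)))() |>
  flowps_loo(flowps_config(p = 0.90))
```

A thin command-line front end over the same functions ships at
`inst/cli/flowps.R` (subcommands `run`, `baseline`, `features`,
`simulate`); all file outputs are plain TSV tables.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed package,
the two worked flanking-point configurations (a feature axis with five
training projections strictly on each side of the validation point, and an
axis where the validation projection lies outside the training cloud) and
writes the largest m passing the m-condition for each as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`scripts/reproduce_tables.R` is the optional integration runner: given a
cohort expression matrix and labels (not shipped), it reproduces the
classical-vs-floating-window comparison table on the top-30 and core
marker panels. Expect hours for cohorts with hundreds of patients.
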