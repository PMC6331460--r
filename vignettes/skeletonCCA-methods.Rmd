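---
title: "Mapping brain-behavior associations with reduced-rank canonical correlation"
author: "skeletonCCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain-behavior associations with reduced-rank canonical correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skeletonCCA)
```

## The problem

Voxelwise white-matter statistics — for example fractional anisotropy (FA)
sampled on a TBSS skeleton — give each subject a feature vector of $P$
in-mask voxels, with $P$ (tens of thousands) far exceeding the cohort size
$N$ (tens to low hundreds). The scientific question this package addresses
is whether a single behavioral score (a personality factor, a cognitive
scale) shares a linear latent dimension with that voxel block, and if so,
*which voxels carry the association and with what sign*.

The model is a one-pair canonical correlation analysis (CCA) between the
reduced voxel block and the score. Because the behavioral block is one
column, CCA degenerates to the multiple correlation of a regression: the
canonical weights $E$ on the reduced imaging scores are proportional to
OLS coefficients and the canonical correlation $R$ equals
$\sqrt{R^2_{\mathrm{OLS}}}$. The package keeps the CCA framing (weights,
variates $U = X^{(Q)}E$, $V = F\,y$) because all the resampling machinery
is built on it.

## The pipeline

For each score, independently:

1. **Reduction.** The $N \times P$ matrix is column-centered and reduced by
   truncated SVD to $Q$ orthogonal score columns
   (`fitTruncatedSVD()`). CCA needs a full-rank block, and $P \gg N$
   makes reduction mandatory.
2. **Dimensionality.** $Q$ is chosen by leave-one-out cross-validation
   (`loocvSelectQ()`): for each candidate $q$ and each held-out subject,
   the basis and canonical fit are recomputed on $N-1$ subjects, the
   held-out subject is projected through them, and the pooled correlation
   of the $N$ held-out variate pairs is the CV correlation; the $q$
   maximizing it wins, ties going to the smallest $q$. Pooling (rather
   than per-fold correlations, undefined for single-subject folds) is the
   implemented reading.
3. **Significance.** The observed $R$ at the selected $Q$ is compared with
   the null distribution obtained by permuting the score vector 10000
   times (`permutationTest()`). Permuting $y$ leaves the feature block
   unchanged, so the SVD basis is computed once and reused. The p-value
   uses the add-one estimator $(1 + \#\{R_{null} \ge R\})/(1 + n_{perm})$,
   which can never be zero.
4. **Saliency.** Subjects are resampled with replacement into $B = 1000$
   folds (`bootstrapSaliency()`). Each fold's SVD components are aligned
   to the full-data components by orthogonal Procrustes rotation
   (reflections included — component sign flips *are* reflections), the
   canonical pair is refit, weights are back-projected to voxel space, and
   the fold's global sign is corrected against the full-data reference.
   The per-voxel bootstrap ratio (fold mean / fold SD) is a pseudo-z
   reliability score, thresholded at 1.96; the surviving voxels form a
   signed map (+1: higher feature value with higher score).
5. **Display.** For rendering, the signed map can be thickened into
   neighboring voxels with mean feature value above 0.2
   (`fillForDisplay()`); this never feeds back into analysis.

Age and gender enter as co-regressors by residualizing *both* blocks on
them (`residualize()`, `adjustedAndUnadjusted()`); results are reported
unadjusted and adjusted.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nPerm` | 10000 | permutations for the p-value; 199 is enough for calibration studies |
| `bFolds` | 1000 | bootstrap folds; ratios stabilize above ~100 |
| `threshold` | 1.96 | two-sided 5% normal critical value on the bootstrap ratio |
| `faThreshold` | 0.2 | mean-FA mask restriction, applied to the across-subject mean |
| `qMax` | full | cap on the LOO-CV grid $1..N-2$ |

The sign convention fixes $F > 0$ (the behavioral weight), so $R \ge 0$
always and a positive voxel weight means the feature rises with the score.
The published analysis fixes signs only relative to a reference fold; we
take the full-data solution as that reference because it is unique and
deterministic.

## The synthetic cohort generator

No clinical data ship with the package; `generateCohort()` plants a known
rank-one association to calibrate and stress the pipeline:

$$X = s\,z a^\top + E, \qquad
  y = \alpha z + \beta_{age}\,\mathrm{age} + \beta_{gender}\,\mathrm{gender} + \varepsilon$$

with $z, \varepsilon \sim N(0,1)$, noise $E_{ij} \sim N(0,\sigma^2)$, and a
unit-norm loading $a$ supported on `nSalient` voxels with a configurable
share of negative signs. Two closed-form calibrations define the defaults:

* $\alpha = \rho/\sqrt{1-\rho^2}$ makes the population correlation between
  the latent $z$ and the score exactly $\rho$ (with confounds at zero);
* $s = \sigma\sqrt{n_{salient}}$ gives each salient voxel a per-voxel
  signal-to-noise ratio of 1, so the oracle projection $Xa$ recovers $z$
  with correlation $\sqrt{n_{salient}/(n_{salient}+1)}$ (about 0.99 at the
  default 50), and the best linear readout of $X$ attains essentially
  $\rho$ against $y$.

Defaults (N = 160, about 20000 skeleton voxels, $\rho = 0.6$, 50 salient
voxels, 30% negative) emulate a controls-sized elderly cohort whose
full-data $R$ lands in the 0.4–0.9 range typical of such fits. Ages are
uniform on 65–80 and gender Bernoulli(1/2); confounds enter the score
only, which is sufficient to exercise the co-regression path. The mask is
a random thin sheet set — the analysis is geometry-agnostic, so only the
mask bookkeeping needs to be realistic, not the anatomy. Noise is i.i.d.
across voxels by default; an optional Gaussian smoothing switch
(`smoothFwhm`) adds spatial autocorrelation, but the method makes no
spatial assumption so the default omits it. What passing tests on these
cohorts do *not* show: robustness to registration error, anatomical
spatial correlation structure, non-Gaussian FA distributions, or
site/scanner effects.

## Numerical choices

* Column order of the flattened voxel dimension is the column-major raster
  order of the mask (first grid index fastest) — fixed, documented, and a
  pure function of the mask.
* Centering statistics always come from the fitting data and are reused
  for held-out projections.
* Singular values below $10^{-10}\sigma_1$ are dropped with a warning
  rather than inverted.
* Bootstrap folds with a constant resampled score (or rank collapse below
  $Q$) are redrawn, up to 100 times; CCA is undefined there.
* Bootstrap SD uses the $B-1$ denominator; a zero-variance voxel weight
  distribution gets the sentinel $\mathrm{sign}(\mathrm{mean})\cdot\infty$
  and is flagged.
* In the display fill, a voxel reached by both signs takes the sign of the
  summed contributions; exact ties stay 0. Suprathreshold voxels keep
  their own sign.
* The LOO-CV argmax breaks ties toward the smallest $q$ (parsimony).

## Design decisions that were genuinely open

* **$Q$ is selected once, on unpermuted data, and held fixed during
  permutation.** Re-selecting per permutation would change the null
  hypothesis being tested. The cost of this reading is quantified below.
* **Permutations reuse the full-data SVD basis**, since permuting $y$
  cannot change $X$.
* **Procrustes uses the full orthogonal group** (rotations + reflections)
  because SVD component signs are arbitrary.
* **The bootstrap-ratio threshold is read as 1.96**, the two-sided 5%
  normal critical value.
* The study driver analyzes one group per invocation and computes no
  between-group statistics; group contrasts are a different design.

## Known limitations

* **Selection inflation.** Choosing $Q$ by LOO-CV on the same pairing that
  the permutation test then evaluates inflates the type I error of the
  *full chain*: on null cohorts (N = 50, P = 200) the rejection rate at
  $\alpha = 0.05$ is about 0.11 with LOO-CV-selected $Q$, versus 0.050
  (exact) at any preset $Q$. The permutation machinery itself is exactly
  calibrated; the inflation is a property of the selection-then-test
  procedure, and p-values near the threshold should be read accordingly.
* With a rank-one signal the CV curve is nearly flat beyond the true rank,
  so the selected $Q$ fluctuates between replicates even though $R$ at the
  selected $Q$ barely moves; averaging CV curves across replicates
  recovers the small true rank.
* A one-column behavioral block only; multi-pair CCA (K > 1), sparse or
  kernel variants are out of scope.
* No familywise correction across scores is applied; scores are analyzed
  and reported independently.

## Problem sizes used in the shipped checks

Unit and property tests run on cohorts of N = 10–160 subjects and up to a
few thousand voxels; the simulation studies use N = 150, P = 2000 with 20
replicates (parameter recovery), 500 null cohorts of N = 50, P = 200
(permutation calibration), and B = 300 bootstrap folds (saliency
recovery) — sizes at which the Monte-Carlo error is well below the asserted
tolerances while a full run stays in the minutes range on one CPU. The
acceptance script reports the same quantities at the same scales.
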