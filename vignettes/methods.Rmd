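---
title: "Methods: repeated-split GMD classification and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-split GMD classification and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedure the package implements,
the design choices made where more than one convention was defensible, the
generative model behind the synthetic cohorts, and what the passing test
suite does and does not establish about real data.

## 1. The analysis pipeline

### Masking and features

A single grey-matter mask is built from one template pair of tissue
probability maps: voxel $v$ is included iff $\mathrm{gm}(v) > 0.40$ and
$\mathrm{wm}(v) < 0.60$, with **both inequalities strict**. Boundary voxels
differ between conventions, so the choice is fixed and tested; the mask is
serialisable as a uint8 NIfTI whose header description records the voxel
linearization rule. That rule — ascending linear index in the column-major
storage order of the volume — defines the column order of every feature
matrix, making matrices comparable across runs and machines.

The tissue-probability inputs are template/mean maps, one pair per study,
not per-subject maps: the analysis uses one shared mask for all subjects.
Feature values are GMD in $[0,1]$ read directly at mask coordinates;
no standardization, reduction or selection is applied at any point.

Gaussian smoothing (`smooth_volume()`) is provided for synthetic images
only; real modulated-smoothed inputs are consumed as-is, since smoothing
belongs to the upstream segmentation pipeline. The kernel uses
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis converted to voxel
units, truncated at $4\sigma$, applied separably with per-row
renormalization: constants are preserved everywhere, and on the interior
(further than the truncation radius from any edge) the operation equals
plain convolution with the normalized kernel, which the oracle test checks
against direct kernel evaluation.

### Classifier

Each model is a binary L2-penalized logistic regression,
$$\min_{w,b}\; \tfrac12\|w\|^2 + C\sum_i \log\!\big(1 + e^{-y_i (w^\top x_i + b)}\big),
\qquad C = 1,$$
with an **unpenalized intercept** — the parameterisation used by liblinear,
in which "penalty = 1" is the cost $C$. Features stay on their native GMD
scale; with all features sharing the $[0,1]$ range, standardization is
unnecessary and is deliberately omitted.

The solver is deterministic: an L-BFGS pass followed by damped Newton
steps whose directions are obtained by conjugate-gradient solves of
Hessian-vector products (the Hessian is never formed; one product costs
$O(np)$). The fit is accepted when the gradient max-norm falls below
$10^{-6}$; the solution is therefore independent of the solver path, which
the tests confirm by matching an independent ridge-logistic implementation
(`glmnet` with $\lambda = 1/(nC)$) to $10^{-4}$.

### Split design and evaluation

Each iteration draws, without replacement, 88 training cases per in-scheme
group — the three psychosis groups and CON — with a **single CON draw
shared by all three models of that iteration**. Every group's test set is
its full complement, so with the default biotype group sizes
(150/185/222/251) the held-out counts are 62/97/134/163 per iteration, and
154/50/89/163 under the diagnosis scheme (242/138/177/251). The other
scheme's labels play no role in case selection. The training size of 88
keeps at least 50 test cases in the smallest group.

Test subjects are labelled psychosis when evidence (the predicted
probability of the psychosis class) exceeds 0.5; evidence exactly at the
threshold is labelled CON — an explicit deterministic tie rule, relevant
because a zero model scores exactly 0.5. Per iteration and model the
package records sensitivity, specificity, balanced accuracy
$(\mathrm{sens}+\mathrm{spec})/2$, pooled raw accuracy, transfer rates on
the other two groups' test cases, and per-subject evidence over the entire
test sample.

### Interval inference and specificity

All rates are summarised by equal-tail empirical percentile intervals with
linear interpolation between order statistics (quantile type 7), at level
0.9917 by default — a Bonferroni-style tightening whose printed value is
used verbatim. A rate is *above chance* when the interval's lower bound
exceeds 0.5; the same rule is applied to own-group accuracy and to
out-group transfer rates, since the source analysis applies "above nominal
chance" language to both without further detail. A model is **specific**
iff its own group is above chance and no out-group transfer rate is.

Where "overall classifier accuracy" could mean balanced or pooled raw
accuracy, the package takes the balanced reading — consistent with the
stated accuracy metric — and emits the pooled variant alongside it.

### Reproducibility

Every randomized stage spawns substream seeds as the first $k$ draws of
`sample.int(2^31 - 1)` under its master seed: one seed per subject in the
generator, one per iteration in the split plan. Any subject or iteration
can therefore be regenerated independently, cohorts are reproducible under
subsetting, and identical configuration yields bit-identical reports.

## 2. The synthetic cohort generator

Subject $i$ of group $g$ has
$$y_i(v) = \mathrm{clip}\big(\mu - g_i\,\delta_g(v) + a_i + e_i(v),\,0,\,1\big),$$
with baseline $\mu = 0.5$, combined deficit map $\delta_g$ (the shared
pattern, if $g$ expresses it, plus $g$'s specific pattern), expression gain
$g_i \sim N(1,\,\mathrm{expression\_sd}^2)$ ($g_i \equiv 1$ for CON),
subject offset $a_i \sim N(0,\,0.01^2)$ and voxel noise
$e_i(v) \sim N(0,\,0.05^2)$. With these defaults the values stay well
inside $(0,1)$, so clipping bias is negligible.

The **expression gain is the load-bearing choice.** Without it, every
group member expresses the pattern identically; a linear classifier
averages independent voxel noise over hundreds of support voxels and
accuracy saturates near 1 — and saturated evidence is useless for the
association stage, being nearly collinear with the group dummies.
Between-subject heterogeneity in how strongly an individual expresses a
morphometric pattern is also the realistic regime: it places accuracies in
the moderate range reported for GMD classifiers and spreads evidence over
$(0,1)$.

Geometry is deterministic (no randomness in pattern placement): spheres
inside the region where the synthetic grey-matter template exceeds the
mask threshold. The templates are smooth bumps — grey matter peaking at
the centre, white matter rising toward the periphery — so that both mask
criteria exclude some voxels.

The `paper_like` preset encodes the qualitative structure the analysis is
meant to detect: B1 expresses a spatially extensive specific pattern
(reduction 0.010 over a large sphere — strong through its extent) plus a
pattern shared with B2 (0.012 over a medium sphere inside B1's); B2
expresses only the shared pattern; B3 a weak small pattern (0.008)
overlapping B1's sphere but clear of the shared one. Consequences, by construction: the B1
model's signal is dominated by B1-specific features, so B2 cases (shared
features only) transfer below chance and B1 is specific; the B2 model's
signal *is* the shared pattern, which B1 cases express equally, so B1
cases transfer above chance and B2 is not specific; B3's model is weakest,
and B1 cases (which express B3's overlapping region strongly) transfer
into it. No quantitative effect sizes are available for the real GMD
gradient, so these magnitudes are calibrated only to reproduce the
qualitative ordering of accuracies (B1 > B2 > B3) and the specificity
pattern at moderate accuracy levels — not any printed accuracy value. The
`null` preset zeroes all magnitudes; `shared_only` gives all three groups
the identical shared pattern.

Clinical outcomes are linear in the **pattern expression score** — each
subject's mean GMD shortfall over the B1 support, z-scored. The real
analysis's analogue is classifier output, but the generator needs an
explicit latent, and this one makes slope recovery checkable by
closed-form OLS. Outcomes are
$\mathrm{intercept} + \mathrm{slope}\cdot\mathrm{expression} +
\mathrm{group\ offset} + N(0, \sigma^2)$, with the slope identical across
groups (group-invariant by construction) and missingness injected
completely at random. The default outcome table emulates the six measures
of the association analysis: a WRAT-like measure with slope $-0.4$ and
noise sd 1, GAF/SFS-like functioning scores with group offsets only, and
three null biomarker components; missing rates loosely follow the reported
proportions. Diagnosis labels are assigned by random permutation at the
study's marginal counts, independent of biotype, so the two schemes cut
across each other.

**What the generator does not emulate:** anatomy, cortical topology,
registration/modulation artefacts, scanner and site effects, spatially
correlated noise, non-Gaussian tails, and any systematic biotype-diagnosis
association. Passing tests therefore establish that the pipeline's
inferential machinery behaves correctly under its stated assumptions — not
that the scientific findings would replicate on real images.

## 3. Weight maps

The exact aggregation recipe behind the original feature-importance maps
is described only in supplementary material that is not available; the
package implements a documented **reconstruction**: per voxel, the mean
weight across iterations and the sign consistency (fraction of iterations
whose weight sign matches the mean's sign), placed at mask coordinates and
zero elsewhere. Both are computable from stored models and suffice for the
qualitative claim the tests check — that high-consistency, high-magnitude
voxels are most numerous for the B1 model and fewest for B3. No
statistical thresholding is applied: a feature's contribution depends on
the other features in the model, and the maps are descriptive.

## 4. Evidence associations

Per iteration and outcome, the design is
$[1,\ \tilde{p},\ d_{B1},\ d_{B2},\ d_{B3},\ d_{B1}\tilde{p},\ d_{B2}\tilde{p},\ d_{B3}\tilde{p}]$
where $\tilde{p}$ is classifier evidence centered on its mean **over the
rows entering that regression** — i.e. after listwise deletion of missing
outcomes — and CON is the reference group with all-zero dummies. Centering
reduces collinearity between main effect and interactions; the tests
verify that shifting raw evidence by a constant leaves all non-intercept
coefficients unchanged. Missing outcomes are handled by listwise deletion
per outcome per iteration (no imputation, matching the source's reported
missingness handling). Outcomes are analysed on their raw scale by
default, with a `z_outcomes` flag, because the printed coefficient scales
are ambiguous across outcomes. Only the B1 model's evidence is wired by
default (it is the specific model), but any model's evidence is accepted
for synthetic experiments.

A term is significant when the 95% percentile interval of its coefficient
across iterations excludes zero. Note what this interval is: variability
across resampled splits of *one* cohort. Subjects recur across iterations'
test sets, so the interval ignores that dependence; it is reproduced as
the source procedure defines it, not as an independent-replicates
confidence interval. PCA reduction (`reduce_pca()`) operates on the
correlation matrix (inputs z-scored), excludes incomplete rows before
fitting, orders components by eigenvalue and fixes each component's sign
so its largest-|loading| measure loads positively.

## 5. Numerical details and problem sizes

* Logistic tolerance $10^{-6}$ on the gradient max-norm; OLS via QR
  (`lm.fit`) with an explicit rank check (rank deficiency, e.g. zero
  evidence variance within a group, is an error, not a silent drop).
* Percentile intervals require $\ge 2$ values and a level strictly inside
  $(0,1)$; all-equal inputs give a degenerate interval $(v,v)$.
* Degenerate inputs error early with informative messages: empty mask
  (naming both thresholds), all-constant feature matrix, groups too small
  for the training draw, empty out-group, single-class truth.
* The test suite and acceptance script run the full pipeline at a
  $20^3$ grid (≈1100 mask voxels) with 150–200 iterations and the study's
  group sizes — sizes chosen so the whole suite exercises every stage,
  including two full scheme runs, in a few minutes on one CPU. The
  pipeline itself has no scale-specific logic; grid, iteration count and
  group sizes are ordinary parameters.

## 6. Known limitations

* Transfer-rate "above chance" calls use the same percentile-interval rule
  as own-group accuracy; no alternative multiple-comparison scheme is
  offered.
* Repeated splits of a fixed finite cohort are slightly optimistic even
  under the null (the models can exploit chance structure of the specific
  cohort that generalises to its own held-out remainder); the acceptance
  script measures exactly this calibration.
* The synthetic presets target qualitative structure, not printed accuracy
  levels; absolute accuracies on synthetic cohorts are a property of the
  preset parameters.
* Upstream VBM (segmentation, DARTEL registration, modulation) is out of
  scope; the package consumes its outputs.
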