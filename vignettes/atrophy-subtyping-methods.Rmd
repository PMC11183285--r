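---
title: "Mixture-of-experts subtyping of cortical atrophy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-of-experts subtyping of cortical atrophy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moesubtype)
```

## The scientific problem

Mild cognitive impairment (MCI) is heterogeneous: some patients are
morphologically close to cognitively normal (CN) aging and rarely progress,
others carry focal temporal–frontal atrophy and decline quickly, and others
show diffuse cortical thinning. Plain clustering of MCI thickness features
struggles because the MCI–CN contrast is subtle. This package implements a
semi-supervised alternative: subtypes are first discovered where the signal
is strong — in the Alzheimer's disease (AD) group, anchored against CN —
and MCI subjects are then mapped onto those subtypes through the fitted
classifier geometry.

## The model

Subjects are represented by 68 Desikan–Killiany ROI mean cortical
thicknesses (mm), residualized against a CN-only covariate model. The
estimator couples $K$ linear max-margin experts with fuzzy C-means (FCM)
memberships over the $N$ AD subjects:

$$
\min_{\{w_k, b_k\},\, \{m_{ik}\}} \sum_{k=1}^{K} \Big\{
  \tfrac12 \lVert w_k \rVert_1
  + C \textstyle\sum_i s_i\, m_{ik} \big(1 - y_i (w_k^\top x_i + b_k)\big)^2
  + t \textstyle\sum_i m_{ik}^2 \lVert x_i - d_k \rVert^2 \Big\}
$$

subject to $\sum_k m_{ik} = 1$, $m_{ik} \in [0,1]$, with centroids
$d_k = \sum_i m_{ik}^\alpha x_i \big/ \sum_i m_{ik}^\alpha$. Labels are
$y = +1$ for AD and $y = -1$ for CN. Every CN subject enters **every**
expert's loss with fixed unit weight — the "anchor" — while memberships
and centroids range over AD subjects only; $s_i$ is the AD:CN class weight
$\rho$ for AD samples and 1 for CN. The squared margin loss
$(1 - y f)^2$ is used literally (a least-squares-SVM-style loss; a
squared-hinge variant sits behind `moe_config(loss = "squared_hinge")`).
An unpenalized intercept $b_k$ is fitted by default because a
through-origin boundary is unreasonable for thickness residuals;
`intercept = FALSE` gives the strict form.

### Optimization

The three blocks each admit an exact or monotone update, so alternating
them never increases the objective (asserted on every test run):

* **Experts.** At fixed memberships, each $(w_k, b_k)$ solves a weighted
  L1-penalized least-squares problem (for $y \in \{-1, +1\}$ the squared
  margin loss equals the squared residual). Solved by warm-started cyclic
  coordinate descent with soft-thresholding, in compiled code. Tests
  cross-check the solution against an independently mapped `glmnet` fit.
* **Centroids.** With $\alpha = 2$ (the package fixes this; it makes the
  printed centroid formula the exact minimizer) the centroid update is a
  closed-form weighted mean.
* **Memberships.** Each row solves
  $\min_m \sum_k [C \rho L_{ik} m_k + t D_{ik} m_k^2]$ on the probability
  simplex — a quadratic program with the closed-form KKT water-filling
  solution $m_{ik} = \max\{0, (\lambda_i - C\rho L_{ik}) / (2 t D_{ik})\}$.
  $D_{ik}$ is floored at $10^{-12}$. Tests compare against a brute-force
  support-set-enumeration oracle.

Initialization is standard FCM on the AD rows (`e1071::cmeans`, seeded);
`n_restarts = 5` restarts keep the best final objective. Convergence is
declared when the largest membership change drops below `tol = 1e-4`
(`max_iter = 100`) — standard FCM practice, all overridable. Dead experts
(vanishing total membership) are re-seeded at the worst-fit AD subject and
the fit errors after three failed rescues. Argmin/argmax ties resolve to
the lowest index; a decision value of exactly 0 classifies as $+1$.

### Model selection

`grid_search_select()` scans $C$ and $t$ over powers of two ($2^{-3}$ to
$2^{10}$ by default) and class weights $\rho = 1..5$, recording
cross-validated accuracy (Acc), the maximum pairwise inner product of
unit-normalized expert weights ($W_r$; small = distinct experts), and the
Bezdek partition coefficient (BPC $= \frac1N \sum_{i,k} m_{ik}^2 \in
[1/K, 1]$; large = crisp). How to combine the three indices is genuinely
open; the package applies a lexicographic rule — maximize Acc, break ties
by minimal $W_r$, then maximal BPC, then smallest $C$, then smallest $t$ —
and returns the full grid so users can re-select.

A note on scale: the clustering distances $D_{ik}$ are summed squared
millimetres over all ROIs, typically one to two orders of magnitude larger
than the unit-scale margin loss. The package default `t = 0.1` reflects
that imbalance for 68-ROI residuals; large `t` makes memberships converge
toward plain FCM memberships of the distance term (a tested limit) and
blurs expert specialization. Tune per dataset with the grid search.

## Covariate residualization

`fit_cn_glm()` fits each ROI's thickness on intercept + age + sex +
education + intracranial volume (ICV) by OLS **on CN subjects only**, and
`residualize()` subtracts that normal-aging prediction from every subject
(CN, MCI and AD alike) using the subject's own covariates. Sex is coded
F = 1. No shrinkage is applied; diagnosis labels never enter the fit, and
follow-up visits are residualized with visit-specific age. One printed
form of the residual formula indexes education by the CN set; that reading
is unimplementable across index sets, so each subject's own education is
used, consistent with the other covariates.

## Mapping MCI and naming subtypes

Each MCI subject is assigned to the expert with the smallest **unsigned
geometric distance** $|w_k^\top x + b_k| / \lVert w_k \rVert_2$
(`assign_min_distance()`; a signed mode exists for sensitivity analysis).
AD subjects, who carry memberships, are labeled by argmax membership
instead. Experts are named by severity (`rank_and_name_subtypes()`): the
mean ROI residual of an expert's argmax-membership AD subjects scores its
atrophy depth (more negative = deeper), and labels run MIN → MID → DIF for
$K = 3$ (otherwise S1..SK). A mean-residual score was preferred over
counting significant ROIs because it is monotone and threshold-free.
Converters are re-assigned at their conversion-visit features — this is
informative exactly because that scan sits between the MCI and AD atrophy
levels, where the margins of the experts disagree most.

## Longitudinal screening

The month-24 visit is the screening cut-off. The implemented rules
(`screen_baseline()`, `resolve_m24()`, `screen_periods()`):

1. keep baseline-MCI subjects with a baseline scan;
2. resolve M24: present → observed; absent with M06–M18 and M36 scans and
   an M36 state of MCI → imputed as still-MCI; absent with M36 state
   AD/CN → excluded as indeterminate (unless an AD/CN state was already
   observed at an earlier period, which dates the event to that visit);
3. sweep M06 → M24: observed AD is a conversion event, observed CN a
   reversion, both absorbing — the subject leaves all later at-risk sets
   and that period's rate denominator.

The backward retention expression (a subject missing a period's scan stays
at risk if a later visit covers them) is isolated in one internal function
so alternative readings can be swapped. A diagnosis recorded at a visit
without a scan does not trigger an event by default
(`require_scan = FALSE` honors it with a warning). Per-period conversion
rate = converters / at-risk; `at_risk_series()` reports the series, and a
period with nobody at risk reports `NA` rather than 0.

## The synthetic cohort generator

`generate_cohort()` emulates an ADNI-1-like cross-section — defaults 228
CN / 396 MCI / 192 AD (the published text's counts; the source tables are
internally inconsistent about two of them), 68 ROIs with healthy means
ramping 2.0–3.2 mm, noise SD 0.12 mm, age slope −0.005 mm/y, sex offset
+0.02 mm, education slope +0.002 mm/y and a zero ICV slope (thickness,
unlike volume, is weakly head-size-dependent; ICV is still residualized
downstream). Each patient draws a latent template; thickness is baseline +
covariate effects − scale × template weights + noise, with scale 1 for AD
and `mci_scale` (default 0.5) for MCI. `default_templates()` mimics the
minimal / temporal–frontal / diffuse patterns qualitatively;
`orthogonal_templates()` plants disjoint-block patterns for recovery
experiments. APOE alleles are two independent draws from per-group
frequencies (carrier = at least one ε4/ε2); cognitive scores are linear in
latent atrophy burden plus noise — plumbing for the trajectory reports,
not inputs to any estimator.

`generate_longitudinal()` walks MCI subjects through bl/m06/.../m36 with
per-visit missingness and per-template per-period conversion (and
reversion) probabilities; both transitions are absorbing and the true
event visit is recorded for testing. Atrophy evolves continuously through
the diagnostic boundary: the conversion-visit scan carries atrophy halfway
between the MCI and AD levels, later visits the full AD pattern. An
instantaneous jump to full AD depth would be unphysiological — and at full
AD depth the unsigned min-distance rule is geometrically ambiguous (the
own-expert margin $+1$ and the other experts' margins $-1$ are
equidistant), so the mid-trajectory convention is also what makes
conversion-time attribution meaningful.

Randomness is split into per-stage streams derived from one master seed
(`derive_seed()`), so enlarging the cross-section does not perturb visit
randomness. What the generator does **not** emulate: spatial correlation
between neighboring ROIs, scanner/site effects, non-Gaussian measurement
error, informative missingness, and item-level cognitive structure.
Passing recovery tests on this generator therefore demonstrates
correctness of the estimator under its own assumptions, not performance on
real ADNI data.

## Problem sizes and numerical choices in the shipped checks

The test suite and acceptance script exercise: the membership QP against a
support-set-enumeration oracle on 100+ random instances ($K \le 4$,
$N \le 30$, tolerance $10^{-6}$); objective monotonicity on 20 seeded fits
($K = 2, 3$; 100 AD + 100 CN; 20 ROIs); three-subtype recovery on planted
orthogonal 0.4 mm patterns (150 AD + 150 CN + 300 MCI, 68 ROIs, noise
0.1 mm) requiring adjusted Rand index ≥ 0.9 for AD memberships and ≥ 0.7
for MCI min-distance assignment; a $K = 1$ reduction to a single weighted
L1 classifier (objective gap $< 10^{-6}$); chance-level cross-validated
accuracy on label-permuted data; an exactly hand-traced six-subject
screening fixture; and the published-count percentage arithmetic
(half-up rounding to one decimal, which reproduces the printed
count/percent pairs; one published ε2 entry, 3/64 as 4.6%, appears to be a
typo — the arithmetic gives 4.7%). The end-to-end synthetic run uses 500
subjects and a reduced 4×4 $(C, t)$ grid with 10-fold cross-validation.

## Known limitations

* Linear experts only; no kernels, no GAN-style augmentation.
* The ROI atrophy flags use uncorrected p < 0.05 Welch tests by design —
  a descriptive map, not a multiplicity-controlled inference.
* CSF biomarkers are not simulated; abnormality cut-points are
  cohort-calibrated constants outside this package's scope.
* No site harmonization (ComBat etc.) and no nonlinear age effects in the
  covariate model.
* Headline real-data values (cross-validated accuracy near 85%, $W_r$
  near 0.3, BPC near 0.7 at $K = 3$) depend on restricted ADNI data and
  serve only as plausibility context for synthetic runs here.
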