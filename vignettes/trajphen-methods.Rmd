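---
title: "Trajectory subphenotyping of ICU cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory subphenotyping of ICU cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

trajphen identifies dynamic clinical subphenotypes of critically ill
patients — developed for acute pancreatitis ICU cohorts — from the
trajectories of five routinely measured vital signs (systolic and
diastolic blood pressure, heart rate, respiratory rate, temperature)
over the first 12 hours after ICU admission, and then asks whether the
subphenotypes differ in prognosis and in their response to early fluid
resuscitation. This vignette documents the models, the tunable
parameters, the synthetic-cohort generator used for verification, and
the numerical choices that an analyst replicating or extending the
pipeline should know about.

## Trajectory preparation

Raw observations `(patient, time, channel, value)` are aggregated into
hourly bins `[h, h+1)` with `h = floor(time)` and `h = 0` at ICU
admission; multiple measurements of a channel within an hour are
averaged. An hour enters the analysis only if **all five** channels are
present — partial hours are removed entirely, so no imputation is ever
applied to the trajectory data. Cohort eligibility keeps the first ICU
stay per patient, age ≥ 18 years, ICU length of stay ≥ 24 h, and at
least two complete observed hours within the 12-hour window, applied in
that order with per-reason exclusion counts.

Each channel is then z-scored by pooling all patients and observed hours
(not per hour). A validation or external cohort is standardised with the
*development* cohort's means and SDs by default; this keeps the
mean-squared-error assignment (below) on a single scale. Per-hour
standardisation and joint re-standardisation were considered and
rejected: the former distorts within-patient dynamics, the latter makes
external assignment depend on the external cohort's composition.
Temperature is accepted in °C only (a Fahrenheit conversion helper is
provided but never applied implicitly).

## The group-based multi-trajectory model

For patient $i$, hour $h$, channel $c$, the model is a $K$-class finite
mixture in which class $k$ contributes, over the patient's observed
cells,

$$\log f_k(y_i) = \sum_{(h,c)\ \mathrm{observed}}
  \log \mathcal{N}\!\left(y_{ihc};\ \textstyle\sum_{j=0}^{p}
  \beta_{kcj}\, t_h^{\,j},\ \sigma^2_{kc}\right), \qquad t_h = h/11,$$

with mixing proportions $\pi_k$. Scaling the time covariate to
$[0, 1]$ keeps the polynomial design well conditioned. Parameters are
estimated by EM: the E-step computes posteriors
$\tau_{ik} \propto \pi_k f_k(y_i)$ with log-sum-exp stabilisation; the
M-step sets $\pi_k$ to mean posterior weight and solves
$\tau$-weighted least squares per class and channel, with residual
variances floored at $10^{-6}$ to prevent degenerate spikes.

Choices that matter:

* **Polynomial order** — default 3 (configurable 0–5), identical across
  channels and classes. Cubic curves accommodate the non-monotone
  early-ICU shapes (overshoot-then-settle) without the oscillation risk
  of higher orders on a 12-point grid.
* **Initialisation** — EM on mixtures is multimodal. The first restart
  seeds hard posteriors from k-means on per-patient observed channel
  means; the remaining `n_restarts − 1` (default 9) use random
  posteriors; the best final log-likelihood wins.
* **Convergence** — relative log-likelihood change below `1e-6`, cap
  500 iterations. The trace is stored and is non-decreasing (a property
  the test suite asserts).
* **Degeneracy** — a class whose effective weight drops below $p + 2$
  aborts the restart; a class-specific singular design (too few
  distinct observed hours) reduces the polynomial order for that fit
  with a warning.

Missing hours are simply absent from the likelihood sum, which for
conditionally independent Gaussian cells equals fitting on the observed
subset.

## Choosing the number of subphenotypes

Stability under resampling drives the choice of $K$ (candidates 2–6).
For each $K$ and each of `n_resamples` (default 100) replicates, 80% of
patients are subsampled without replacement and the mixture is refitted
(3 restarts); the consensus matrix entry $M_{ij}$ is the fraction of
co-samplings in which $i$ and $j$ were modally co-assigned. The
empirical CDF of off-diagonal consensus values is summarised by its
area $A(K)$ (100-bin Riemann sum) and the relative delta area
$\Delta(K) = (A(K) − A(K−1))/A(K−1)$, with $\Delta(2) = A(2)$.

A candidate $K$ is *admissible* when (a) every cluster of the consensus
matrix (average-linkage hierarchical clustering of $1 − M$) has mean
within-cluster consensus above 0.8, and (b) the smallest mixture class
holds at least 10% of the cohort. The published size constraint is
worded as a *maximum* of 10%, which would defeat its stated purpose of
excluding clinically irrelevant slivers; the package treats it as a
minimum share by default and offers `class_share_mode = "max"` for the
literal reading. Among admissible $K$ the delta-area elbow picks the
largest $K$ with $\Delta(K) \ge 0.1$; when none clears the threshold
the admissible $K$ with the largest $\Delta$ is chosen. Information
criteria (AIC, BIC, ICL = BIC + 2·entropy, normalised entropy
$1 − E/(N\ln K)$) are tabulated as sensitivity evidence, not as hard
criteria.

## External and early assignment

A fitted model assigns new patients by mean squared error against the
class mean curves, averaged over the patient's observed cells; the
class with the lowest MSE wins (ties to the lower index, logged). The
same machinery quantifies early prediction: truncate the panel to the
first $H$ hours (6–12), reassign, and report agreement with the
full-window assignment. The 12-hour reference is itself the MSE
assignment — not the posterior modal label — so that the comparison
isolates the effect of the shortened window; on synthetic data the two
labelers agree almost everywhere anyway. Agreement is plain percent
agreement with no chance correction.

## Outcome comparisons

Descriptives are median (Q1, Q3) for continuous variables and n (%) for
categorical; groups are compared with Kruskal–Wallis and Pearson
chi-square (no continuity correction) tests, two-sided α = 0.05, no
multiplicity correction. Thirty-day mortality contrasts use Cox
proportional-hazards models (Efron ties — times at day resolution tie
heavily) with the hypertensive class as reference, crude and adjusted
for age, gender and race; a constant covariate (e.g. race in a
single-ethnicity cohort) is dropped automatically with a note.
"Adjusted Kaplan–Meier" curves are direct-adjusted (corrected group
prognosis) survival: the Cox model's predicted curves are averaged over
the pooled covariate distribution with phenotype set to each class in
turn. Comorbidities with cohort prevalence strictly above 5% enter one
multivariate Cox model per phenotype stratum.

## Fluid-response analysis

Within each phenotype, a random-forest classifier predicts ICU death
from baseline characteristics plus day-1 and day-2 fluid intake
(mL/day over the first 48 h). Hyperparameters (trees ∈ {200, 500},
depth ∈ {∞, 6, 10}, minimum node size ∈ {1, 5, 20}) are selected by
stratified 5-fold cross-validation on AUROC; the winner is refitted on
the full stratum. Partial dependence is *true* partial dependence:
$PD(x_1, x_2)$ averages the model's predicted death probability over
cohort members with the two fluid features forced to the grid point and
all other features at their jointly observed values. The grid is
0–6000 mL in 100-mL cells on both axes, matching the resolution at
which lowest-risk ranges are reported.

Cells are ranked by PD and cut into deciles ("risk gradients"); the
lowest-risk range is the bounding box of the 4-connected component of
bottom-decile cells containing the global PD minimum. Rank-based
cutting (rather than value quantiles) keeps heavily tied, plateau-rich
forest surfaces well defined. A constant surface degenerates to a
single stratum and reports "no range".

Partial dependence over a 60 × 60 grid is prediction-heavy; the package
therefore averages over a background subsample of the stratum
(`background` argument). The reported analyses use 150 background
patients (60–300 in replication loops), which changes PD values by less
than the cell-to-cell resolution at the cohort sizes involved.

The lactated-Ringer's analysis is a per-phenotype Cox model of 30-day
mortality on receipt within 48 h, adjusted for age, gender and race.

## Missing data in the feature table

Variables with missing rates strictly above 20% are dropped (exactly
20% is retained). Remaining gaps are filled by a four-method ensemble:
mean substitution, and single-imputation chained equations (5
variable-by-variable sweeps, mean/mode initialisation) with a
regression tree, a random forest, and a lasso-regularised linear model
as the per-variable learner. The four completed datasets are combined
cell-wise — arithmetic mean for continuous cells, majority vote for
categorical cells with ties broken by the method order listed above.
Observed cells are never modified, and the stochastic methods are
deterministic given the seed. Because the analysis collapses to a
single completed dataset, no between-imputation variance is propagated;
that is a deliberate scope decision, not an oversight.

## The synthetic cohort generator

The generator exists so every stage has a ground truth. Its defaults
*are* the study conditions:

* **Class structure** — four latent classes with mixing proportions
  (14.1, 17.6, 27.0, 41.2)% (normalised to sum to one — the printed
  shares total 99.9%): A hyperinflammatory (high TEMP/HR/RR),
  B hypertensive (high SBP/DBP), C hypotensive (low SBP/DBP),
  D hypoinflammatory (low TEMP/HR/RR). Trajectories are order-2
  polynomials on the z-scale, hand-set to these qualitative patterns
  (±1–1.5 SD on the defining channels) because no trajectory
  coefficients are published; they are stipulated templates, not
  estimates. Channel noise SD defaults to 0.5 with independent hourly
  errors (an AR(1) option exists for robustness checks), matching the
  conditional-independence assumption of the mixture model.
* **Missingness** — individual observations drop completely at random
  (default rate 0.1), exercising the complete-hour filter.
* **Survival** — exponential 30-day event times with administrative
  censoring; the hypertensive reference hazard is calibrated to ≈5%
  30-day mortality and classes A/C/D to hazard ratios 3.38/1.87/0.77.
  Proportional hazards hold by construction, so Cox recovery is
  well-posed. Covariates are independent of class by default (crude =
  adjusted in truth); a confounding switch shifts age by class for
  crude-vs-adjusted contrasts.
* **Fluids and ICU death** — day-1/day-2 volumes are truncated normal
  around the class optimum (A 4200/3500, B 4050/900, C 4500/2800,
  D 3300/2000 mL; SD 700; sampling mean offset +300 mL, reflecting a
  tendency to run above the optimum). ICU-death log-odds are the
  class baseline (12.5/5.0/6.7/2.0% at the optimum) plus a curvature
  term. The curvature is direction-specific:
  `c(day1_below = 60, day1_above = 1.2, day2 = 0.15)` per squared
  litre — a steep under-resuscitation wall below the day-1 optimum, a
  gentle overload slope above it, mild day-2 dependence. A symmetric
  isotropic bowl (scalar curvature) is supported but makes the
  bottom-decile region of any smooth PD surface a ~360-cell disk on
  the 60 × 60 grid, i.e. a bounding box over 2 L wide — geometry, not
  estimation error — and therefore cannot reproduce the narrow
  published lowest-risk ranges; the directional default is calibrated
  (on the generator's own closed-form risk surface, before any
  model-based testing) so the exact bottom-decile box is
  [4100, 5100] mL on day 1. One consequence of the steep wall is that
  the *marginal* ICU-death rate of a class-A fluid cohort (~45%)
  exceeds the at-optimum baseline; the 30-day survival records, which
  carry the printed hazard calibration, are generated separately.
  Lactated Ringer's is received by 50% and multiplies both the class-C
  hazard and the class-C death odds by 0.48.

What the generator deliberately does **not** emulate: joint correlation
between labs and comorbidities (marginals only), hospital length-of-stay
dynamics, measurement artifacts/outliers, informative (non-MCAR)
missingness, and weight-based (mL/kg) fluid dosing. Passing tests
therefore demonstrate that the pipeline recovers known structure under
its own model assumptions — not that real EHR data satisfy them.

## Problem sizes and reproducibility

The demonstration study runs 800 patients, K ∈ 2–5 and 30 consensus
resamples, completing end-to-end in a few minutes on one core; the
recovery experiments use n = 2,612 (mixing proportions), 20,000
(phenotype hazard ratios), 10,000 (Ringer's contrast) and 3,000 with a
150-patient PD background (fluid ranges). Every stochastic stage takes
a seed; the pipeline expands one global seed into per-stage seeds, so
any stage can be rerun in isolation and reproduce its outputs
byte-for-byte (checksummed in the run manifest).

## Known limitations

Residual variances are class- and channel-specific but homoscedastic
over hours; mixing proportions do not depend on covariates; the
consensus-clustering refit makes K-selection the computational
bottleneck; MSE assignment weights all channels equally on the z-scale;
and Monte-Carlo spread at the stated cohort sizes leaves a few percent
of seeds outside the recovery tolerances for the hazard-ratio
experiments — a property of the experiment sizes, not of the
estimators, which are unbiased.
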