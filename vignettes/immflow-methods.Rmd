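---
title: "Methods: immune-age pseudotime scoring and its cohort machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-age pseudotime scoring and its cohort machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immflow)
```

## The model

`immflow` treats a cohort of immune phenotypes as points on a
one-dimensional manifold — an ageing trajectory — embedded in the
8-dimensional space of subset frequencies known to shift with
immunosenescence: total T cells, naive CD4, effector memory CD4/CD8, EMRA
CD8, CD28− CD8, CD57+ CD8 and regulatory T cells. The score of a sample is
its pseudotime: how far along that trajectory it sits, measured from a
biologically anchored origin and scaled to [0, 1].

The estimator makes three assumptions worth stating plainly:

* **A dominant gradient exists.** The diffusion map recovers trajectory
  geometry only if the leading variation in standardized feature space is
  the ageing/differentiation axis. The eight features were chosen because
  they all load on that axis; a cohort whose main variance is, say, a batch
  effect will be scored along the batch axis instead.
* **Samples are exchangeable.** Repeated measures of one person at
  different days are embedded as independent samples. This matches how the
  score is used (each timepoint gets its own score) but means the embedding
  ignores within-person correlation.
* **CD28 loss marks the old end.** The trajectory origin is the sample
  with the lowest CD28− CD8 frequency (equivalently the highest CD28+
  fraction). CD28 loss on CD8 T cells is a canonical senescence marker, so
  distance from this root increases with phenotypic age; the orientation of
  the score depends entirely on this anchor, not on any eigenvector sign
  convention.

## Pipeline and parameters

`immage()` runs: missing-feature exclusion → trimmed standardization →
diffusion map → root selection → pseudotime → min-max scaling. The
tunables, all in `immage_config()`:

| parameter | default | meaning and rationale |
|---|---|---|
| `trim_fraction` | 0.10 | proportion removed per tail before computing the standardizing mean/SD; with `k = floor(0.1 n)` extremes removed the location/scale estimates resist the heavy tails that trauma samples produce. 0 gives the ordinary z-score. |
| `kernel_bandwidth` | median pairwise distance | σ of the Gaussian kernel. The median of non-zero pairwise distances is scale-free: it adapts to cohort size and feature dispersion without a tuning run. A fixed number may be supplied. |
| `n_components` | 3 | non-trivial diffusion components retained. The feature space is 8-D and cohorts are small (tens to low hundreds); one component carries the trajectory, two more absorb curvature. |
| `diffusion_time` | 1 | components are weighted by eigenvalue^t, so distance in the embedding equals the diffusion distance at time t. Larger t smooths the trajectory but blurs its ends. |
| `root_rule` | `min_cd28neg_cd8` | trajectory origin; an explicit sample id may be forced instead. |

Standardization is pooled over the whole retained analysis set — controls
and all trauma timepoints together. Stratifying by group would erase
exactly the between-group displacement the score is meant to measure.

The density normalization uses the anisotropic α = 1 construction
(kernel divided by the outer product of its row sums before row
normalization). This removes sampling-density bias: trauma days are
unevenly sampled, and without it densely sampled regions would contract
the trajectory.

Pseudotime is the diffusion distance from the root, not a graph shortest
path or a fitted principal curve: it is the simplest quantity consistent
with "position along the trajectory", it needs no extra tuning, and it is
exactly checkable against an analytic oracle (for samples collinear in
standardized space, score ranks must equal position ranks — a property the
test suite asserts).

## Numerical choices and degenerate inputs

* **Determinism.** Eigenvector signs are fixed (largest-magnitude entry
  positive), and diffusion distances are invariant to sign flips anyway;
  the whole pipeline is bit-reproducible and invariant to sample order to
  1e-9.
* **Ties.** Root ties (equal CD28− CD8) break lexicographically by sample
  id. If the maximum raw score is duplicated, all duplicates score 1.
* **Degenerate inputs.** A feature constant after trimming, fewer than 8
  complete samples, an all-identical cohort (undefined bandwidth), or a
  flat pseudotime vector each raise a typed error naming the offender;
  nothing is silently imputed or dropped beyond the declared
  missing-feature exclusion.
* **Panel validation tolerance.** The CD45RA/CCR7 quartet must sum to
  100 ± 0.5 percentage points and the CD28−CD57+ intersection may exceed
  min(CD28−, CD57+) by at most 0.5 — real gated exports carry rounding, so
  exact equality would reject valid data.

## The statistics layer

The comparison machinery mirrors common practice in cohort
immunophenotyping. The normality screen is a Lilliefors-corrected
Kolmogorov–Smirnov test (reference normal estimated from the sample —
using the uncorrected KS null with estimated parameters would be
anti-conservative). Two-group comparisons default to the Student t test
with a Welch variant available; the package does not guess a
non-parametric fallback for non-normal data — routing is the analyst's
explicit choice. The summary-statistic form (mean, SD, n per group) exists
so printed cohort tables can be re-tested; it agrees with the raw-vector
form to 1e-9. ANOVA post hoc contrasts use the pooled residual variance
with Bonferroni adjustment `min(1, m·p)` over the m requested contrasts.
All tests are two-sided at α = 0.05.

The sepsis feature ranking is a `randomForest` classifier (ntree = 500,
mtry = ⌊√p⌋) ranked by permutation importance on out-of-bag samples (mean
decrease in accuracy). Rows with missing features are listwise-deleted
and counted. Class imbalance (septic patients outnumber non-septic
roughly 2:1) can be countered with a stratified bootstrap flag, off by
default. Which timepoint feeds the forest is an explicit argument of the
pipeline configuration (default day 3, the earliest sample) rather than a
hidden assumption. Correlated features split importance between them —
the suite pins this behaviour with a duplicated-feature test — so ranks
of collinear immune measures should be read jointly.

## What the synthetic cohort does and does not emulate

`generate_cohort()` exists so every stage is testable end to end with
planted ground truth. It emulates the *statistical structure* the
analyses assume: 55 controls and 57 trauma subjects sampled at days 3,
14, 28 and 60; ages uniform on 20–85; a latent immune age that rises
linearly with age in controls and is offset upward after trauma, peaking
at day 14 (matching the observed nadir of naive T cells); compositional
subset draws from Dirichlet distributions whose means shift with the
latent variable, so simplex constraints hold exactly; log-normal
(right-skewed) cytokines elevated in trauma in proportion to the latent
offset and further elevated under sepsis; lymphopenia with a pre-day-60
nadir; completely-at-random dropout of later timepoints (default 30%,
reproducing shrinking per-day n); and sepsis labels drawn from a logistic
model on the latent immune age, intercept-calibrated to a 65% incidence.
The 65% default follows the recruitment-count arithmetic (37 of 57);
the source literature also quotes 67.85% for the same cohort, an
inconsistency we document rather than resolve.

It deliberately does **not** emulate: raw cytometry events, spectra,
gating noise or batch effects; within-person longitudinal autocorrelation
beyond the fixed timepoint offsets; non-uniform age structure; or any
mechanistic link between cytokines and cell subsets. Passing
parameter-recovery tests on this generator therefore shows the estimator
recovers a planted monotone gradient under realistic noise and
missingness — it does not certify performance on real cohorts with batch
structure or confounded trajectories.

Determinism is hierarchical: a single global seed spawns one stream per
subject, so an individual's draws are stable when cohort sizes change.

## Problem sizes in the test suite

The suite works at the scale the method targets: default cohorts of ~220
samples for scoring and recovery checks; 100-seed Monte-Carlo runs at 25
subjects per arm for null calibration of the generator; 1000–2000
replicates for type-I-error calibration of the t test and ANOVA; 20-seed
random-forest experiments at n = 200 with 10 features. These sizes give
the calibration checks enough resolution (± 1–2 percentage points on a 5%
error rate) while keeping a full run under a minute.

## Known limitations

* The score is cohort-relative: min-max scaling means a sample's value
  depends on who else was scored, so scores are comparable within one
  analysis run, not across cohorts.
* No out-of-sample projection: adding a sample changes the embedding, so
  there is deliberately no `predict()` method.
* The orientation anchor is a single sample (the root); in very small
  cohorts an outlier with aberrantly low CD28− CD8 could anchor the
  trajectory poorly. The explicit `root_rule` override exists for exactly
  that case.
* Repeated measures are treated as independent; with many timepoints per
  person the embedding over-weights well-sampled individuals.
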