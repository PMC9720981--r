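# immflow

Immune-ageing pseudotime scoring of flow-cytometry cohorts.

Severe traumatic injury remodels the adaptive immune system in ways that
resemble ageing: naive T cells fall, senescent (CD28−CD57+) and memory T
cells accumulate, and regulatory T cells expand. A single gated subset is a
poor summary of this state, so the field uses a composite **IMM-AGE score**:
a per-sample *pseudotime* position along a data-driven trajectory through
immune-phenotype space, scaled to [0, 1], with higher values indicating a
phenotypically older immune compartment. `immflow` implements the
flow-cytometry adaptation of this score and the cohort analyses built on
it, for immunologists and trauma researchers working with gated subset
frequency tables.

## The score

Given per-sample frequencies of eight subsets — total T cells, naive CD4,
effector memory CD4 and CD8, EMRA CD8, CD28− CD8, CD57+ CD8 and regulatory
T cells — the pipeline is:

1. **Trimmed standardization.** Each feature *x* is standardized as
   (x − m₀.₁) / s₀.₁, where m₀.₁ and s₀.₁ are the mean and SD of the 10%
   two-tailed trimmed sample (lowest and highest ⌊0.1·n⌋ values removed).
2. **Diffusion map.** With pairwise Euclidean distances *d(i,j)* in
   standardized space, a Gaussian kernel w(i,j) = exp(−d²/2σ²) (σ = median
   non-zero pairwise distance) is density-normalized (anisotropic, α = 1),
   row-normalized to a Markov matrix, and eigendecomposed; the top
   non-trivial eigenvectors ψ₂…ψ₄, each weighted by its eigenvalue λᵏ,
   form the embedding.
3. **CD28-anchored pseudotime.** The root is the sample with the lowest
   CD28− CD8 frequency (the highest CD28+ fraction — the senescence-low end
   of the trajectory). A sample's raw score is its diffusion distance from
   the root, i.e. its Euclidean distance in the eigenvalue-weighted
   embedding.
4. **Scaling.** Scores are min-max scaled so the root scores exactly 0 and
   the far end exactly 1. Samples missing any required feature are excluded
   and reported, never imputed.

Around the score, the package provides the study's comparison machinery
(Lilliefors normality screen, Student/Welch t tests — from raw vectors *or*
printed mean ± SD summaries — one-way ANOVA with Bonferroni post hoc
contrasts, univariate OLS), random-forest ranking of sepsis-associated
features by out-of-bag mean decrease in accuracy (ntree = 500,
mtry = ⌊√p⌋), a validated data model for gated panels with absolute-count
derivation, and a synthetic cohort generator that emulates a longitudinal
trauma/healthy-control design with planted ground truth.

## Worked example

```r
library(immflow)

cohort <- generate_cohort(sim_config(seed = 42))
cohort_summary(cohort$subjects)
#> Cohort: 223 samples; 55 healthy controls, 57 trauma subjects (168 trauma samples)
#>   trauma samples per day: d3=57, d14=43, d28=36, d60=32
#>   sepsis: 42/57 trauma subjects (73.7%)
#>   age (years): HC 50.3 +/- 19.9; trauma 51.7 +/- 17.7

fit <- immage(cohort$panels)
fit
#> Immune-age pseudotime fit
#>   samples scored: 223 (excluded for missing features: 0)
#>   root: HC036 (lowest CD28- CD8 frequency)
#>   diffusion components: 3, kernel bandwidth: 5.082
#>   eigenvalues: 0.3948, 0.1523, 0.0749
#>   score range: [0.000, 1.000] (scaled)

scores <- coef(fit)
grp <- with(cohort$subjects, ifelse(group == "HC", "HC", paste0("day", timepoint_day)))
round(tapply(scores[cohort$subjects$subject_id], grp, mean), 3)
#> day14 day28  day3 day60    HC
#> 0.738 0.649 0.697 0.639 0.460
```

Trauma samples score higher than controls at every timepoint, peaking at
day 14 — the trajectory position reflects the planted post-injury shift
toward an aged phenotype. In controls the score rises with chronological
age:

```r
hc <- cohort$subjects$group == "HC"
univariate_regression(cohort$subjects$age_years[hc],
                      scores[cohort$subjects$subject_id[hc]])
#> OLS (n = 55): slope = 0.01049, intercept = -0.06779, R^2 = 0.758, F = 165.7, p = 6.08e-18
```

`run_pipeline(pipeline_config(out_dir = "out"))` chains the whole sequence
— simulate, validate, score, compare, regress, random forest — writing CSV
tables and a JSON manifest; reruns with the same configuration are
byte-identical.

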