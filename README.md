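# trajphen

Dynamic clinical subphenotyping of ICU patients from early vital-sign
trajectories, with downstream prognosis and treatment-response
analysis. The package was built for acute-pancreatitis ICU cohorts,
where four subphenotypes — hyperinflammatory (A), hypertensive (B),
hypotensive (C) and hypoinflammatory (D) — emerge from the first
12 hours of systolic/diastolic blood pressure, heart rate, respiratory
rate and temperature, and differ sharply in 30-day mortality and in
their response to early fluid resuscitation.

## What it implements

**Group-based multi-trajectory model (GBMTM).** A K-class finite
mixture over patients in which class *k* gives channel *c* a polynomial
mean curve: for observed cells,

    y_ihc | class k  ~  N( Σ_j β_kcj (h/11)^j ,  σ²_kc )

fitted by EM (log-sum-exp E-step, weighted-least-squares M-step,
multiple restarts, monotone log-likelihood). Incomplete hours are
excluded rather than imputed: an hour counts only when all five
channels are present.

**Model selection.** Longitudinal consensus clustering for K = 2..6:
subsample 80% of patients, refit, record modal co-assignment; summarise
stability by the consensus-CDF area A(K) and delta area
Δ(K) = (A(K) − A(K−1))/A(K−1). K must keep every consensus cluster
above 0.8 mean consensus and every class at ≥ 10% of the cohort;
AIC/BIC/ICL/entropy are reported as sensitivity evidence.

**Assignment and early prediction.** External or truncated-window
patients are assigned to the class whose mean curves minimise the mean
squared error over their observed cells; agreement between 6–12 h
windows and the full 12-h assignment quantifies how early the
subphenotype is identifiable.

**Prognosis.** Median/IQR and n (%) descriptives, Kruskal–Wallis and
chi-square group tests, Pearson correlations with phenotype indicators,
crude/adjusted Cox hazard ratios against the hypertensive reference,
direct-adjusted Kaplan–Meier curves, and per-phenotype comorbidity Cox
models (prevalence > 5%).

**Fluid response.** Per-phenotype random-forest ICU-death classifiers
(5-fold CV on AUROC), two-predictor partial-dependence surfaces over
the day-1 × day-2 fluid grid (0–6000 mL, 100-mL cells), decile risk
strata, the lowest-risk fluid range as the connected bottom-stratum
region around the PD minimum, and an adjusted Cox contrast for lactated
Ringer's receipt.

**Synthetic cohorts.** A seeded generator calibrated to the published
estimates (class shares 14.1/17.6/27.0/41.2%, hazard ratios
3.38/1.87/0.77 vs class B, Ringer's hazard ratio 0.48 in class C,
fluid-risk optima per class) so that the full pipeline is verifiable
without access to clinical databases. See the methods vignette
(`vignettes/trajphen-methods.Rmd`) for every modelling and calibration
choice.

## Worked example

```r
library(trajphen)
library(dplyr)

cfg    <- generator_config(n_patients = 800, seed = 42)
cohort <- generate_cohort(cfg)
prep   <- prepare_trajectories(cohort$raw_vitals, cohort$baseline)
prep$panel
#> <trajectory_panel> 800 patients, 5690 observed hours (of 9600), z-score scale

fit <- fit_gbmtm(prep$panel, K = 4, n_restarts = 5, seed = 42)
fit
#> <gbmtm_fit> K = 4, order = 3, n = 800
#>   loglik = -23121.11 (converged, 3 iter)
#>   mixing: 0.426, 0.262, 0.167, 0.144
```

The four classes recover the generator's mixing structure (41.2, 27.0,
17.6, 14.1% up to label order). Mapping fitted classes to the named
phenotypes and contrasting 30-day mortality against the hypertensive
class B:

```r
phenotype <- match_template_classes(fit, cfg, prep$stats)[
  assign_modal(fit$posterior)]
labels <- tibble(patient_id = prep$panel$patient_id, phenotype = phenotype)
surv <- cohort$survival |> select(-phenotype) |>
  inner_join(labels, by = "patient_id")
fit_cox(surv, covariates = c("age", "gender"), reference = "B")
#> # A tibble: 5 × 7
#>   term          HR conf_low conf_high p_value model    reference
#> 1 phenotypeA 2.08     0.871      4.95  0.0992 adjusted B
#> 2 phenotypeC 1.21     0.514      2.86  0.659  adjusted B
#> 3 phenotypeD 0.577    0.236      1.41  0.228  adjusted B
```

At n = 800 the point estimates order as generated (A worst, D best);
the recovery experiments in `scripts/acceptance.R` run the same
contrasts at n = 20,000 where the intervals tighten around the
generating hazard ratios. Early identifiability:

```r
agreement_by_hours(fit, prep$panel, c(6, 9, 12))
#> # A tibble: 3 × 4
#>       H agreement n_compared n_excluded
#> 1     6         1        768         32
#> 2     9         1        795          5
#> 3    12         1        800         0
```

The whole study — simulate → prepare → fit → select K → assign →
outcomes → treatment — runs as one call with per-stage seeds and a
checksummed manifest:

```r
run_pipeline(default_pipeline_config(n_patients = 800, seed = 1),
             out_dir = "results/demo")
```

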