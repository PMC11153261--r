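# t2dsubgroups

Data-driven subgrouping of type 2 diabetes in longitudinal registry
cohorts, and everything needed to ask whether the subgroups are worth
having: do they stay stable over follow-up, do they separate risk-factor
trajectories, complication risks and treatment patterns, and do they
predict progression better or worse than the raw clinical indicators they
were built from?

## Who this is for

Biostatisticians and epidemiologists working with routine-care diabetes
registries (long-format visit, event and medication tables on a
diabetes-duration time axis), and methodologists studying the behaviour of
discrete phenotype clusters over time. The source registries for this kind
of analysis are typically access-restricted, so the package includes a
seeded synthetic cohort generator with the same statistical skeleton —
every stage of the pipeline runs and is tested without any external data.

## The method in brief

Individuals with diagnosis age ≥ 35, GAD negativity and complete baseline
indicators within 2 years of diagnosis are clustered on five z-scored
indicators — age, BMI, HbA1c (mmol/mol), C-peptide (nmol/l) and
HDL-cholesterol (mmol/l) — by sex-stratified k-means (k = 5), pooled
across sexes by optimal centroid matching. Pooled centres are named
SIDD / SIRD / MOD / MD / MDH against reference mean vectors by exact
minimum-distance assignment over all 120 permutations. Downstream:

* **Consistency over follow-up** — within 2-year windows `[0,2) … [6,8)`,
  membership is re-assessed by de novo re-clustering and by nearest-centre
  reallocation against the frozen baseline model; agreement is scored by
  accuracy (with exact binomial CI), Cohen's κ, and per-class sensitivity,
  specificity and specific agreement `2·n_cc/(row_c + col_c)`; transition
  trajectories are ranked and severe/mild movements (severe = SIDD, SIRD)
  extracted.
* **Trajectories** — annual subgroup means ± SD and random-intercept
  linear mixed models (ML, not REML) for nine clinical parameters.
* **Complications** — 1 − Kaplan–Meier cumulative incidence, global and
  pairwise logrank with Benjamini–Hochberg correction within outcome, and
  Cox models on the duration timescale with delayed entry at the baseline
  observation, Efron ties, MDH reference and Schoenfeld PH checks.
* **Treatment** — deterministic ATC-code mapping to six treatment steps
  (NoTreatment, OnlyCVD, Step1 metformin/glinides, Step2 +sulfonylurea,
  Step3 +insulin, OtherOAD), yearly step assignment from the first
  observation per year, area-graph tables, and multinomial logistic models
  (NoTreatment reference category, MD reference subgroup).
* **Predictor-set comparison** — every model refitted with indicators
  only, subgroups only, and both; compared by AIC and relative likelihood
  `RL = exp((AIC_min − AIC)/2)`, with per-row min–max scaled AIC for
  heatmap display and RL ≤ 0.1 flagged as a significant difference.

See the methods vignette (`vignettes/methods.Rmd`) for the model details,
the generator's assumptions and the numerical choices.

## Worked example

```r
library(t2dsubgroups)

params <- default_params("DCS", n_individuals = 1000, seed = 42)
sim      <- simulate_cohort(params)          # cohort + true subgroups
co       <- apply_inclusion_criteria(sim$cohort)
baseline <- select_baseline(co)
model    <- name_clusters(fit_subgroups(baseline, seed = 42),
                          table1_centres("DCS"))
model
#> <cluster_model> k = 5 (named)
#>         age    bmi  hba1c c_peptide    hdl
#> MDH   0.778 -0.643 -0.359    -0.575  1.434
#> SIRD  0.838  0.044 -0.424     1.088 -0.519
#> MOD  -0.805  1.662 -0.013     0.609 -0.292
#> MD   -0.538 -0.302 -0.278    -0.534 -0.289
#> SIDD -0.278 -0.232  2.176    -0.338 -0.120
#> cluster sizes: 184, 217, 142, 332, 116
```

Each row is a pooled centre in per-sex z-score space; the signature
pattern is exactly what the subgroup names encode (SIDD: HbA1c +2.18 SD;
MDH: HDL +1.43 SD; MOD: BMI +1.66 SD; SIRD: C-peptide +1.09 SD and older).

```r
compare_partitions(sim$true_labels[names(model$labels)], model$labels)
#> <agreement_report> n = 991
#> accuracy 0.8254 (95% CI 0.8003, 0.8486)   kappa 0.7751
```

At the realistic within-subgroup spread, fitted subgroups agree with the
generating labels for 83% of individuals (κ 0.78) — the mixture components
genuinely overlap.

```r
wt   <- window_indicators(co, window_spec(c(0, 2, 4, 6, 8)), baseline)
cons <- consistency_report(model$labels, centre_reallocate(wt, model))
round(cons$accuracy, 3)
#> [0,2) [2,4) [4,6) [6,8)
#> 0.957 0.835 0.805 0.799
```

Membership decays over follow-up as treatment pulls HbA1c down and the
parameters drift — most of the loss is in the first re-assessment.

```r
st  <- outcome_table(co, "AMI", model$labels, baseline)
cox <- fit_cox(st, reference = "MDH")
cox$table[, c("term", "hr", "lower", "upper", "schoenfeld_p")]
#>           term   hr lower upper schoenfeld_p
#> 1 subgroupSIDD 1.53 0.730  3.22        0.761
#> 2  subgroupMOD 1.69 0.852  3.36        0.761
#> 3 subgroupSIRD 1.98 1.070  3.65        0.761
#> 4   subgroupMD 1.62 0.899  2.92        0.761
```

SIRD carries the largest AMI hazard versus MDH, the only CI excluding 1
at this cohort size; the Schoenfeld p-values show no evidence against
proportional hazards.

The whole analysis (simulate/ingest → cluster → trajectories → outcomes →
treatment → comparison → reallocation → transitions, with every table
written as CSV plus a JSON manifest) runs from one call:

```r
run_pipeline(list(simulation = list(style = "DCS", n = 1000),
                  seed = 42, output_dir = "out"))
```

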