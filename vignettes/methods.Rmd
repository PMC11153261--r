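---
title: "Methods: data-driven type 2 diabetes subgroups over follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven type 2 diabetes subgroups over follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Type 2 diabetes is clinically heterogeneous. A widely used way of making
that heterogeneity operational is to cluster newly diagnosed individuals on
a small set of routine clinical indicators — age at baseline, BMI, HbA1c
(mmol/mol), C-peptide (nmol/l, a proxy for insulin secretion/resistance
where fasting-glucose-based HOMA indices are unavailable) and
HDL-cholesterol (mmol/l) — into five phenotype subgroups:

* **SIDD** — severe insulin-deficient diabetes (high HbA1c),
* **SIRD** — severe insulin-resistant diabetes (high C-peptide, older),
* **MOD** — mild obesity-related diabetes (high BMI),
* **MD** — mild diabetes (moderate on all indicators),
* **MDH** — mild diabetes with high HDL-cholesterol.

This package implements the full analytical pipeline around that
stratification for longitudinal registry cohorts on a diabetes-duration
time axis: inclusion filtering and baseline selection, sex-stratified
k-means subgrouping, windowed re-assessment of membership over follow-up,
per-subgroup trajectory models, time-to-complication models, treatment-step
patterns from ATC codes, and an AIC/relative-likelihood comparison of the
discrete subgroups against the raw indicators as predictors. Because the
registries this kind of analysis runs on are access-restricted, the package
also ships a seeded synthetic cohort generator with the same statistical
skeleton, so every stage is testable end to end.

## Clustering

Clustering operates on the baseline observation: the visit nearest to
diagnosis carrying all five indicators, required within 2 years of
diagnosis. Ties on duration keep the first record in file order (with a
warning); baseline age is age at diagnosis plus the baseline duration.

Indicators are z-scored per sex on the baseline sample (sample SD,
denominator $n-1$). "Scaled" is deliberately interpreted as the z-score:
it makes Euclidean distance unit-free and matches the convention of the
clustering lineage this analysis belongs to. Men and women are clustered
separately (k-means, $k = 5$) to prevent sex differences in indicator
distributions from driving the partition, then the five female clusters
are matched one-to-one to the five male clusters by minimal total
Euclidean distance between centroids, and each matched pair is pooled.
The pooled centre is the arithmetic mean of the scaled indicator vectors
of all members of the pair, both sexes.

k-means is delegated to `stats::kmeans` (Hartigan–Wong) with 25 random
restarts, `iter.max = 100` and a fixed seed; with 25 restarts on
five-cluster clinical data the returned optimum is stable across seeds in
our tests. Empty clusters trigger a logged re-run with a new sub-seed.

Cluster naming assigns the five subgroup labels to the fitted centres by
the one-to-one assignment minimising total Euclidean distance to a named
reference set. At $k = 5$ this is solved exactly by enumerating all 120
permutations — never greedily, since greedy matching can be trapped by
close centroids. The default reference is the published per-subgroup
baseline mean vectors of the chosen registry style (`table1_centres()`),
scaled with the model's own per-sex scaling and pooled with
stratum-size weights; externally supplied centres are accepted. Scaling is
computed within the analysed cohort (the alternative — reusing another
cohort's scaling — is supported by passing already-scaled references).

Later observations are assigned by `assign_nearest_centre()`: the
Euclidean-nearest centre in scaled space, ties broken by the fixed
canonical order SIDD < SIRD < MOD < MD < MDH. Assignment is invariant to
any common positive rescaling of the scaled axes.

## Agreement between partitions

`compare_partitions()` reports the 5×5 confusion matrix, overall accuracy
with an exact Clopper–Pearson 95% CI (the CI method is a package choice),
Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal
products, and per class $c$: sensitivity $n_{cc}/\mathrm{row}_c$,
specificity $(n - \mathrm{row}_c - \mathrm{col}_c +
n_{cc})/(n - \mathrm{row}_c)$, and positive specific agreement
$2 n_{cc}/(\mathrm{row}_c + \mathrm{col}_c)$ — the per-class
chance-uncorrected agreement.

## Consistency over follow-up

Follow-up is divided into half-open windows on the duration axis, by
default $[0,2), [2,4), [4,6), [6,8)$ years (half-open to avoid double
counting). Within a window, BMI, HbA1c and HDL are the means of the
available in-window values (the mean is robust to visit timing; last- or
first-observation summaries would be noisier), age is taken at the first
in-window visit, and C-peptide is carried forward from baseline — registry
follow-up rarely re-assays C-peptide, and the carry-forward convention is
kept faithfully, with a switch (`carry_forward_cpeptide = FALSE`) to use
measured values where present. Carrying C-peptide forward tends to
overstate subgroup stability; that is a known limitation of the design,
not of the implementation.

Two re-assessment algorithms are provided:

* **De novo re-clustering** — re-scale within the window, re-fit the
  sex-stratified k-means, and name the shifted centres against the
  *baseline* centres by exact optimal assignment (consistency is defined
  against the baseline subgroups, so the baseline model is the reference,
  not any external centre set). Per-window re-scaling is intentional:
  scaling is part of "repeating the clustering".
* **Centre-based reallocation** — assign each windowed indicator vector to
  the nearest baseline centre under the frozen baseline scaling. No
  re-fitting, no re-scaling, no randomness; on unchanged data it is the
  identity on labels.

Per-window agreement against the baseline partition, ranked transition
trajectories over individuals observed in all windows (ties broken
lexicographically), per-subgroup stay fractions, and the severe/mild
movement dichotomy (severe = SIDD, SIRD; mild = MOD, MD, MDH) are built on
top.

## Trajectory, outcome and treatment models

*Trajectories.* Nine clinical parameters (BMI, HbA1c, HDL, SBP, DBP, total
and LDL cholesterol, creatinine, triglycerides) are summarised as annual
per-subgroup means ± SD (missing values omitted) and modelled with a
linear mixed model: value ~ predictor set + sex + duration + per-individual
random intercept, fitted by **maximum likelihood, not REML** — the point of
the exercise is AIC comparison across fixed-effect structures, which REML
would invalidate. Duration enters linearly; no splines, no random slopes,
no imputation. Subgroups enter as four contrasts against a configurable
reference (SIDD by default).

*Outcomes.* First events of AMI, CHF, PVD, stroke, CKD and ESRD are
analysed on the duration timescale with delayed entry at the baseline
observation: individuals join the risk set only from their baseline
duration onward, which is the operational meaning of left truncation when
enrolment happens after diagnosis. Cumulative incidence is 1 − Kaplan–Meier
(no competing-risk estimator, by design). Logrank tests (global and all 10
pairwise comparisons) use `survival::survdiff`, or the Cox score test when
entry times are present (the two coincide for a group factor);
Benjamini–Hochberg correction is applied within each outcome's 10 pairwise
tests — the within-outcome family, recorded in the output metadata. Cox
models use Efron tie handling, Wald 95% CIs, a MDH reference, optional
age/sex adjustment, and Schoenfeld residual tests per model term with
violation flagged at p < 0.05.

*Treatment.* Active ATC codes map deterministically to one of six
mutually exclusive steps — NoTreatment, OnlyCVD (C01–C10), Step1
(metformin A10BA02 or glinides under A10BX), Step2 (sulfonylurea A10BB),
Step3 (insulin A10A), OtherOAD (A10BH, A10BJ, A10BF, A10BK, A10BG, plus
A10BX07 and A10BX09, which are excluded from the glinide rule). The default
precedence Step3 > Step2 > Step1 > OtherOAD > OnlyCVD > NoTreatment reads
the step definitions as a cumulative ladder whose observed step is the
highest rung, OtherOAD applying only when no ladder drug is present; the
alternative ranking (OtherOAD above steps 1–2) is selectable and the rule
in force is recorded. Yearly steps come from the first available
observation in each year bin, with no carry-forward across empty bins and
censoring ignored — accepting a known underestimation of intensive steps
late in follow-up. The multinomial logistic model uses NoTreatment as the
reference category and MD as the reference subgroup, so the headline
contrast (insulin vs no treatment, SIDD vs MD) is a single coefficient.

## Predictor-set comparison

Every target model (each trajectory parameter, each outcome's Cox model,
the treatment multinomial) is fitted three times on identical data with the
same estimator: indicators only, subgroups only, both. Models are compared
by AIC and relative likelihood $RL = \exp((AIC_{\min} - AIC)/2)$; the
AIC minimiser has RL = 1 by construction. "Scaled AIC" is per-row min–max
normalisation to [0, 1] (a display convention, documented in the output),
and a difference is flagged as significant when RL ≤ 0.1.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical skeleton the analysis assumes,
not any real registry's joint distribution:

* Baseline indicators are drawn from a five-component mixture of
  **independent truncated-normal marginals** (truncated at 0 to respect
  positivity) whose per-subgroup means and SDs equal the published
  baseline characteristics of the chosen registry style (DCS-like or
  GoDARTS-like), as do the mixing proportions, male fractions and baseline
  treatment-step distributions. No within-subgroup covariances are
  published, so independence is the default; the profile structure accepts
  edits if correlation is wanted.
* Baseline duration is uniform on [0, 0.5] years for the DCS style and a
  point mass at 0.02 years for the GoDARTS style, reflecting how soon after
  diagnosis each registry first observes its participants.
* Longitudinal values follow baseline + linear drift + individual random
  intercept + residual noise; the baseline visit carries the drawn values
  exactly (noise enters from the second visit), so baseline sample means
  estimate the configured profile means without attenuation. C-peptide is
  constant within individual. Drift slopes and variance components are
  free parameters with documented defaults, not registry facts.
* Treatment escalates yearly along the NoTreatment → Step1 → Step2 → Step3
  ladder (OtherOAD as a parallel branch, CVD-only as a possible start),
  with escalation probability 0.25/year while HbA1c exceeds the 53
  mmol/mol target and 0.03/year otherwise. Once glucose-lowering treatment
  is underway after baseline, HbA1c is pulled 70% of the way to target
  over a 2-year ramp. Because SIDD starts farthest above target, this
  single mechanism makes SIDD both the most intensively treated and the
  least stable subgroup — the qualitative pattern the consistency analysis
  is designed to detect.
* First-event times are exponential from study entry with hazard
  $\exp(\text{base} + \text{subgroup offset})$, right-censored at end of
  follow-up or an exponential censoring time (rate 0.03/year). The
  SIRD-vs-MDH offsets for AMI and CKD are anchored at log(1.65) and
  log(1.38); the remaining offsets are plausible free defaults. There is
  no competing-risk death process and no calendar-time effect.

`simulate_linear_cohort()` is the counterpart in which longitudinal values,
log-hazards and treatment log-odds are **linear in the continuous baseline
indicators** rather than functions of the discrete subgroup. Under it the
subgroup label carries no information beyond the indicators, which is the
regime in which the indicators-only predictor set should win the AIC
comparison; the subgroup-driven generator provides the converse regime.

What passing tests on these generators shows: the estimators recover known
truth, the two reallocation methods order as expected under drift, and the
predictor-set comparison responds to the generating mechanism. What it
does not show: behaviour under real-registry features the generator omits —
correlated indicators, informative visit schedules, non-linear drift,
competing mortality, coding artefacts in ATC data.

## Numerical choices and degenerate inputs

* k-means: 25 restarts, `iter.max` 100, fixed seed; strata smaller than
  $k$ are an error; empty clusters re-run with a logged sub-seed.
* Mixed models: `lme4::lmer(REML = FALSE)` with its default deterministic
  optimiser; non-convergence is an error carrying the optimiser message;
  singular fits (variance at the boundary) warn and keep the boundary
  value. At a true zero random-intercept variance the model costs at most
  2 AIC relative to ordinary least squares.
* Multinomial: `nnet::multinom` with `reltol = 1e-15`, `maxit = 2000`,
  so the two-category case agrees with binary logistic IRLS to ~1e-7.
* Cox: Efron ties; monotone likelihood (separation) is converted from a
  warning into an error with diagnostics; constant covariates are dropped
  with a warning.
* Zero-variance indicators make scaling an error naming the (sex,
  indicator) pair; measurements must be strictly positive where present;
  missing values are empty cells, never coded numbers.
* Missing GAD status excludes by default (the conservative reading of a
  GAD-negativity criterion); `missing_gad_as_negative = TRUE` relaxes it.
* Determinism: every stochastic step takes a seed; the pipeline derives
  per-stage seeds from one master seed by a fixed rule recorded in its
  manifest, and identical configurations reproduce outputs byte for byte.

## Test problem sizes

The shipped test-suite and acceptance script use simulation sizes chosen to
make Monte-Carlo checks sharp while keeping a full run inexpensive on one
CPU: label-recovery and reallocation checks at 400–2,000 individuals,
parameter-recovery fits at 500 individuals × 6 visits (mixed models),
5,000 person-years (multinomial) and 2,000 individuals (Cox), and
directional replication studies at 50 replicates. These are the package's
own choices of problem size; all scale linearly if larger runs are wanted.

## Known limitations

Independent indicator marginals; carried-forward C-peptide; no
competing-risk modelling; no time-varying covariates or random slopes; no
imputation (missing data are omitted analysis-wise); treatment patterns
ignore censoring; cluster count fixed at $k = 5$ with no autoimmune
subgroup (GAD-positive individuals are excluded at intake); assignment of
an individual on both insulin and another OAD to Step3 follows the ladder
precedence and is a convention, not an observed fact.
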