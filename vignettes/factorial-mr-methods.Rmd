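---
title: "Factorial Mendelian randomization: models, generator, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial Mendelian randomization: models, generator, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

Mendelian randomization (MR) uses genetic variants as instruments for an
exposure: because alleles are assorted at conception, a weighted allele
score is essentially randomized with respect to later confounding.
*Factorial* MR pushes the analogy to a 2x2 factorial trial. Two
independent genetic scores — here an Lp(a)-lowering proxy and either an
LDL-C-lowering drug-target proxy (HMGCR, NPC1L1, PCSK9, LDLR) or a
lifestyle trait (BMI, SBP, smoking, alcohol, physical activity) — are
each split at their sample median, and the cohort falls into four
naturally randomized subgroups: higher on both (the reference,
"untreated" arm), lower on one only, or lower on both. Comparing the
both-lower subgroup against the sum of the single-arm effects asks
whether two interventions combine additively on the log-hazard scale.

`factorialMR` implements this analysis chain end to end:

1. **Scores** (`read_weights()`, `compute_score()`): a score is
   \(S_i = \sum_j g_{ij} \beta_j\) with dosages \(g_{ij} \in \{0,1,2\}\)
   and per-allele weights \(\beta_j\) in trait units — mg/dL for lipid
   scores, which is what makes "per 50 mg/dL" reporting meaningful.
   Weights are stored trait-increasing; a "lowering" arm is the same
   score read through the sign of its fitted coefficient, never a
   re-signed weight table (one stored orientation avoids double-negation
   bugs; `flip_score()` exists for the rare case an analyst wants the
   other convention, and scaled reporting is invariant to it).
2. **Median split and allocation** (`dichotomize()`,
   `allocate_factorial()`): ties at the median go to the *lower* group.
   Any fixed rule would do; a documented deterministic one keeps
   allocations reproducible, and ties only arise in practice for
   degenerate integer-valued scores.
3. **Engines** (`fit_linear()`, `fit_cox()`): ordinary least squares with
   \(\hat\sigma^2 (X'X)^{-1}\) standard errors, and a Cox
   proportional-hazards fitter maximizing the Breslow-approximation log
   partial likelihood by Newton–Raphson (start \(\beta = 0\),
   step-halving on likelihood decrease, convergence at
   \(\max_j |U_j| < 10^{-8}\), at most 50 iterations, SEs from the
   inverse observed information). Breslow tie handling is the default and
   only the default is exercised by the shipped analyses: simulated
   continuous times make ties essentially impossible, and fixing the
   convention makes results bit-reproducible. Monotone likelihoods
   (perfect separation) are flagged via the `converged` field, never
   silently returned. The hot loop is a single O(n p^2) risk-set scan in
   C++.
4. **Analysis stages** (`biomarker_association()`, `per50_hr()`,
   `factorial_contrasts()`, `interaction_test()`,
   `composite_outcome()`): every model adjusts for the same set — age,
   sex, assessment-center indicators (first center dropped), and the
   first ten genetic principal components. The per-50-mg/dL-decrease
   hazard ratio is \(\exp(-50\hat\beta)\) with CI endpoints
   \(\exp(-50(\hat\beta \mp 1.96\,\mathrm{se}))\); non-lipid arms have no
   mg/dL scale and are reported per SD decrease instead (`per_sd_hr()`).
   Composites (3- and 4-point MACE) are first-event unions of component
   outcomes.

## The interaction test

Dichotomized scores are convenient for display but statistically
inefficient for detecting interactions, so the test of record uses the
*continuous* scores: a Cox fit with standardized \(Z_A\), \(Z_B\) and
their product, the interaction p-value being the Wald p on the product
term. Standardizing first decouples the product coefficient from the
arms' native scales (an mg/dL x mg/dL product would carry units of
mg^2/dL^2); the raw-scale product is available behind
`standardize = FALSE`. The dichotomized analogue — a product of the two
lower-group indicators — is implemented too
(`interaction_test_dichotomized()`), purely as the comparator in the
power study.

"Departure from additivity" is operationalized on the log-hazard scale,
i.e. as departure from multiplicative combination of hazard ratios. That
is the scale on which a product term inside a Cox linear predictor lives;
additive-risk-scale interaction is a different estimand and is out of
scope here. Similarly, with a multiplicative-hazards data-generating
process and no product term, the both-lower subgroup's log-HR should
equal the sum of the single-arm log-HRs — the additive baseline that
`run_additivity()` verifies. All tests are two-sided.

## The synthetic cohort generator

Individual-level biobank data of the kind this design needs is
access-controlled, so the package ships a generator
(`generate_cohort()`) whose defaults encode the cohort the analysis
assumes, with every parameter recorded in a ground-truth JSON sidecar:

* **Genotypes**: independent variants, dosage ~ Binomial(2, eaf) —
  the analysis model for clumped instruments in weak LD. Correlated
  variants are deliberately not modeled; instruments are treated as
  already clumped, and independence keeps closed-form score moments
  available for the oracles (\(E[S] = \sum_j 2 f_j \beta_j\),
  \(\mathrm{Var}[S] = \sum_j \beta_j^2\, 2 f_j (1 - f_j)\)).
* **Instruments**: the bundled weight tables mirror the published
  instrument cardinalities per arm (43 variants for Lp(a); 26, 6, 42 and
  52 for HMGCR, NPC1L1, PCSK9, LDLR; 237 for overall LDL-C; 62, 455,
  248, 98 and 16 for BMI, SBP, smoking, alcohol and physical activity),
  but frequencies and effects are synthetic: counts come from the
  literature, values do not. Each table's effects are scaled so the score
  SD is realistic — about 17 mg/dL for the Lp(a) score (Lp(a) is largely
  genetically determined), a few mg/dL for the drug-target scores.
* **Biomarkers**: each of seven lipids is intercept + loading-weighted
  scores + Gaussian noise, with intercepts solved so population means hit
  their targets (Lp(a) 17.6 mg/dL, LDL-C 138.0, etc. — mid-life European
  cohort values) and noise SDs chosen so total variances are realistic
  (Lp(a) total SD near 19.7 once the genetic SD of 17 is added). The
  Gaussian model allows negative Lp(a) values in the tail; that is an
  accepted simplification — group contrasts, not marginal shapes, are
  what the analyses consume. Cross-trait loadings give the Lp(a) score a
  weak positive effect on measured LDL-C and a negative effect on
  triglycerides, emulating the measured cross-trait pattern of LPA-region
  variants; the TG loading (-0.12 mg/dL per mg/dL of predicted Lp(a))
  was set so the median-split TG contrast lands near +3 mg/dL.
* **Covariates**: age ~ N(56.7, 8.0), 46% male, 22 assessment centers,
  10 standard-normal PCs. Covariates carry small nonzero hazard effects
  by default (age 0.02/yr, sex 0.15, PC 0.02, a 0.05-amplitude spread of
  fixed center effects) so that covariate adjustment in the analyses is
  exercised rather than vacuous.
* **Outcomes**: event times are exponential — constant baseline hazard —
  with linear predictor \(\sum_s \beta_s S_s\) (+ optional product term
  on standardized scores), administratively censored at 12 years. The
  Cox model is semi-parametric, so recovery of log-HRs is unaffected by
  the baseline shape, and the exponential form gives closed-form event
  probabilities \(1 - e^{-\lambda_0 C}\) for the tests. Baseline hazards
  are set so 12-year cumulative incidences land at 4–12% —
  deliberately inflated relative to a real mid-life cohort so desk-scale
  samples carry adequate events. Only incident events are generated:
  real cohorts also contain prevalent cases, but no defensible time
  origin for them exists without stating a handling convention, so the
  generator does not emulate prevalence.

One master seed drives everything; each component (genotypes per score,
covariates, biomarkers, survival per outcome, each simulation replicate)
draws from a deterministic substream (`substream_seed()`), so components
can be regenerated independently and whole pipelines are byte-identical
under a fixed seed.

### What passing tests do and do not show

The generator matches the *statistical structure the analysis assumes*:
independent instruments, linear score-biomarker links, proportional
hazards, correctly specified adjustment. Passing recovery, coverage and
size checks therefore shows the estimator chain is correct under its own
assumptions. It does not show robustness to what real data add: LD
between variants, pleiotropy beyond the configured loadings, population
stratification beyond simulated PCs, non-proportional hazards,
prevalent-case time origins, or ascertainment by diagnostic codes.

## The Monte-Carlo validation surface

`run_suite("acceptance")` (also reachable via
`pipeline_evaluate()`) runs the pre-registered scenarios of
`inst/suites/acceptance.yaml`:

* **Recovery** — 200 replicates at n = 20,000, generating truths
  spanning per-50 HR 0.7 / 0.9 / 1.0: bias of the per-50 log-HR within
  3 Monte-Carlo SEs of zero. Truths are read back from each replicate's
  generating config, never restated in the harness.
* **Coverage** — 1,000 replicates at n = 2,000: empirical 95% CI
  coverage inside [93.5%, 96.5%] (the 3-SE binomial band).
* **Type-I error** — 1,000 replicates at n = 5,000 under interaction
  truth zero: continuous product test rejects at 5% +- 1.5%, and the
  null p-values pass a uniformity check.
* **Power ordering** — 250 replicates per point on the effect grid
  {0, 0.05, 0.10, 0.15} (log-HR per standardized-score product): the
  continuous test's power is never below the dichotomized test's by more
  than twice the paired Monte-Carlo SE, and rises along the grid. The
  grid was placed by pilot runs so that it spans low to near-complete
  power at n = 5,000.
* **Additivity** — 200 replicates at n = 10,000 with both arm effects
  nonzero (per-50 HRs 0.8 and 0.75) and zero interaction: mean
  discrepancy between the both-lower log-HR and the sum of the single-arm
  log-HRs within 3 Monte-Carlo SEs of zero.

Scenario sizes (n = 2,000–20,000; 200–1,000 replicates) are the
package's desk-scale choices: large enough that binomial 3-SE bands are
informative, small enough that the whole suite runs in minutes on one
CPU. Simulation scenarios use a compact two-arm design (20 variants per
score, 4 centers, one outcome at a ~19% event proportion) rather than the
full ten-arm cohort; the estimators are identical, only the bystander
dimensions shrink. Every rate is reported with its Monte-Carlo SE, and
non-convergent replicates are counted and reported, never dropped.

## Numerical and design notes

* **Tie rule**: ties at the median go to the lower group (documented,
  deterministic).
* **Center/sex coding**: one-hot center indicators dropping the first
  category; sex as 0/1. Any coding with the same column space gives the
  same fit; one is fixed for reproducibility.
* **Rank checks**: both engines refuse rank-deficient designs and name
  the collinear columns rather than silently dropping them.
* **Cox numerics**: columns are mean-centered and the linear predictor
  max-shifted before exponentiation; both shifts cancel exactly in the
  partial likelihood. The line-search accept tolerance is relative
  (\(10^{-9}(|\ell| + 1)\)) so floating-point noise at the optimum cannot
  trigger spurious step-halving. Fits with any \(|\beta_j| > 15\) are
  flagged non-converged (a hazard ratio of \(e^{15}\) per unit is a
  separation artifact, not an estimate).
* **Medians** are always computed on the analysis cohort as given;
  there is no notion of pre-exclusion medians.
* **Interaction adjustment**: interaction models carry the same
  covariate adjustment set as every other model.
* **Composite censoring**: a censored composite ends at the shortest
  component censoring time, so composites remain well-defined if
  components ever had different horizons.

## Known limitations

* No LD, no allele harmonization, no real genotype formats (VCF/BGEN):
  weight tables are consumed, not derived, and synthetic dosages are
  already oriented to the effect allele.
* Exponential baseline hazards and incident-only outcomes, as discussed
  above; no competing risks, stratified baselines, time-varying effects,
  or robust variance.
* No multiple-testing adjustment across outcomes — deliberate, to match
  the analysis style this package mirrors.
* Hazard-ratio subgroup contrasts are non-collapsible in principle;
  with the moderate effects and event rates used here the induced
  deviation from additivity is far below Monte-Carlo resolution, and the
  additivity scenario verifies exactly that.
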