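# mrdose

Linear and nonlinear Mendelian randomization (MR) for quantitative
exposures — lipid traits are the motivating case — against binary disease
and cause-specific mortality outcomes, using genetic risk scores as
instruments.

MR treats genetic variants as natural randomization: a variant $G$ that
raises an exposure $X$ but is independent of confounders $U$ and affects an
outcome $Y$ only through $X$ identifies the causal effect of $X$ on $Y$.
`mrdose` implements the full analysis design used in large biobank studies
of apolipoprotein B, LDL cholesterol, and triglycerides:

- **Instruments** — weighted genetic risk scores (GRS) with external GWAS
  weights, allele harmonization, greedy LD pruning (r² < 0.001),
  variance-explained and F-statistic diagnostics
  ($F = (n-2)R^2/(1-R^2)$, F > 10 rule), confounder screening, and Blom
  inverse rank-normalization.
- **Association engines** — linear and logistic regression and Cox
  regression on the **attained-age timescale** with delayed entry, Efron
  ties, and cause-specific censoring for competing causes of death, with
  the standard epidemiological adjustment sets (age/birth-year terms, sex,
  interactions, 20 principal components) as named presets.
- **Linear MR** — the ratio method
  $\hat\theta = \hat\beta_{GY}/\hat\beta_{GX}$ plus the
  sensitivity-estimator suite: inverse-variance weighted (IVW, with
  multiplicative random effects), MR-Egger (directional-pleiotropy
  intercept), weighted median (bootstrap SE), and the contamination
  mixture (profile likelihood over valid/invalid variant configurations,
  possibly disjoint confidence sets).
- **Multivariable MR** — two-stage GRS estimation of direct effects of
  correlated exposures, with Sanderson–Windmeijer-style conditional F
  statistics.
- **Nonlinear MR** — doubly ranked stratification (instrument pre-strata,
  exposure ranking within pre-strata), stratum-specific localized average
  causal effects (LACE), fractional polynomial meta-regression on the
  derivative basis (powers {−2, −1, −0.5, 0, 0.5, 1, 2}), trend and
  nonlinearity tests, and dose-response curves reported relative to the
  median exposure.
- **Synthetic cohorts** — a generator with known causal curves (linear,
  quadratic, threshold, J-shape), a hidden confounder, three competing
  Weibull cause-specific hazards, recruitment ages 40–69, ~7% disease
  prevalence and ~7% deaths, and optional exposure-dependent selection —
  so every stage is testable without access to individual-level biobank
  data.

## Worked example

Simulate a cohort with a linear causal effect of 2 log-odds units per
exposure unit (≈ 0.5 per exposure SD of 0.25), run the whole pipeline, and
read off the estimates:

```r
library(mrdose)

cfg <- analysis_config(
  sim = sim_config(n_individuals = 20000, n_variants = 100,
                   causal_curve = causal_curve("linear", 2), seed = 1),
  outcomes  = c("disease", "allcause"),
  methods   = c("ratio", "ivw", "egger", "weighted_median", "conmix",
                "nonlinear"),
  subgroups = "sex", n_strata = 10, seed = 2024)
res <- run_pipeline(cfg)
print(res)
```

```
MR pipeline results
  n = 20000; score R^2 = 0.119 (F = 2693)
  linear MR estimates:
            method  outcome subgroup theta     se ci_low ci_high        p
1            ratio  disease      all 0.485 0.0751 0.3375   0.632 1.08e-10
2              ivw  disease      all 0.508 0.0738 0.3631   0.652 6.01e-12
3            egger  disease      all 0.424 0.1236 0.1818   0.666 6.03e-04
4  weighted_median  disease      all 0.479 0.1111 0.2608   0.696 1.65e-05
5           conmix  disease      all 0.507 0.0729 0.3641   0.650 3.55e-12
6            ratio  disease     male 0.622 0.1040 0.4181   0.826 2.21e-09
7            ratio  disease   female 0.336 0.1085 0.1230   0.548 1.97e-03
8            ratio allcause      all 0.218 0.0723 0.0766   0.360 2.53e-03
...
  subgroup difference tests:
          outcome comparison     z      p
disease   disease        sex 1.905 0.0567
allcause allcause        sex 0.386 0.6998
  nonlinear MR: 10 strata per outcome; curves on 101 grid points
```

The GRS explains 11.9% of exposure variance (F = 2693, far above the
weak-instrument threshold of 10). On the rank-normalized (per-SD) scale
the ratio estimate for disease is 0.485 log-odds per SD — an odds ratio of

```r
row <- subset(res$linear, method == "ratio" & outcome == "disease" &
              subgroup == "all")
round(exp(c(OR = row$theta, lo = row$ci_low, hi = row$ci_high)), 2)
#>   OR   lo   hi
#> 1.62 1.40 1.88
```

consistent with the simulated truth of exp(0.5) ≈ 1.65 per SD, and all
four sensitivity estimators agree. The nonlinear analysis correctly finds
no departure from linearity (trend p = 0.76, fractional-polynomial
nonlinearity p = 0.64 for disease), and the dose-response curve in
`res$curves` passes through 0 at the median reference exposure.

Published subgroup contrasts can be tested directly from printed
confidence intervals:

```r
male   <- estimate_from_ci(1.81, 1.70, 1.92, "logOR")
female <- estimate_from_ci(1.43, 1.32, 1.55, "logOR")
subgroup_difference_z(male, female)$p
#> [1] 4.562316e-06
```

## Package layout

- `R/simulate.R`, `R/sim_config.R` — synthetic cohort generator and true
  causal curves
- `R/instruments.R` — GRS construction, diagnostics, pruning,
  rank-normalization
- `R/assoc.R` — linear / logistic / Cox (attained age, cause-specific)
  engines
- `R/mr_linear.R`, `R/mr_mvmr.R` — ratio method, sensitivity estimators,
  multivariable MR, conditional F
- `R/mr_nonlinear.R` — doubly ranked strata, LACE, fractional polynomial
  meta-regression, trend/nonlinearity tests, curve export
- `R/io.R`, `R/pipeline.R` — GWAS-format file I/O, cohort round-tripping,
  the end-to-end pipeline with seeded substreams and a run manifest
- `vignettes/mrdose-methods.Rmd` — the models, assumptions, tuning
  parameters, and design choices in detail
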