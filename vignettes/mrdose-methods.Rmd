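---
title: "Linear and nonlinear Mendelian randomization with mrdose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and nonlinear Mendelian randomization with mrdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mrdose` implements a complete Mendelian randomization (MR) analysis of a
quantitative exposure — a lipid trait such as apolipoprotein B, LDL
cholesterol, or triglycerides is the motivating case — against a binary
disease outcome and cause-specific mortality, in both linear and nonlinear
(dose-response) form. Because individual-level biobank data cannot be
redistributed, the package pairs every estimator with a synthetic cohort
generator whose true causal curve is known, so that each stage of the
analysis can be exercised and validated end to end.

## The instrumental-variable model

Genetic variants $G_1, \dots, G_J$ (biallelic dosages in $[0,2]$) are valid
instruments for exposure $X$ with respect to outcome $Y$ when they are (i)
associated with $X$, (ii) independent of the unmeasured confounder $U$, and
(iii) affect $Y$ only through $X$. A weighted genetic risk score (GRS)

$$Z_i = \sum_j w_j \, g_{ij}$$

aggregates the variants, with weights taken from an external GWAS rather
than re-estimated in the analysis cohort (avoiding winner's-curse
compounding). Instrument strength is summarized by the covariate-adjusted
incremental $R^2$ of the score and the univariate-form F statistic
$F = (n-2)R^2/(1-R^2)$; $F > 10$ is the conventional threshold below which
weak-instrument bias is a concern. Whether the published diagnostics used
incremental or marginal $R^2$ is ambiguous in most applied reports;
`score_strength()` defaults to the covariate-adjusted incremental form and
offers `mode = "marginal"`.

The linear causal estimate is the ratio of two covariate-adjusted
associations, $\hat\theta = \hat\beta_{GY} / \hat\beta_{GX}$, with
first-order delta-method standard error
$\mathrm{se} = \mathrm{se}_{GY}/|\hat\beta_{GX}|$. The first-order form
ignores the uncertainty in $\hat\beta_{GX}$; with $F \gg 10$, as in every
intended use here, the neglected term is a second-order correction (the
package's tests bound it by parametric bootstrap).

Association engines follow the epidemiological design exactly: linear
regression for quantitative traits (after inverse rank-normalization when
comparability across traits is wanted), logistic regression for combined
prevalent-plus-incident disease, and Cox regression for mortality with
**attained age as the timescale** — the risk set at age $t$ contains
individuals with entry age $< t \le$ exit age (delayed entry), which makes
age itself the baseline stratifier. Disease models adjust for baseline age,
age$^2$, sex, their interactions, and 20 genetic principal components
(`"cad_set"`); mortality models replace the age terms with birth-year terms
(`"mortality_set"`), since age is already the time axis. Cause-specific
hazards treat deaths from competing causes as censorings at the event age;
Fine-Gray subdistribution hazards are deliberately out of scope. Ties are
handled by the Efron method (attained-age data tie frequently); the
applied literature rarely states its tie method, so this is recorded here
as the package's choice. Convergence uses a relative log-likelihood
tolerance of 1e-8 with an iteration cap of 50.

## Sensitivity estimators

The ratio method assumes all instruments valid. Four summary-statistic
estimators with different validity assumptions are provided, all consuming
the same per-variant table $(\hat\beta_{GX,j}, \hat\beta_{GY,j},
\mathrm{se}_j)$:

* **IVW** — zero-intercept weighted regression of $\hat\beta_{GY}$ on
  $\hat\beta_{GX}$ with weights $1/\mathrm{se}_{GY,j}^2$; algebraically the
  precision-weighted mean of per-variant ratios. Heterogeneity is absorbed
  multiplicatively: the fixed-effect SE is scaled by $\sqrt{Q/(J-1)}$ when
  Cochran's $Q$ exceeds its expectation. Fixed- versus random-effects is
  rarely stated in applied work; multiplicative random effects is the
  default of the underlying methodology and is what the package uses.
* **MR-Egger** — the same regression with a free intercept after orienting
  all $\hat\beta_{GX,j} \ge 0$; a nonzero intercept estimates directional
  pleiotropy and the slope is consistent under the InSIDE assumption.
* **Weighted median** — the weighted median of per-variant ratios with
  weights $\propto \hat\beta_{GX,j}^2/\mathrm{se}_{GY,j}^2$, interpolating
  the weighted CDF at 0.5 through midpoint positions $p_j = (\mathrm{cum}_j
  - w_j/2)$; consistent when at least half the weight is valid. Its SE
  comes from a seeded parametric bootstrap (default 1000 draws) — the
  original method's approach.
* **Contamination mixture** — each variant's ratio is modelled as valid,
  $\mathcal N(\theta, \mathrm{se}_j^2)$, or invalid, $\mathcal N(0,
  \mathrm{se}_j^2 + \psi^2)$; the profile likelihood maximizes over
  validity per variant on a 501-point grid spanning the ratio range
  extended by 25%. The 95% confidence set is the likelihood region
  $2(\ell_{\max} - \ell(\theta)) < 3.84$ and may be disjoint; the hull is
  reported with the modes attached. $\psi$ defaults to 1.5 times the SD of
  the ratio estimates, the default of the method's original description;
  both $\psi$ and the grid are configurable and recorded in the result.

All estimators are invariant to joint sign-flips of
$(\hat\beta_{GX,j}, \hat\beta_{GY,j})$, and all internal effect estimates
stay on the log scale; exponentiation to ORs/HRs per exposure SD happens
only at export.

## Multivariable MR and conditional instrument strength

With correlated exposures (apoB and LDL-C correlate near 0.96), direct
effects are estimated by a two-stage GRS analysis: stage 1 regresses each
exposure on all the scores plus covariates, giving the coefficient matrix
$B$; stage 2 regresses the outcome on all the scores, giving coefficients
$c$ with covariance $V$; direct effects solve $B^\top \theta = c$, with
delta-method covariance $A V A^\top$, $A = (B^\top)^{-1}$, treating $B$ as
fixed (first-order; the stage-1 coefficients are estimated with very high
precision at biobank scale). Instrument sets are merged, de-duplicated and
LD-pruned before scoring. Instrument strength per exposure *conditional on
the others* uses a Sanderson-Windmeijer-style statistic: the incremental F
of the instruments for one exposure after partialling out the genetically
predicted values of the other exposures, computed from span projections so
that exactly collinear score sets collapse to $F = 0$ rather than erroring.
A score with zero variance cannot identify its exposure; that exposure is
dropped from both stages with a warning, reducing the model to the
lower-dimensional analysis.

## Nonlinear MR: doubly ranked strata and fractional polynomials

Stratifying on the exposure itself would condition on a collider and
induce instrument-confounder associations within strata. The **doubly
ranked** method avoids this: individuals are sorted by the instrument
score, cut consecutively into pre-strata of size $S$, ranked by exposure
within each pre-stratum, and the individual with exposure rank $j$ joins
final stratum $j$. Final strata then differ systematically in exposure
while the instrument remains (approximately) independent of confounders
within each stratum — the package's tests verify both this independence
and its failure under naive exposure deciles. Note what the method does
*not* do: the confounder itself is **not** balanced across strata (exposure
rank within a pre-stratum is partly confounder-driven), and no such balance
is needed for validity; the working property is instrument-confounder
independence within strata. A final incomplete pre-stratum of size $r < S$
sends its members to final strata $1..r$ after ranking; exposure ties break
by instrument order, instrument ties by exposure then input order — all
deterministic. The default is $S = 10$ strata.

Within each stratum, the ratio estimate is recomputed on the **raw
exposure scale** (no rank-normalization: clinical interpretation of a
dose-response curve needs absolute exposure units). The stratum estimate
$\hat\theta_k$ is interpreted as the causal curve's derivative near the
stratum mean exposure $\bar x_k$ — the localized average causal effect
(LACE). Strata without events or exposure variance are flagged and
excluded from meta-regression with a warning.

The curve is then estimated by **fractional polynomial meta-regression**:
for every candidate power set from $\{-2,-1,-0.5,0,0.5,1,2\}$ (0 meaning
$\log x$; repeated powers use the log-modified basis $x^p, x^p\log x$) up
to degree 2, the stratum estimates are regressed, with weights
$1/\mathrm{se}_k^2$, on the *derivative* basis of the candidate curve at
$\bar x_k$; the best-likelihood model wins, with ties broken toward lower
degree and then toward power 1. The fitted derivative is integrated
analytically, term by term, and the curve is reported relative to the
sample median exposure (effect 0 at the reference, pointwise CIs from the
coefficient covariance). Exposures are shifted by $1 - \min \bar x_k$
before applying powers whenever any $\bar x_k \le 0$, and the shift is
inverted on output.

Two hypothesis tests accompany the fit. The **trend test** is the z-test
of the slope in a fixed-effect weighted meta-regression of $\hat\theta_k$
on $\bar x_k$. The **nonlinearity test** compares the best fractional
polynomial against the linear model (degree 1, power 1) by likelihood
ratio. Its reference distribution needs care: raw maximum-likelihood
selection essentially always prefers a degree-2 candidate (one extra
coefficient), and the candidate bases are highly correlated, so neither
the naive extra-parameter count (df = 1, anticonservative at 7.5% in null
simulations of the package's study design) nor the power-counting
conventions (df = 2 at 2.5%, df = 3 at 1.3%) are calibrated. The package
uses a Satterthwaite-style effective df matched to the null mean of the
statistic in meta-regression simulations — df = 1.5 for a degree-2 best
model (null mean LR 1.56 over 1000 simulated linear-effect cohorts), df =
1 for a degree-1 best model — giving an empirical size of about 4.3% at
the nominal 5% level under the null. When the selected model *is* the
linear model the p-value is 1 by convention. The effective df was
calibrated for 10-stratum designs; very different stratum counts may
shift it slightly.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the real
analysis population without reproducing any of its data:

* a few hundred independent biallelic variants, MAF uniform on a
  configurable range (default 0.05-0.45), dosages Binomial(2, MAF) —
  instruments are assumed LD-pruned, so no linkage structure is simulated;
* per-allele effects drawn normal and rescaled so the true score explains
  a target share of exposure variance (default `target_r2 = 0.12`,
  matching the ~10-15% seen for lipid GRSs); exposure scaled like apoB in
  g/L (mean 1.0, SD ~0.25);
* a single standard-normal hidden confounder $U$ feeding the exposure
  (default 0.08 units/SD) and every outcome's linear predictor (default
  0.3) — the minimal structure that biases naive regression while leaving
  MR consistent;
* disease from a logistic model with the causal curve centred at the
  reference exposure, intercept set for ~7% prevalence;
* three competing causes of death (cvd / cancer / other) with Weibull
  baseline hazards on the age timescale (default shape 1 = constant
  hazard, rate 9e-4 each, giving ~7% deaths by the administrative
  censoring age of 82); event times are drawn conditional on survival to
  the recruitment age (correct left truncation for delayed-entry Cox
  models), and the causal curve loads on the causes with configurable
  multipliers (default: full effect on cvd, none on cancer, a quarter on
  other — mirroring the qualitative pattern reported for lipid traits);
* recruitment ages uniform on 40-69, recruitment years 2006-2010, sex
  balanced, and 20 principal components simulated as independent standard
  normals with zero effect (pure adjustment covariates, retained so the
  adjustment sets match the applied design exactly);
* optional pre-recruitment selection: individuals retained with
  probability decreasing in exposure, emulating survival to recruitment.
  The strength of such selection is not quantifiable from published
  reports, so these are scenario knobs, not estimates.

The generator exposes the confounder, the true per-variant weights, and
the true causal curve (`true_curve()`, centred at the grid median) to
tests only. What passing tests on these cohorts shows is that the
estimators recover known truths under the assumed data-generating model —
independent instruments, a single additive confounder, proportional
hazards, logistic disease; they do not certify behaviour under linkage
disequilibrium, assortative mating, population stratification, or
time-varying effects, none of which the generator produces.

## Numerical and design choices

* Inverse rank-normalization uses the Blom offset,
  $\Phi^{-1}((r - 3/8)/(n + 1/4))$, with average ranks for ties; published
  descriptions rarely name the offset.
* LD pruning is greedy by ascending p-value with threshold $r^2 < 0.001$;
  p ties break lexicographically by variant id.
* Logistic separation and monotone Cox likelihoods are raised as errors,
  not returned as unstable estimates; rank-deficient designs name the
  collinear columns.
* One pipeline seed fans out to fixed per-stage substreams, so toggling a
  stage never perturbs another stage's randomness and a run manifest
  (seed, config hash, package version) reproduces any run bit-identically.
* Simulation-based tests use cohorts of 1.5k-50k individuals and 10-100
  variants, and 40-1000 replicates depending on the property; these sizes
  were chosen to make Monte Carlo error small relative to the tested
  tolerances.

## Known limitations

The FP nonlinearity test's effective df is a simulation-matched
approximation, not an exact distribution. MVMR standard errors treat
stage-1 coefficients as fixed (adequate at biobank scale; a bootstrap is
the honest alternative at small n). The contamination-mixture SE is a
hull-width proxy accompanying a possibly disjoint likelihood-region CI.
The generator's exposures are unimodal and homoscedastic; real lipid
distributions are right-skewed, which matters mainly for the tails of
dose-response curves.
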