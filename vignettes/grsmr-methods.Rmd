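---
title: "Methods: bidirectional Mendelian randomization with genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional Mendelian randomization with genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmr)
library(dplyr)
```

## The problem

Observational studies consistently report that obesity and atopic dermatitis
(AD) co-occur more often than chance, but association alone cannot say
whether a higher body-mass index (BMI) causes AD, whether chronic skin
disease leads to weight gain, or whether both are driven by shared
confounders. Mendelian randomization (MR) addresses this by using genetic
variants as instrumental variables: alleles are allocated at conception, so
a genetic score that raises BMI is (under the instrumental-variable
assumptions) independent of lifestyle confounders and unaffected by disease
onset. `grsmr` implements the full bidirectional analysis — BMI as a
continuous exposure of a binary AD-like outcome, and AD liability as a
binary exposure of continuous BMI — together with the synthetic-data
generator used to validate every stage by simulation.

## Data-generating model

The generator draws, for individual $i$ and SNP $j$:

* genotypes $g_{ij} \sim \text{Binomial}(2, p_j)$, independent SNPs in
  Hardy–Weinberg equilibrium (no LD, matching the use of independent index
  SNPs in practice);
* a standard-normal confounder $U_i$;
* exposure
  $x_i = \mu + \textstyle\sum_j \gamma_j g_{ij} + c_x U_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma^2)$, in kg/m² (default $\mu = 27$, total
  SD 4.8 — typical adult BMI moments);
* outcome $y_i \sim \text{Bernoulli}(\text{logit}^{-1}(b_0 + \beta x_i +
  c_y U_i + \sum_j \alpha_j g_{ij}))$, where $\beta$ is the causal log-odds
  per exposure unit and $\alpha_j$ are direct (pleiotropic) SNP effects;
* optional reverse causation: cases gain `reverse_beta` kg/m² after the
  outcome draw, the simplest mechanism that produces a reverse-direction
  signal.

With $\alpha \equiv 0$ and `reverse_beta = 0` the exclusion restriction
holds by construction. The intercept $b_0$ is solved from the target
prevalence (default 5%, inside the 2–10% adult AD range).

Six presets ship as flat YAML files (`inst/extdata/scenarios/`): `null`,
`forward_causal`, `confounded_null`, `directional_pleiotropy`,
`balanced_pleiotropy`, `reverse_causal`. Scalar knobs are expanded into
per-SNP vectors deterministically: allele frequencies evenly spaced in
[0.1, 0.5], per-allele exposure effects evenly spaced over a relative range
and rescaled so the SNPs jointly explain the target variance fraction, and
binary-trait risk loci with per-allele log-odds 0.08–0.18 (odds ratios
1.08–1.20, the magnitude of published AD loci; 24 of them, matching the
number of European AD loci used as reverse-direction instruments).

Key preset choices and why:

* `forward_causal`: 100 exposure SNPs explaining 2% of BMI variance at
  n = 20,000 per cohort, true causal OR 1.05 per kg/m², moderate
  confounding ($c_x = 1$ kg/m², $c_y = 0.3$). These are the conditions of
  the package's recovery study.
* `null` and `confounded_null` run at n = 10,000: type-I error and the
  confounding contrast are sample-size-invariant properties, and the
  smaller cohorts let the studies use 1000 and 200 replicates respectively.
* `directional_pleiotropy` / `balanced_pleiotropy` use 100 *individually
  strong* instruments (10% of exposure variance at n = 50,000, per-allele
  effects within a factor of 3, so every per-SNP F exceeds 10). MR-Egger's
  identifiability convention orients all SNP-exposure effects positive; with
  weak instruments, noise flips the orientation of small-effect SNPs and
  corrupts the intercept, so the pleiotropy calibration scenario is defined
  in the strong-instrument regime where the convention is sign-stable.

What the generator does *not* emulate: linkage disequilibrium, population
stratification, relatedness, genotyping error, assortative mating, or
selection into the cohort. Passing the simulation studies therefore shows
the estimators are correct under the MR identifying assumptions — not that
those assumptions hold in any particular real cohort.

## Instruments

Summary statistics travel as tab-separated tables
(`variant_id, effect_allele, other_allele, eaf, beta, se, pvalue, n`) with
column aliases for foreign dialects. Validation routes bad records
(non-positive SE, identical or non-ACGT alleles, out-of-range p or
frequency, duplicates) to an exclusion log rather than dropping them.

`harmonize()` aligns an outcome table to the exposure's effect alleles:
direct and strand-complement matches pass through, swapped labels flip the
outcome beta and reflect the allele frequency, and palindromic (A/T, C/G)
SNPs are excluded under the default `strict-exclude` policy. The
`infer-eaf` option keeps palindromic SNPs whose allele frequencies are
informative on both sides (both below 0.42 or both above 0.58); the
thresholds leave a symmetric uncertainty band around 0.5 where strand
cannot be inferred. Harmonization conserves SNPs (each input appears
exactly once across the retained set and the log) and is involution-safe.

`build_grs()` forms $s_i = \sum_j w_j g_{ij}$ with weights defaulting to
exposure-GWAS betas; missing genotypes are a hard error, with mean
imputation (`impute_genotypes()`, $2 \cdot$eaf) available as an explicit
step only. Instrument strength is reported as first-stage $R^2$ and
$F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$; `confounder_screen()` regresses
each covariate on the standardized score and flags nominal p < 0.05 with no
multiplicity adjustment (screening, not testing).

## Estimators

Per-SNP Wald ratios $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ use the
first-order delta SE $se_{\Gamma_j}/|\hat\gamma_j|$ by default; a
second-order option adds the $\hat\Gamma_j^2 se_{\gamma_j}^2/\hat\gamma_j^4$
term.

**IVW.** $\hat\beta = \sum w_j \hat\gamma_j \hat\Gamma_j / \sum w_j
\hat\gamma_j^2$ with $w_j = 1/se_{\Gamma_j}^2$, equivalently weighted least
squares of $\hat\Gamma$ on $\hat\gamma$ through the origin. Fixed-effect SE
$\sqrt{1/\sum w_j\hat\gamma_j^2}$; the multiplicative random-effects mode
inflates by $\sqrt{\max(1, Q/(J-1))}$. With many individually weak
instruments the classical denominator overestimates $\sum w_j\gamma_j^2$ by
$\sum w_j se_{\gamma_j}^2$ and dilutes the estimate toward the null by
roughly $\bar F/(\bar F + 1)$; `mr_ivw(debiased = TRUE)` subtracts that
term (the debiased IVW of the many-weak-instrument literature) with a
delta-method SE carrying the exposure-side noise. The pipeline defaults to
the debiased denominator because its simulated instruments have per-SNP F
near 4; `mr_ivw()` itself defaults to the classical formula. If the
debiased denominator is non-positive the classical one is used with a
warning.

**MR-Egger.** Weighted regression of $\hat\Gamma$ on $\hat\gamma$ with an
intercept after orienting $\hat\gamma > 0$; the slope estimates the causal
effect under InSIDE, the intercept the average directional pleiotropy. SEs
use the multiplicative inflation $\max(1, RSS_w/(J-2))$. Two consequences
worth knowing: (i) the orientation step misbehaves when instruments are
weak enough for sign flips (see the preset discussion above); (ii) under
*balanced* pleiotropy the inflation absorbs the extra additive dispersion,
so the intercept test is conservative — its empirical size falls below the
nominal 5% rather than above it.

**Weighted median.** Wald ratios sorted, weights
$1/se^2_{ratio}$ normalized, linear interpolation of the cumulative-weight
midpoints at 0.5 (equal weights and odd J reduce to the sample median). SE
by parametric bootstrap (default 1000 draws of $\hat\gamma_j, \hat\Gamma_j$
from their sampling normals).

**Heterogeneity.** Cochran's $Q = \sum w_j(\hat\beta_j - \hat\beta)^2$ with
first-order ratio weights, df $J-1$, upper-tail chi-square p.

**One-sample.** `mr_tsls()` is just-identified two-stage least squares with
structural-residual (IV sandwich) SEs, not naive second-stage SEs.
`mr_grs_ratio()` handles a binary trait on either side: a linear or
logistic first stage for the focal trait, a logistic or linear reduced form
for the outcome, causal estimate $\hat\Gamma_s/\hat\gamma_s$ with the
delta-method SE assuming independent stages (a bootstrap validation exists
in the test suite). Binary-outcome effects are reported on the log-odds
scale; because the logistic model is non-collapsible, the marginal
reduced-form coefficient is attenuated by roughly 2–3% at these effect
sizes relative to the conditional causal parameter — visible as a small
downward shift of the one-sample arm in the recovery study. A weak-instrument
F below 10 warns and never errors (reported, not enforced).

**Scales.** Binary-exposure (reverse-direction) effects are estimated per
unit log-odds and multiplied by $\ln 2$ for the per-doubling-of-odds scale;
odds ratios are exponentiated only at reporting, with the log-scale parent
retained. All scale transitions are recorded in the estimate rows.

**Meta-analysis.** Fixed-effect inverse-variance pooling combines the one-
and two-sample arms; DerSimonian–Laird random effects (moment estimator of
$\tau^2$, truncated at 0) pools observational per-study odds ratios entered
as OR + 95% CI via the CI-width SE reconstruction. $I^2 = \max(0,
(Q-df)/Q)$. Grouped pooling reproduces adult/child × overweight/obese
strata from a `group` column.

## Pipeline design

`run_forward()` simulates two cohorts: cohort A supplies the one-sample
analysis and the instrument-trait GWAS; an independent cohort B supplies
the outcome-trait GWAS, so the two-sample arm has no sample overlap (an
`overlap_fraction` knob deliberately reintroduces overlap; the induced bias
is toward the null). The GRS in cohort A is weighted by effects estimated
in cohort B — external weights, as when weighting by a published GWAS —
which avoids the overfitting of internally derived weights. The combined
estimate is the fixed-effect pool of the one-sample ratio and the
two-sample IVW; random-effects pooling is available but fixed-effect is the
default for two arms estimating the same parameter. `run_reverse()` swaps
the trait roles (logistic first stage, linear reduced form, per-doubling
scaling); `run_observational()` fits logistic outcome-on-exposure
regressions overall and within half-open BMI strata (default [25, 30) and
[30, ∞) kg/m²), skipping strata with fewer than 10 cases. Every stochastic
stage derives its seed from the master seed, so reports are byte-identical
across reruns; report CSVs round to 10 significant digits and exclude
timestamps for that reason.

## Numerical choices

* Per-SNP GWAS scans are closed-form (linear) and per-SNP Newton–Raphson in
  compiled code (logistic; tolerance 1e-8 on the coefficient step, maximum
  30 iterations, step-halving above 5 units, warm start from the linear
  slope divided by $\bar y(1-\bar y)$). Both match `lm()`/`glm()` to
  at least 6 decimals in the tests.
* Monomorphic SNPs are flagged with missing SEs and excluded at
  harmonization with an explicit reason.
* Weighted-median ties interpolate linearly between adjacent order
  statistics; at the boundaries the extreme ratio is returned.
* Egger requires J ≥ 3; J = 1 random-effects IVW falls back to fixed with a
  notice; `meta_dl()` requires k ≥ 2 and directs to `meta_fixed()` otherwise.
* p-values are two-sided normal on the estimate scale (no small-sample
  correction), floored at the smallest positive double.

## Simulation studies and their sizes

The calibration studies run by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use: 200 replicates of `forward_causal` (recovery,
CI coverage, Q calibration), 1000 of `null` (type-I error), 200 of
`confounded_null` (confounding contrast), 200 reverse-direction runs of
`forward_causal` (reverse-null recovery), 100 each of the pleiotropy
presets (Egger power and size), and 100 of `reverse_causal` in the
acceptance script (recovery against the generator-implied per-doubling
effect, $\text{reverse\_beta} \cdot E[p(1-p)] \cdot \ln 2$). Replicate
counts follow the study design where it fixes them (200 recovery, 1000
type-I) and otherwise balance Monte-Carlo precision against a desktop-scale
runtime of roughly a quarter of an hour for the full battery.

## Known limitations

* The one-sample binary-outcome estimator is a two-stage approximation on
  the log-odds scale; it inherits logistic non-collapsibility and is not a
  conditional-likelihood IV estimator.
* The delta SE of the ratio assumes independent stages; with one cohort the
  stages share data, and the approximation is validated only by simulation.
* No MR-PRESSO, mode-based estimators, multivariable MR, or Steiger
  filtering; no LD-aware instrument handling, clumping, or proxy lookup.
* The weighted-median bootstrap resamples summary statistics parametrically;
  it does not propagate harmonization decisions.
* Egger's orientation convention is unreliable when instruments are weak
  (see above); diagnose with the per-SNP F before trusting the intercept.
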