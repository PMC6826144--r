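---
title: "Methods: Mendelian randomization of telomere length against aging outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of telomere length against aging outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomr)
```

## The problem and the model

Leukocyte telomere length (LTL) shortens with age (~25 bp/year in adults) and
has a strong inherited component. A panel of common variants in and around
telomere-maintenance genes (*TERC*, *TERT*, *NAF1*, *OBFC1*, *RTEL1*, ...)
jointly explains about 2.23% of LTL variance, enough to use genetically
predicted telomere length as an instrumental variable: if the variants satisfy
the instrumental-variable assumptions (associated with LTL, independent of
confounders, no pathway to the outcome except through LTL), the regression of
per-allele SNP–outcome effects on per-allele SNP–exposure effects estimates
the causal effect of LTL on the outcome.

With summary statistics $\hat\gamma_j$ (SD of LTL per effect allele, SE
$\sigma_{x,j}$) and $\hat\Gamma_j$ (log odds or SD of outcome per allele, SE
$\sigma_{y,j}$) for $J$ instruments with pairwise correlation matrix $\rho$
(the elementwise $\sqrt{r^2}$ of the LD matrix), the package implements three
estimators:

* **IVW (correlated instruments).** Generalized least squares through the
  origin, $\hat\theta = (\gamma^\top\Omega^{-1}\gamma)^{-1}
  \gamma^\top\Omega^{-1}\Gamma$ with
  $\Omega_{ij} = \sigma_{y,i}\sigma_{y,j}\rho_{ij}$. Under the
  random-effects model the SE is inflated by $\max(1, \sqrt{Q/(J-1)})$,
  where $Q$ is the GLS residual sum of squares; the inflation is floored at
  1 so the random-effects SE never undercuts the fixed-effect SE.
* **Likelihood-based.** The joint normal likelihood of
  $(\hat\gamma, \hat\Gamma)$ with means $(\xi, \theta\xi)$, within-block
  covariance built from the SEs and $\rho$, and zero cross-block covariance
  (two-sample setting; the overlap correlation is an argument but only 0 is
  supported). The slope is profiled — given $\theta$ the latent
  $\xi$ solve a linear system — optimized by BFGS from the IVW start and
  polished to a $10^{-13}$ fixed point of the exact score updates; the SE
  comes from the full $(J+1)$-dimensional observed information.
* **MR-Egger.** The same GLS regression with a free intercept, instruments
  oriented so every effect allele lengthens telomeres. The intercept
  estimates average directional pleiotropy and is tested against zero; the
  slope remains consistent under the InSIDE assumption. Random-effects
  inflation uses a $J-2$ denominator.

A single instrument degenerates to the Wald ratio $\hat\Gamma/\hat\gamma$
with a two-term delta-method SE.

Estimates are natively per 1 SD of LTL (~650 bp) and are reported per 250 bp
(~one decade of adult attrition) by multiplying log-scale effects by
$250/650$, equivalently exponentiating odds ratios: OR 1.2/SD is OR 1.07
per 250 bp. Confidence intervals are rescaled by the same deterministic
transform, not recomputed.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bp_per_sd` | 650 | bp | one SD of LTL in base pairs |
| `bp_per_year` | 25 | bp/year | adult attrition rate; 650 bp = 26 years |
| `target_r2` | 0.0223 | fraction | LTL variance explained by the panel |
| power OR | 1.2 / SD | odds ratio | detectable effect for binary outcomes |
| power beta | 0.1 / SD | SD | detectable effect for continuous outcomes |
| power alpha | 0.01 | — | significance level (multiple-testing allowance) |
| `fdr_alpha` | 0.05 | — | highlighting threshold on BH-adjusted p |
| low-power threshold | 0.80 | — | strict `<` flag |

## Power conventions

Analytic power uses the normal (non-centrality) approximation:
$\Phi(\sqrt{nR^2K(1-K)}\,|\ln \text{OR}| - z)$ for binary outcomes and
$\Phi(\sqrt{nR^2}\,|\beta| - z)$ for continuous ones. Calibrating against the
published power column fixes the critical value at the *one-sided*
$z_{1-\alpha}$ for binary rows and the *two-sided* $z_{1-\alpha/2}$ for
continuous rows; both conventions sit behind the `sided` argument and the
calibrated pair is the default. The asymmetry is a property of the upstream
web calculator, not of the statistics. One borderline row (breast cancer,
n = 139,940, 10,184 cases) computes to 0.6253 and therefore prints 0.63 at
two decimals where the source table prints 0.62; a handful of very-low-power
rows are known not to reproduce under any convention and are excluded from
hard assertions.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates the statistical structure the analysis
assumes, not a real population:

* **Genotypes.** Gaussian-copula haplotypes: two latent MVN draws
  thresholded at the allele-frequency quantile and summed, so each SNP is in
  Hardy–Weinberg equilibrium. Latent correlations are calibrated by
  root-finding on the bivariate-normal orthant probability so realized
  *dosage* correlations match the target $r$ (plain thresholding attenuates
  them); targets unattainable at the given allele frequencies are capped
  with a warning. This matters: the estimators are fed $\rho$, so the
  generator must realize it.
* **Exposure.** LTL in SD units = allele score scaled to explain exactly
  `target_r2` of variance plus Gaussian noise to unit total variance. With
  synthetic panel betas this exact rescaling is the only way to pin 2.23%.
* **Outcomes.** Binary: logistic model in LTL (+ optional per-SNP direct
  effects for pleiotropy studies, + optional confounder), intercept solved
  by root-finding so the marginal prevalence matches the target to 1e-6.
  Continuous: the same linear predictor plus noise to unit variance.
* **Parental ages.** Normal ages at death (father 72.22 ± 11.05, mother
  77.37 ± 9.83 years, the published summary), truncated at 20, optional
  premature-death mixture and survivorship fraction (default 25% alive, a
  realistic figure for a 40–70 cohort).
* **Raw phenotype fields.** 49 Bernoulli deficit items with age-dependent
  rates (expected counts ~6.3 at 60+, ~1.7 below, matching the published
  means), sex-specific normal grip and muscle-mass index bracketing the
  EWGSOP cutoffs, log-normal reaction times centred near 556 ms, Poisson
  visual-memory errors, and survey responses drawn at roughly the published
  prevalences. The source study gives no distributional detail for these
  fields; the choices are calibration conveniences, not claims about the
  source cohort.

Not emulated: realistic genome-wide LD, imputation uncertainty, relatedness,
healthy-volunteer ascertainment, follow-up censoring. A green full-chain test
therefore establishes parameter recovery and calibration *under the assumed
model*, not robustness to those features.

## Numerical choices

* Non-PSD $\sqrt{r^2}$ matrices (and GLS weight matrices) are repaired by
  clipping eigenvalues at 1e-8 and rescaling to unit diagonal, with a
  warning.
* Logistic fits are plain ML via IRLS (1e-8 tolerance on the log-likelihood,
  50 iterations, observed-information SEs); perfect separation flags the
  result non-converged. Firth correction is not used — the source analysis
  does not state it and case counts here are large.
* The early-death cutoff estimates the modal age at death from a Gaussian
  KDE (Silverman bandwidth, 0.1-year grid) and a half-normal SD from ages
  above the mode. A plain Gaussian-ML variant (`cutoff_method`) exists
  because a full-sample normal fit is what the source text literally says,
  but its mean − SD is inconsistent with the cutoffs it reports (57/46);
  the mode-based variant is skew-robust and is the default.
* Boundary behaviour is strict where the definitions say "below"/"<"
  (grip < 30/20 kg, SMI < 8.87/6.42 kg/m², power < 0.80) and inclusive at
  "≥" (parental age thresholds 87/90/96/100, Fried ≥ 3 criteria).
* z-scoring of continuous outcomes happens within the stratum analysis
  sample, after exclusions, immediately before association fitting.
* Fried's 20% grip/activity cuts use type-7 quantiles by sex within the
  analyzed sample.
* All randomness flows from one master seed; stages derive independent
  streams via fixed offsets (`stage_seed`), so stages are independently
  re-runnable and whole runs byte-reproducible.

## Open design decisions taken

* **FDR family.** The source highlights FDR-adjusted p < 5% without stating
  which method's p-values enter; the likelihood-based method is the headline
  estimator, so its p-values within the 60+ stratum form the default family
  (`fdr_method`, `fdr_stratum` configurable).
* **Panel fixture.** The per-SNP instrument weights are not printed in the
  main text; the shipped file `panel_synthetic.tsv` is explicitly synthetic
  — real rsIDs and loci from the telomere-GWAS literature, placeholder
  betas/frequencies scaled so the uncorrelated variance explained is 2.23%,
  one mildly correlated pair (r² = 0.16) to exercise the correlated path.
* **Slow walking pace** is coded from the categorical self-report; the
  "3 miles per hour" phrasing is noted as ambiguous and not used.
* **Config dialect** is JSON (`jsonlite`), the only hierarchical text
  format available in the supported environment.

## Known limitations

Logistic non-collapsibility attenuates marginal per-allele log-odds by a
factor $\approx (1 + \theta^2\sigma^2/1.7^2)^{-1/2}$; at the effect sizes
studied this is ≪ 1% and invisible at test tolerances. One-sample bias is
avoided in the validation studies by simulating separate exposure and
outcome cohorts; the pipeline itself estimates both from one cohort, which
is the usual biobank compromise. The likelihood-based SE assumes the
information matrix is well-conditioned; near-perfect LD should be pruned
first (`prune_perfect_ld`).
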