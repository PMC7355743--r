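---
title: "Methods: polygenic risk scoring for childhood obesity cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scoring for childhood obesity cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedigrs)
library(dplyr)
```

## The score

`pedigrs` analyses a weighted polygenic risk score (pGRS) for body-mass-index
in children. Given a panel of biallelic SNPs with a designated risk allele
and a per-allele weight $\beta_i$ (typically the effect estimate from a large
adult-BMI GWAS meta-analysis), each child's score is the raw weighted sum

$$\mathrm{pGRS}_j = \sum_i \beta_i \, d_{ji},$$

where $d_{ji} \in \{0, 1, 2\}$ counts the risk alleles the child carries at
SNP $i$ (fractional after imputation). The sum is deliberately not divided by
the number of SNPs or the sum of weights: with 40--60 SNPs and GWAS-scale
weights the score lands around 1.2 with a standard deviation near 0.15,
which is the scale on which published per-unit and per-0.1-unit effects are
reported.

Risk-allele orientation comes solely from the weights table. No strand
flipping or ambiguous-allele resolution is attempted; a genotype call whose
alleles do not match the panel's pair is a hard error naming the SNP and
individual, because silently flipped alleles corrupt scores in ways that are
very difficult to detect downstream.

## Genotype quality control

Variants are dropped for a call rate below 95% or for deviation from
Hardy-Weinberg equilibrium (HWE), call rate checked first. The HWE test is
the exact conditional test: given the observed allele counts, the
probability of every attainable heterozygote count is evaluated through the
standard recurrence, and the p-value sums all configurations no more
probable than the observed one. The exact test was chosen over the
chi-square approximation because QC operates at exactly the small genotype
counts where the approximation fails; the two agree closely in large
balanced samples (verified in the test suite). Ties in "no more probable"
are resolved by `<=` with a relative tolerance of 1e-12.

The HWE alpha defaults to `1e-3` in `qc_filter()` and is recorded in the QC
report's attributes. Per-individual call rate is reported informationally
but never drops anyone; QC uses all individuals, not a control subset, and
the report says so by construction (every input SNP appears exactly once
with its status).

Missing calls that survive QC are imputed as twice the observed risk-allele
frequency of the variant (the observed column mean), so column means are
preserved and the per-individual imputed fraction is attached to the result.
Children, not variants, are never dropped for missingness.

## Association and prediction

Continuous outcomes use ordinary least squares with the score as exposure;
the exposure's contribution is summarised as the partial R^2 (full-model R^2
minus the R^2 without the exposure). Binary obesity outcomes use
maximum-likelihood logistic regression; both the deviance-based D^2 and
Nagelkerke pseudo-R^2 are emitted, because published work sometimes labels
such a quantity "h^2" without defining it, and emitting both keeps the
ambiguity visible instead of hidden. The per-0.1-unit odds ratio is computed
as $\exp(0.1\hat\beta)$ — the standard transform. Some published narratives
instead divide the per-unit OR by 10; the two differ substantially for large
effects, which is why the function documents the exact formula it uses.

Quantile strata use the linear-interpolation sample quantile convention
(R type 7) with ties assigned to the lower stratum; both choices are
recorded in the result's attributes. Confidence intervals are Wald-type: on
the t distribution for linear models, on the normal for logistic, and
exponentiated for odds ratios.

Predictive ability follows the split-sample design: a stratified 75/25
train/test split (stratification keeps small test sets usable and is
recorded in the output), a logistic model per risk-factor set fitted on
training rows, and the AUC of its predicted risks measured on test rows with
a DeLong 95% interval (via pROC, the implementation the field uses).
Complete cases are taken per factor set, mirroring published predictor
tables whose n varies by row, and single-factor models reaching a test AUC
of 0.60 are combined into one model on the complete-case intersection with a
fresh seeded split. Separation in a training fit is tolerated here — the
predictions are only used to rank test individuals — whereas the same
condition is a hard error in `fit_logistic()`, where the Wald machinery
would be meaningless. Cohorts still containing the overweight middle class
are refused so the case/control framing is never silently diluted.

## The interaction scan

For each quantitative or ordinal lifestyle factor $E$ the scan fits

$$\mathrm{BMI\,Z} = \beta_0 + \beta_1\,\mathrm{pGRS} + \beta_2 E +
  \beta_3\,(\mathrm{pGRS} \times E) + \beta_4\,\mathrm{Origin} +
  \beta_5\,\mathrm{Tanner} + \varepsilon$$

and tests $\beta_3$ with the two-sided marginal t-test (asymptotically the
likelihood-ratio test for this one-degree-of-freedom comparison; the suite
checks $t^2$ against the LR statistic). Variables enter uncentred by
default — the literal model — with a `center` flag for ill-conditioned
factors; centring provably leaves $\beta_3$ unchanged and the suite checks
that to 1e-8. Ordinal questionnaire items enter as numeric codes. The
Benjamini-Hochberg adjustment spans the whole scan as a single family,
never per-category subfamilies, and complete cases are taken per factor with
n recorded per row. For interaction plots, children are banded at the score
mean plus/minus one standard deviation and the outcome-on-factor slope is
fitted within each band.

## Longitudinal trajectories

Insulin resistance is classified from HOMA-IR with inclusive cut-offs: 2.5
at Tanner I, and 3.38 (boys) / 3.90 (girls) at Tanner II-V. Weight status
uses an age- and sex-specific BMI cut-off table supplied as data (nearest
half-year row; the obesity class is inclusive at its cut-off). Trajectory
groups are assigned from explicit, exported mapping tables
(`trajectory_mapping()`): scheme 1 maps joint (weight, IR) transitions onto
five groups — stable normal-weight non-IR children as reference, and
overweight/obese children split by never-IR, resolved, incident and
persistent IR; scheme 2 maps weight-only transitions and is total.
Transitions outside the scheme-1 design (for example a normal-weight child
with IR) raise an explicit "unclassifiable" error rather than being silently
binned, because the five-group design genuinely does not cover them and any
silent choice would be invisible in downstream odds ratios.

Trajectory odds ratios dichotomise the score at the third tertile (top vs
bottom two) and fit one logistic model per comparison group against the
reference group, BH-adjusted across groups. Deltas between timepoints carry
their direction as an attribute because both conventions appear in practice:
T1 − T0 for cardio-metabolic changes, T0 − T1 (positive = reduction) for
treatment response.

## The trial analysis

Two parallel analyses of the placebo/metformin trial: (1) OLS of the BMI Z
reduction (T0 − T1) on score, arm, and score-by-arm; (2) a linear
mixed-effects model on the long table with a random intercept per child,
all two-way products and the three-way score-by-time-by-arm term, tested by
Wald t with Satterthwaite degrees of freedom (lme4/lmerTest; the contract
fixed here is the model structure and the tested term, not the optimiser).
With balanced complete two-timepoint data the three-way fixed effect equals
the delta-regression interaction up to the sign implied by the opposite time
direction — the module's central correctness check, asserted to 1e-6.

## The synthetic-cohort generator

No individual-level cohort data are deposited for studies of this design, so
every stage is exercised on synthetic cohorts with known ground truth. The
generator's defaults describe the study conditions the package targets:

* **Panel**: 56 candidate SNPs, risk-allele frequencies uniform on
  [0.1, 0.5], per-allele weights uniform on `beta_scale * [1/3, 5/3]` with
  `beta_scale = 0.045`, the GWAS-BMI scale that makes the resulting score
  mean ≈ 1.2 and SD ≈ 0.15.
* **Genotypes**: multinomial draws from exact HWE proportions
  (p^2, 2pq, q^2) — chosen over allele-wise sampling for its simpler
  invariants. Eight designated variants receive a fixed 10% missingness
  (deterministically below the 95% call-rate bar); four are drawn with an
  excess-homozygosity distortion (inbreeding coefficient F > 0) whose
  magnitude is solved from the noncentral chi-square power relation
  `ncp = n F^2` so the exact test rejects with probability at least
  `hwe_reject_prob`. That target defaults to 1 − 1e-6 rather than a looser
  value because the engineered fixture is meant to yield its failure count
  deterministically; an n too small for the required F is an explicit error
  naming the minimum n. Clean variants are guaranteed to pass the exact test
  at the configured fixture alpha (a null draw is repeated on the rare
  chance rejection), so "engineered failures" and "QC drops" coincide by
  construction; the conditioning distorts the null distribution only at
  order alpha. The fixture alpha defaults to 1e-4 — a decade below the
  filter default — so that chance rejections among ~50 clean variants are
  expected well under once per fixture.
* **Phenotype**: BMI Z is the standardised true score signal scaled so its
  variance share equals `h2_target` (default 0.05, the mid-single-digit
  percentage typical of adult-BMI scores applied to children), plus
  sex/Tanner/origin effects worth `cov_var = 0.10` of the variance, plus
  Gaussian noise; the realised share and the implied true slope are recorded
  in the ground truth, not assumed. Weight status is labelled from
  configurable BMI Z cut-offs (defaults 1.04 and 1.64, approximately the
  85th and 97.5th centiles).
* **Environment**: 47 questionnaire-style factors (ordinal codes 0-4 by
  default; a continuous generator is available since published
  questionnaires rarely state their scale). A factor with a configured
  nonzero coefficient modifies BMI Z by exactly
  `coefficient x score x factor`; all others are pure noise.
* **Trajectories**: five groups with default sizes (20, 20, 20, 20, 16) —
  96 children — drawn on the correct side of every weight and IR cut-off for
  their group; optional top-tertile score enrichment with a configured odds
  multiplier in the persistent-IR group.
* **Trial**: 59 placebo / 65 treated children, a per-child random intercept
  (SD 0.5) inducing within-child correlation, and configurable treatment and
  score-by-treatment effects on the T0 − T1 response.

One RNG stream per sub-simulation is derived from the master seed by fixed
offsets, so enlarging the panel does not perturb phenotype draws, and
identical configurations reproduce byte-identical outputs.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (variants are independent, as an additive score assumes), the true
covariance of multi-analyte biomarker panels, measurement error in
questionnaire answers, and real BMI-reference growth curves. Passing tests
therefore demonstrate that the statistical machinery is correct under the
stated generating model, not that any particular real cohort's coefficients
will be reproduced — published real-cohort values (effect sizes near B ≈
1.6 per score unit, split-sample AUCs near 0.8, trajectory odds ratios in
the tens) are not recoverable without the undeposited data, and the package
makes no such claim.

## Numerical choices

* Lilliefors-type normality check: the KS statistic against a normal with
  estimated mean/SD, p-value by seeded Monte Carlo (default 10,000
  replicates) rather than table lookup, so it is reproducible and the
  replicate count is a visible parameter.
* The exact-test tie tolerance (1e-12 relative), the BH step-up formula with
  a one-ulp guard so adjusted values are never below raw ones, AUC tie
  handling (half credit, the Mann-Whitney convention), and the stratified
  split's per-class rounding are all asserted against independent oracles in
  the test suite: full enumeration for the exact test (all totals ≤ 30),
  exhaustive pair counting for the AUC (n ≤ 50), a multiply-accumulate loop
  for the score, closed-form 2x2 odds ratios with Woolf standard errors, and
  the balanced-data mixed-model/delta-regression identity.
* Monte-Carlo problem sizes in the suite (for example 200-seed coverage at
  n = 400, 2000-replicate size checks at n = 100) were chosen as the
  smallest sizes at which the binomial error of the check is comfortably
  inside the asserted band.

## Known limitations

* Only biallelic SNPs; no PLINK bed/bim/fam input; no reference-panel
  imputation or LD pruning.
* The descriptive-statistics battery around such studies (normality tests,
  ANOVA/Kruskal-Wallis, post-hoc comparisons) is deliberately out of scope —
  base R provides it directly.
* Scheme-1 trajectory groups cover the five-group pubertal design only;
  other designs need their own mapping table (the error messages list any
  uncovered transition).
* The mixed model supports a random intercept per child, which is what a
  two-timepoint design identifies; random slopes are out of scope.
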