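---
title: "Methods: drug-target Mendelian randomization of blood pressure on frailty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target Mendelian randomization of blood pressure on frailty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the design

Observational associations between antihypertensive medication use and
frailty are vulnerable to confounding by indication and to reverse
causality: frail people are medicated differently, and frailty itself
changes blood pressure (BP). Drug-target Mendelian randomization sidesteps
both by using common genetic variants in or near the genes encoding a drug
class's pharmacological targets — for example *ACE* for ACE inhibitors, or
*ADRB1*/*KCNH2* for beta-blockers — as lifelong, randomly allocated proxies
for pharmacological modulation of that target. The package implements the
two complementary arms of such an analysis:

1. **Individual-level, one-sample MR** by two-stage predictor substitution
   (2SPS): a per-person genetic risk score (GRS) built from BP-associated
   variants in the target-gene regions instruments measured BP, and a
   multinomial logistic second stage relates genetically predicted BP to a
   three-level frailty state (non-frail / pre-frail / frail) derived from a
   deficit-accumulation frailty index (FI).
2. **Summary-level SMR**: for each target gene, the ratio of the top
   cis-eQTL's effect on the outcome to its effect on gene expression
   estimates the effect of expression on the FI, with the HEIDI
   heterogeneity test distinguishing a single shared causal variant from
   linkage of distinct variants.

Because the cohort data used in such analyses are access-restricted, the
package ships a seeded synthetic-data module that generates every input
with the statistical structure the estimators assume. All package-level
claims (calibration, parameter recovery, oracle equivalences) are made on
those synthetic study conditions, and the tests and `scripts/acceptance.R`
recompute them from scratch.

# The frailty index

The FI of a person is the number of health deficits present divided by the
number of deficit items with a non-missing answer, a ratio in [0, 1]. The
default synthetic item count is 49. Clinical categories follow the
validated cutoffs: non-frail below 0.12, pre-frail from 0.12 to 0.24
(closed interval — both boundary values fall in the middle band), frail
above 0.24. Two sensitivity variants are built in:

* a **modified FI** excluding a configurable cardiometabolic item subset
  (8 items by default, labelled `deficit_cm_*` by the generator — synthetic
  stand-ins, since the published item list is not reproduced here); and
* a **missing-data rule** excluding persons with 10 or more missing items
  (`max_missing = 10`).

The main-analysis denominator is items *answered*, not total items, the
standard deficit-accumulation convention; the missingness cap bounds how
far the two can diverge.

# Instrument selection and the genetic risk score

Candidate instruments per drug class are GWAS SNPs lying within ±100 kb of
a target gene (inclusive), associated with the BP exposure at p < 5×10⁻⁸
(strict) and common (minor allele frequency strictly above 1%). Candidates
are then greedily LD-clumped: ranked by association p-value (ties by
position, then id), each SNP is kept only if its squared correlation with
every already-kept SNP is below the threshold — r² < 0.4 within drug-gene
regions (a deliberately lenient bound that raises explained variance),
0.1/0.01 as sensitivity settings, and 0.001 for the pooled genome-wide
instrument. The greedy output is provably the lexicographically first
maximal admissible subset in p-order; the test suite checks it against an
exhaustive enumeration oracle on 12-SNP windows.

Weights are oriented so every effect allele raises BP (labels swapped,
dosages complemented as 2 − g, zero-beta SNPs dropped); the weighted score
is

$$\mathrm{GRS} = \left(\sum_i \beta_i \, g_i\right) \times \frac{n}{\sum_i \beta_i},$$

i.e. n times the β-weighted mean dosage, which keeps the score on an
allele-count scale; an unweighted score (plain allele count) probes
sensitivity to weighting. The first-stage F statistic uses the
single-instrument form F = (r²/1)/((1 − r²)/(n − 2)); published
covariate-adjusted F values from real cohorts are not recomputable from
that closed form and are not treated as targets.

# Two-stage predictor substitution

Observed BP is the mean of the available automated readings (two for most
people, one for a few percent), plus 15 mmHg systolic / 10 mmHg diastolic
for people on antihypertensive medication — the conventional correction
for treatment masking. In the generator, medication *subtracts* exactly
15/10 from observed BP, so the correction inverts it exactly and the
adjustment code path is testable against ground truth.

Stage one regresses adjusted BP on the GRS plus covariates (age, sex,
assessment center, smoking, alcohol, BMI, deprivation, genotyping array,
ten genetic principal components; categorical covariates are
treatment-coded). Stage two fits a multinomial logit of the frailty
category (reference: non-frail) on the stage-one fitted values with the
same covariates — predictor substitution, per the method's name, rather
than residual inclusion. Coefficients are reported as relative risk ratios
(RRR) per 10 mmHg systolic / 5 mmHg diastolic *decrease*
(RRR = exp(−unit·coef)), the scale of antihypertensive trials. Two
exposures give a Bonferroni significance bound of 0.025, with (0.025,
0.05) flagged suggestive. Subgroup (age ≥ 60) and modified-FI switches
reproduce the sensitivity analyses. BMI enters continuously (a categorical
switch is possible via the covariate list); "predicted probability" from a
linear first stage is read as fitted values.

Numerical choices: the multinomial fit uses `nnet::multinom` with tight
convergence settings, followed by analytic Newton polishing until the
maximum score component is below 1e-8 — after which a two-category
collapse agrees with `glm`'s logistic solution to well under 1e-6 — and
standard errors come from the analytic observed information (equal to the
expected information for the canonical logit). All numeric predictors are
centred before the fit: slopes and their standard errors are unchanged,
but mmHg-scale predictors otherwise leave the information matrix so badly
conditioned that `nnet`'s numeric Hessian returns unusable standard
errors. Stage-two standard errors are naive Wald errors that ignore
first-stage estimation uncertainty, the common 2SPS convention; with
first-stage F in the hundreds the correction is negligible, but it is a
documented limitation.

# The synthetic cohort

Genotypes are drawn per LD block from a latent AR-1 Gaussian field
(lag-one correlation ρ per block) thresholded at each SNP's Hardy-Weinberg
genotype-frequency quantiles — the minimal model with tunable r² for
clumping tests. The default genome is seven 8-SNP blocks, one per mapped
target gene, with the ARB block carrying no BP effect so that a drug class
with "no proxy available" flows through every stage. True systolic BP is
additive: intercept 135 mmHg, per-allele effects of 0.55–0.9 mmHg on
roughly half the SNPs (sized so the score explains a few percent of BP
variance, as for real BP scores), covariate effects, a standard-normal
confounder U (3 mmHg/SD), and Gaussian noise (SD 16 mmHg); diastolic
effects are 0.55× systolic. An external GWAS is emulated by propagating
the joint effects through the within-block dosage covariance (blocks are
independent by construction, so cross-block covariance is exactly zero)
and adding sampling noise at the standard error implied by N = 750,000.

Deficits follow a liability model: item j is present when
a_j + θ·(SBP − mean) + c·U + h_i + e_ij > 0, with e_ij independent
standard normal, baseline prevalences spread over 1–18%, and h_i a
person-level shared liability term (SD 0.45) added for a realistic frail
tail — items remain conditionally independent given the liability terms.
Default θ = 0.015 liability-SD per mmHg and c = 0.25. Missingness is
person-correlated: most people miss ~1% of items, a 3% subgroup misses
~25%, so the ≥10-missing exclusion rule has real cases to act on.

What the generator does **not** emulate: population structure and
relatedness, imputation uncertainty, X-chromosome variants, item-level
semantics of real deficits, and realistic covariate–BP confounding
structure. Passing tests on this cohort demonstrate the estimators'
statistical properties under their assumptions, not robustness to those
real-data complications.

## Calibration configuration

Mapping θ to a ground-truth RRR has no closed form under the 49-item
liability model, so for estimator calibration the generator offers
`outcome_model = "multinomial"`: the frailty category is drawn directly
from a multinomial logit on structural (long-term) BP with a known
per-mmHg log-RRR applied to both contrasts (intercepts log 0.497 and
log 0.051, mirroring a 64/32/4% split). The calibration configuration
(`mr_calibration_config()`) uses three 8-SNP signal blocks, no covariate
pathway to BP, and moderate confounding (2.5 mmHg/SD on BP, 0.1
liability/SD on the outcome) — chosen a priori so the non-collapsibility
attenuation of the marginalized logit stays an order of magnitude below
Monte-Carlo resolution while the naive comparator remains visibly biased.
Reference problem sizes: cohorts of n = 20,000; 1,000 replicates for the
size of the 2SPS Wald test (300 of them also fitting the naive model);
200 replicates for recovery of a true RRR of 0.80 per 10 mmHg
(θ = log(1/0.8)/10 per mmHg).

# SMR and HEIDI

For each gene, the top cis-eQTL is the smallest-p SNP within 1 Mb of the
gene with p < 5×10⁻⁸ (ties: larger |z|, then smaller position). The SMR
estimate is b_xy = b_zy/b_zx with test statistic
T = z_zx²·z_zy²/(z_zx² + z_zy²) on one chi-square degree of freedom; the
Bonferroni bound over 15 genes is reported as 0.05/15 rounded to one
significant digit, 0.003.

HEIDI asks whether the per-SNP ratio b_zy/b_zx is constant across
LD-linked cis SNPs. The SNP set excludes weak eQTL proxies
(p_eQTL > 1.6×10⁻³), near-perfect proxies of the top SNP (r² > 0.9, which
carry no independent information), caps the set at the 20 smallest-p SNPs,
and requires at least 3 (otherwise the test is not computed). An optional
lower LD bound (r² < some minimum, excluding near-independent SNPs) is
exposed but off by default, as its use in the source analyses is not
stated.

`heidi_test()` implements the classical analytic route: differences
d_i = b_xy(i) − b_xy(top), first-order delta-method covariance with zero
cross-study covariance (independent eQTL and GWAS samples),

$$\mathrm{Cov}(b_{xy,i}, b_{xy,j}) = r_{ij}\left[\frac{se_{zy,i}\,se_{zy,j}}{b_{zx,i}\,b_{zx,j}} + \frac{b_{zy,i}\,b_{zy,j}\,se_{zx,i}\,se_{zx,j}}{b_{zx,i}^2\,b_{zx,j}^2}\right],$$

standardized to z_d with T = Σ z_d², and a p-value from the null of a sum
of correlated squared standard normals by seeded Monte-Carlo (default 10⁵
draws) with a Satterthwaite moment-matched scaled chi-square as an
analytic cross-check (the two agree within a factor of two through the
decision region).

**Design choice — the default HEIDI null.** Validating that analytic route
against a Monte-Carlo oracle during development showed it is markedly
anti-conservative in windows that admit marginal-strength eQTLs: at the
admission bound p_eQTL ≤ 1.6×10⁻³ a SNP's eQTL z can be as low as 3.2,
where the ratio estimate is over-dispersed relative to its delta-method
standard deviation, and the selection of the top SNP and of the HEIDI set
from the same data conditions the null distribution further. `run_smr()`
therefore evaluates the HEIDI null by default with a
**selection-replicating parametric bootstrap** (`heidi_bootstrap()`):
under the plug-in single-causal-variant null (true eQTL effects = observed
b_zx; true outcome effects = observed top ratio × b_zx), every draw
regenerates the full window with the study-design LD covariance, redoes
top-SNP selection and all exclusions, and recomputes the statistic. The
analytic p-values are reported alongside (`p_heidi_delta`,
`p_heidi_satt`). The bootstrap default is 2,000 draws (Monte-Carlo
standard error ≈ 0.002 at the p = 0.01 decision boundary); the large
calibration suites use 1,500 draws per gene, 2,000 null genes and 500
linkage genes as their reference problem sizes.

The synthetic summary-level scenarios draw estimates from a multivariate
normal with covariance D·R·D (R the AR-1 LD matrix, D the standard
errors): `causal` (one variant, effect on outcome only through
expression), `pleiotropy` (same variant, separate pathways — marginally
indistinguishable from causal, which is exactly HEIDI's blind spot),
`linkage` (two variants in LD, one per trait), and `null`. Defaults: 30
SNPs, ρ = 0.8, top eQTL z = 10, outcome standard errors typical of a
six-figure GWAS.

# Degenerate inputs, ties and tolerances

* LD correlation matrices are symmetrized and eigenvalue-clipped to
  positive semidefinite (then re-normalized to unit diagonal) before any
  Cholesky factorization, with a 1e-10 ridge.
* Clumping ties (equal p) break by position then id; top-eQTL ties by |z|
  then position; all orderings are deterministic so reruns are identical.
* A drug class with zero passing SNPs produces an empty instrument set and
  a flagged report row ("no proxy available"), never an error; a zero-SNP
  score, a zero weight sum, or a zero-variance score are errors.
* Persons with no BP readings or no answered deficit items are excluded
  with counts logged; missing dosages are mean-imputed per SNP.
* Every generator output is a pure function of (configuration, seed);
  stage seeds are derived from the root seed, and Monte-Carlo routines
  restore the caller's RNG state.

# Known limitations

* Naive second-stage standard errors (no first-stage uncertainty, no
  bootstrap over the two stages).
* 2SPS with a non-linear second stage estimates a marginalized
  (population-averaged) coefficient; with strong instruments and moderate
  confounding the attenuation is far below sampling noise at the package's
  reference sizes, but it is not exactly the conditional parameter.
* The pleiotropy scenario cannot be separated from causality by HEIDI by
  construction; only linkage is detectable.
* Two-sample estimators (IVW, MR-Egger, weighted median) and non-linear MR
  are out of scope, as is reading binary eQTL storage formats.
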