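---
title: "Maternal iron status and offspring respiratory outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal iron status and offspring respiratory outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The scientific question

Observational birth-cohort studies suggest that low maternal iron status in
pregnancy may impair childhood lung function and raise the risk of atopic
outcomes, but nutritional exposures are heavily confounded by lifestyle.
Mendelian randomisation (MR) side-steps that confounding by using genetic
variants as instrumental variables: alleles are allocated at meiosis
independently of lifestyle, so a maternal genotype that predicts lower iron
status provides a quasi-randomised contrast of prenatal iron exposure.

`ironmr` implements the full analytical machinery of such a one-sample
maternal MR study: weighted genotypic risk scores for four iron biomarkers
(serum iron, ferritin, transferrin, transferrin saturation), instrument
validation, stratified score-outcome models, the summary-data MR
estimators, and a simulation study of the collider bias that stratifying on
iron supplementation can introduce.  Because the underlying individual-level
cohort data are not publicly deposited, the package ships a synthetic
cohort generator with the study's causal structure, and every downstream
stage is developed and tested against it.

## The weighted genotypic risk scores

The packaged weight table holds 12 SNPs associated at genome-wide
significance with at least one of the four iron biomarkers in a large GWA
meta-analysis.  For biomarker $b$ with selected SNPs $S_b$, the raw score of
individual $j$ is

$$\mathrm{raw}_j \;=\; \sum_{i \in S_b} |w_{ib}| \, g_{ij},$$

where $g_{ij} \in [0,2]$ is the dosage of the *risk allele* (the allele
associated with lower iron status — or higher transferrin, which marks iron
deficiency) and $w_{ib}$ is the published effect estimate in SD units of the
biomarker per risk allele.  Scores are standardised to mean 0, SD 1 over the
analysis sample, so all effects are reported per SD of score.

Two deliberate conventions:

* **Magnitude weights.**  The published effect estimates are negative for
  iron, ferritin and transferrin saturation (the risk allele lowers the
  biomarker).  Multiplying risk-allele counts by signed weights would make
  *lower* scores mean lower predicted iron status, inverting the stated
  semantics "the higher the score, the greater the risk of lower iron
  status".  We therefore weight by $|w_{ib}|$: the score is monotone
  non-decreasing in every risk-allele dosage, and the sign convention is a
  pure reflection with no effect on inference.
* **rs8177240 orientation.**  This SNP's risk allele is T for serum iron but
  G for transferrin and transferrin saturation.  Dosages are stored once, in
  a declared counted-allele orientation, and flipped ($g \mapsto 2-g$) at
  scoring time whenever the stored counted allele differs from the target
  biomarker's risk allele.

Missing dosages are mean-imputed per SNP (standard allele-score practice);
individuals missing more than 20% of a score's SNPs are dropped with a
warning.  The four scores rest on 5, 6, 9 and 5 SNPs respectively.

## The synthetic cohort generator

The generator realises the study's causal diagram as a seeded pure function
of a configuration object:

1. Maternal genotypes at the 12 loci are drawn under Hardy-Weinberg
   equilibrium, independently across loci (the real variants show pairwise
   $r^2 < 0.10$, which we idealise to independence — linkage disequilibrium
   is deliberately out of scope).
2. Latent maternal iron status (SD units) loads negatively on the
   standardised iron score: $\mathrm{iron} = -\sqrt{h^2}\,z +
   \sqrt{1-h^2}\,\varepsilon$.
3. Late-pregnancy iron supplementation is Bernoulli with log-odds
   $\mathrm{logit}(p_0) - \gamma\,\mathrm{iron} + c_s U$, where $U$ is a
   single unmeasured standard-Normal confounder — the minimal structure that
   makes stratification on supplementation a collider problem.
4. Supplementation restores a fraction `supp_restore` of any iron
   *deficit* (`iron + supp_restore * max(0, -iron)`), mirroring clinical
   indication; haemoglobin in late pregnancy tracks the restored value,
   haemoglobin in early pregnancy the unrestored one (early measurements
   predate most supplementation).
5. Continuous offspring outcomes (FEV~1~, FVC, FEF~25-75~) are
   $\beta\,\mathrm{iron} + c_o U + \varepsilon$, re-standardised to emulate
   age/height/gender-adjusted SD units; asthma and atopy are logistic with
   configured baseline prevalences; log IgE is Normal; the ten
   principal-component covariates are pure noise (population substructure
   itself is not simulated, only the adjustment-set plumbing).
6. Child genotypes receive one allele drawn uniformly from the mother's two
   plus a paternal Bernoulli(maf) allele, giving the kinship mother-child
   dosage correlation of 0.5.

Key defaults, chosen once to mirror the study conditions: 6,002
mother-child pairs; late-supplementation base rate 0.424 (2,248 of 5,303
mothers supplemented); $h^2 = 0.03$ and haemoglobin loading 0.6 g/dL per SD,
so the score-haemoglobin slope is near $-0.6\sqrt{0.03} \approx -0.1$ g/dL
per SD of score, the magnitude the proxy-validation analysis reports;
`supp_restore = 0.7`; confounder arms $c_s = c_o = 0.5$; risk-allele
frequencies in the plausible European range for each locus.  The exact
parameters of the original supplementary simulation are unpublished, so
these are declared defaults, not a reproduction; every one is overridable
through `cohort_config()`.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: linkage disequilibrium, genotyping/imputation
error, population substructure correlated with outcomes, missing data
mechanisms, measurement error in haemoglobin timing, and any pleiotropic
path from the SNPs to the outcomes other than through iron.

## Association models

* Continuous outcomes: OLS with Wald (t) intervals.
* Binary outcomes: maximum-likelihood logistic regression, odds ratios with
  Wald intervals; complete separation is detected and raised as an error.
* Total IgE: linear regression of $\log(\mathrm{IgE})$ reporting geometric
  mean ratios $e^\beta$, with heteroscedasticity-robust (Huber-White HC1)
  variances — HC1 matching the `robust` variance of the Stata software used
  in the source analysis.
* Per-allele models enter each SNP's risk-allele dosage as a linear term
  ("p trend").
* The battery runs overall (adjusted for the 10 PCs plus early and late
  supplementation) and within late-supplementation strata (PCs only).
  Strata with fewer than 10 records are skipped with a warning.  Analyses
  are complete-case per outcome; tests are two-sided at 0.05 with no
  multiple-testing correction, matching the source analysis's explicit
  choice.

## Summary-data MR estimators

With harmonised per-SNP summary data $(\hat\beta_{Xj}, \hat\beta_{Yj},
\mathrm{se}_{Yj})$ and first-order weights $w_j = 1/\mathrm{se}_{Yj}^2$:

* **IVW**: weighted regression through the origin,
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, $\mathrm{se} = (\sum w_j \hat\beta_{Xj}^2)^{-1/2}$.
* **MR-Egger**: the same regression with an unconstrained intercept
  (average directional pleiotropy under InSIDE); exposure betas are
  oriented non-negative first.  Constraining the intercept to zero
  reproduces IVW exactly, an identity the test suite asserts.
* **Weighted median**: ratio estimates $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
  sorted ascending with normalised weights $w_j =
  \hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$; the estimate interpolates $r$ at
  cumulative standardised weight 0.5 under the midpoint convention
  $s_j = \sum_{k\le j} w_k - w_j/2$; the standard error comes from a seeded
  fitted-model parametric bootstrap (2,000 draws of
  $\hat\beta_Y^* \sim N(\hat\theta\,\hat\beta_X, \mathrm{se}_Y)$).  Because
  the weighted median is location-equivariant in the ratio estimates, the
  fitted-model bootstrap reproduces its sampling law exactly under the
  estimator's own all-instruments-valid model, and its z-test calibrates at
  the nominal level; centring the draws on the raw observed outcome betas
  instead overstates the dispersion (dispersed ratio configurations inflate
  a median's variance), which we measured as a ~12% upward SE bias and a
  test size near 3%.  Under pleiotropy the fitted-model SE can be
  optimistic; the Egger intercept is the companion diagnostic.  The
  interpolation convention and bootstrap settings are declared defaults —
  the source analysis does not state its own.

Numerical choices worth flagging: IVW and Egger treat the outcome variances
as known (covariance $(X'WX)^{-1}$ with no residual rescaling and normal
quantiles), which makes their null tests exactly nominal in the calibration
suites; the residual-scaling variant found in some MR software is a
heavier-tailed alternative we deliberately do not use.  Exposure-beta
uncertainty cannot be propagated because the meta-analysis publishes betas
without standard errors — a stated limitation of first-order weighting.
Estimators are invariant to joint per-SNP sign flips; zero exposure betas
are rejected where a ratio would be undefined; Egger requires at least
three SNPs and some spread in the exposure betas.

The one-sample setting uses per-SNP outcome betas from the same cohort as
the scores, without cross-fitting, exactly as the substantive analysis did.

## The collider simulation

Mothers supplement *because* they are iron deficient, so supplementation is
a common effect of iron status and of anything else (the confounder $U$)
that drives supplementation; stratifying on it can manufacture score-outcome
associations under the null.  `run_collider_simulation()` quantifies this:
for each $\gamma$ in a grid of iron-to-supplementation effects and each
replicate, it generates a null cohort, regresses the outcome on the
standardised score within each supplementation stratum, and records
rejections at $\alpha$.  Defaults: grid $\{0, 0.5, 1, 2, 4\}$ log-odds per
SD, 1,000 replicates of $n = 5{,}000$, $\alpha = 0.05$ — sized to finish in
minutes on one CPU; the original supplementary simulation's own settings are
unpublished.

The design has a sharp falsifiable signature, which the test suite asserts:
rejection is nominal at $\gamma = 0$; setting *either* confounder arm to
zero restores nominal error at every $\gamma$ (the collider path needs both
arms); and inflation appears only at the extreme end of the grid.  Under
the default instrument strength the inflation is modest even at
$\gamma = 4$: the score explains only $h^2 = 3\%$ of iron variance, so
selection on supplementation depends on the score only weakly and the
induced score-confounder association within strata is second-order.  That
is itself the substantive point — a weak instrument also picks up little
collider bias, so stratified null results are not easily explained away by
collider artefacts.

## Validation strategy and problem sizes

The test suite validates every layer against independent oracles and known
truths, at sizes chosen to keep the default run inside a few minutes of CPU:

* HWE LRT against a brute-force grid-search maximisation of the constrained
  likelihood (agreement to 1e-6); null calibration over 10,000 simulated
  SNPs of $n = 1{,}000$.
* Regression wrappers against hand-rolled normal-equations and IRLS
  oracles (1e-8), a four-point hand-computed slope, a closed-form 2x2 odds
  ratio, and a bootstrap check of the robust IgE variances.
* MR estimators against numerically minimised weighted SSE, weighted `lm`,
  and a stepwise-scan weighted-median oracle on randomised fixtures of 3-10
  SNPs (1e-8); null calibration over 10,000 simulated summary datasets.
* Score-outcome null calibration over 10,000 generated cohorts of
  $n = 400$; parameter recovery of a 0.1 SD/SD causal effect over 500
  cohorts of $n = 5{,}000$ by the one-sample ratio estimator (the
  recovery scenario switches the confounder's outcome arm off because the
  generator's re-standardisation of outcomes would otherwise rescale the
  target by $1/\mathrm{sd} \approx 0.89$; confounded scenarios are covered
  by the collider suite).
* Transmission: mother-child dosage correlation within 0.5 ± 0.02 at
  $n = 50{,}000$; and the child-genotype confounding check — conditional on
  the maternal score the child score is null (exactly, by construction,
  since the child's expected score is linear in the mother's), while its
  marginal association inherits half the maternal signal, which is
  precisely the overlap the child-genotype sensitivity analysis exists to
  expose.
* The haemoglobin dilution pattern: with `supp_restore > 0`, the
  score-haemoglobin slope is stronger among unsupplemented mothers in the
  majority of 200 replicates.

## Known limitations

* First-order MR weights ignore exposure-beta uncertainty (no published
  SEs to propagate).
* The generator's independence idealisations (no LD, PCs as noise) mean the
  pipeline's robustness to those real-data features is untested here.
* The weighted-median bootstrap is parametric; with very few SNPs its
  normal-quantile interval is approximate.
* Haemoglobin "early" (<18 weeks) and "late" (>28 weeks) are column
  semantics; deriving them from raw obstetric records is out of scope, as
  are genotype QC/imputation and the computation of the principal
  components.
* One discrepancy in the source weight table's footnotes: rs8177240's
  genotyped/imputed marker does not match the legend; the packaged fixture
  follows the accompanying text (five genotyped, seven imputed) and flags
  rs8177240 as imputed.
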