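---
title: "Methods: lifetime menstrual-cycle composites and reproductive genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime menstrual-cycle composites and reproductive genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclegrs)
```

# The scientific problem

Cumulative exposure of the endometrium to endogenous estrogens is a central
driver of endometrial cancer risk. Individually, early menarche, late
menopause, nulliparity and little oral-contraceptive use each extend that
exposure; `cyclegrs` analyses them jointly through two composite exposures
in a case-control design:

* a **phenotypic composite** — the total number of menstrual cycles (TNMC) a
  woman experienced during life or up to study interview, and its months
  variant (TMMC);
* a **genetic composite** — risk scores over SNPs that genome-wide studies
  have associated with age at menarche (GRS1) and age at natural menopause
  (GRS2), in the direction of greater inferred estrogen exposure.

The package provides each analysis stage as a plain function over data
frames and matrices, plus a simulator that generates complete synthetic
studies with known ground truth.

# The cycle composite

For one subject,

$$\mathrm{TMMC} = (a_{meno} - a_{men})\times 12 - m_{preg}
  - 1.5\,n_{births} - m_{bf}/2 - m_{OC}, \qquad
  \mathrm{TNMC} = \mathrm{TMMC} \times 30 / \ell,$$

with ages in years, month totals $m$, and average cycle length $\ell$ in
days. The $1.5$-month term is the assumed delay to cycle resumption after
each parturition and half the breastfeeding duration extends it; both enter
only as aggregate totals, so splitting a breastfeeding total across births
never changes the value. Premenopausal subjects substitute their attained
age (diagnosis for cases, interview for controls) for the menopause age.
Subjects with induced menopause use their recorded menopause age but are
flagged via `menopause_type` so natural-menopause-only analyses can exclude
them.

Numerical choices:

* Negative values are arithmetically possible (e.g. decades of continuous
  OC use); they are floored at 0 with a warning rather than silently
  truncated, since no floor rule is part of the formula itself.
* A missing cycle length is an error by default; `impute_cycle_length =
  TRUE` substitutes 28 days explicitly. Explicit opt-in is safer than a
  silent default in a variable that rescales the whole composite.
* The phenotype CSV writer emits doubles with 17 significant digits, so a
  record round-trips bit-exactly and re-scoring a written file reproduces
  TNMC identically.

# Genetic risk scores

Genotypes are additive counts (0/1/2) of an annotated effect allele with a
missingness mask. The pipeline applies, in order:

1. **QC** (`qc_filter`): call rate ≥ 0.90 and minor allele frequency ≥ 0.01
   computed over all subjects; Hardy–Weinberg equilibrium among controls at
   p ≥ 1e-4. The HWE test is the 1-df chi-square goodness of fit against
   $p^2, 2pq, q^2$ — the conventional genotyping-QC choice at this
   threshold, closed-form and well calibrated at study sizes in the
   hundreds (the test suite checks KS-uniformity of its p-values under the
   null). Monomorphic SNPs return p = 1 with a flag rather than an error.
   Computing MAF and call rate on everyone but HWE on controls only mirrors
   standard case-control practice (cases may deviate from equilibrium
   through true association); both populations are configurable.
2. **Selection** (`select_score_snps`): (a) greedy within-locus LD pruning
   at r² ≥ 0.5, keeping the SNP with the larger |published beta| and
   breaking ties lexicographically by id; (b) a strict failed-genotype
   bound (a SNP failing in 5 or more subjects is dropped, i.e. "fewer than
   five" survivors only); (c) the in-study linear regression of the trait
   age on the count must reproduce the published effect direction. LD is
   the squared Pearson correlation of genotype counts — a composite-LD
   surrogate for haplotype r², the best available without phase. The
   direction regression is adjusted for attained age and race, matching the
   adjustment used in the score-age models; the selection step's own model
   is otherwise a genuinely open choice.
3. **Orientation** (`orient_risk_alleles`): the risk allele is defined as
   the allele associated with younger menarche or older natural menopause.
   Counts of flipped SNPs become $2 - x$ and betas are re-expressed in
   risk-allele orientation, making orientation idempotent.
4. **Imputation** (`impute_missing`): missing counts are replaced by the
   within-stratum (case vs control) mean count, rounded to the nearest
   whole unit. Rounding ties (mean exactly .5) round half-up; the rounding
   rule leaves ties unspecified, so the tie-break is fixed and tested.
   Imputation happens on counts before weighting, giving one rule for both
   score types. A pooled-mean fallback (`pooled = TRUE`) serves unlabeled
   data.
5. **Scores**: unweighted GRS = risk-allele count (equal, additive
   effects); weighted GRS = $\sum_j x_j\,|\beta_j|$ with published betas.

# Association battery

* **Binning** is always computed among controls only (quartiles for TNMC,
  tertiles or median splits for scores), with the linear-interpolation
  quantile convention (`stats::quantile` type 7) and intervals closed on
  the right, so a value exactly at a cut is "low". Cut points are reported
  in the output, making any convention drift visible. Degenerate reference
  distributions (a bin with no controls) are rejected.
* **2×2 odds ratios** use the cross-product with the Woolf log-OR normal
  95% interval ($\pm 1.96$ on the log scale). Zero cells error unless the
  Haldane 0.5 correction is explicitly requested. When published tables are
  re-analysed, the package always recomputes the OR from the printed
  counts; if a printed estimate disagrees with its own printed counts the
  discrepancy is surfaced, never reconciled.
* **Logistic models** (`fit_logistic`) are unconditional maximum-likelihood
  fits with Wald intervals and p-values, complete-case per model (each
  model's n reflects its own missingness — deliberately, so sample-size
  accounting is auditable per row of output). The five adjustment sets are
  nested: none; age, race, education; + family cancer history, OC ever-use,
  estrogen use; + BMI; + BMI change. Education enters as an ordinal 1–4
  code; BMI as the continuous value 5 years before interview; BMI change as
  its 4-level category — the published analyses do not state these codings,
  so they are fixed here and documented. Separation/non-convergence and
  rank deficiency raise classed errors rather than returning silently
  unstable estimates. No multiple-testing correction is applied, matching
  the analysis style the battery reproduces.
* **Joint variable** (`joint_tnmc_grs1`): four levels from the control
  medians of TNMC and GRS1 (low/low reference, TNMC named first). The
  median reference population is the controls, consistent with the
  control-based quartiles and tertiles.
* **Interaction**: Wald test of the product of the two median-split
  indicators added to the main-effects logistic model; its null calibration
  is verified by simulation.

# The synthetic cohort generator

The generator (`simulation_config`, `simulate_cohort`) produces the study
structure the analysis assumes, with every latent quantity recorded for
parameter-recovery testing:

* **Genotypes**: independent SNPs (26 menarche, 22 menopause by default);
  per-SNP risk-allele frequency uniform on (0.25, 0.81), whose mean ≈ 0.53
  puts the unweighted GRS1 mean near 27.5 of a possible 52, the realistic
  range for common trait-associated variants. The annotated effect allele
  is the risk allele for a random half of SNPs, so orientation code is
  genuinely exercised. The simulated per-allele effect is written into the
  annotation as the "published" beta.
* **Ages**: menarche = 12.6 ± 1.5 y baseline plus the centred genetic
  contribution (−0.08 y per risk allele by default, jittered ±50% across
  SNPs); natural menopause = 50.8 ± 3.9 y with +0.25 y per allele. These
  magnitudes are typical of menarche/menopause GWAS loci; centring keeps
  the configured baselines as population means.
* **Reproductive history**: live births Poisson(2.5); pregnancy months =
  9 per live birth plus a Poisson(2) loss term (only the aggregate is
  observed downstream); breastfeeding ~ per-birth exponential (2.5
  mo/birth); OC ever-use 65% with Gamma months (mean 60 among users);
  cycle length 28 ± 2 d clamped to 21–35.
* **Obesity**: BMI at 20 ~ N(21.5, 2.5); percent growth to 5-years-before
  interview ~ Gamma (mean 24%, SD 17%), giving a right-skewed positive
  drift.
* **Disease and sampling**: logit risk = −7.3 + ln(1.29)·TNMC/100 +
  0.15·BMI (≈10% prevalence in the source pool of 8,000); cases sampled
  from the diseased, controls from the non-diseased stratum by stratum so
  the control age-group distribution (edges 35, 52, 60, 65, 70, 75, 80)
  matches the sampled cases' within one subject per stratum
  (largest-remainder rounding). 9% of postmenopausal subjects are
  reassigned to induced menopause, their natural age censored. The disease
  model covariates are TNMC and BMI only — the true generating process of
  any real study is unknown, so the model is kept minimal and extensible
  through the config.
* **Seeding**: one master seed spawns a named sub-stream per stage
  (genotypes, phenotypes, disease, missingness) via a string-hash mix
  modulo $2^{31}-1$, so adding a stage never perturbs earlier draws and a
  fixed seed reproduces the cohort bit-identically.

What the generator deliberately does **not** emulate: linkage
disequilibrium between panel SNPs (they are independent, so LD pruning is
exercised only via constructed fixtures), recall error and reporting
heaping, secondary amenorrhea, age-dependent recruitment intensity, and any
real SNP list. Passing tests therefore demonstrate that the *pipeline*
recovers what it assumes — not that those assumptions hold in any real
cohort.

# Verification strategy and problem sizes

The test suite pairs every operation with an independent oracle: hand
arithmetic for the composites and 2×2 tables, closed-form binomial moments
for the genotype generator, the cross-product identity for unadjusted
logistic fits, constructed multiplicative tables for the interaction null,
and simulation for calibration. The simulation checks use 200 replicates of
1,000 cases + 1,000 controls (coverage of a generating odds ratio of 1.29
per 100 cycles), 5,000-subject control cohorts (score-age effect
directions), 2,000 SNPs × 1,000 subjects (HWE uniformity) and 1,000 null
replicates of n = 1,000 (interaction type-I error) — sizes at which
Monte-Carlo error is small relative to the tested tolerances while the
whole suite runs in well under a minute. Parameter-recovery fits condition
on the disease-model covariate (BMI) and the matching variable (attained
age): the marginal odds ratio is attenuated relative to the conditional one
by non-collapsibility of the logistic link, so the conditional model is the
estimand-consistent check.

# Known limitations

* Composite-LD r² understates haplotype r² under some allele-frequency
  configurations; with phased data a haplotype-based pruner would be
  preferable.
* Wald intervals are first-order; profile-likelihood intervals would behave
  better in small strata, but Wald matches the reporting conventions of the
  analyses this package reproduces.
* The weighted score takes published betas at face value (absolute values
  in risk orientation); no shrinkage or winner's-curse correction is
  applied.
* Induced menopause is handled by flagging and subsetting, not by modelling
  the censoring mechanism.
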