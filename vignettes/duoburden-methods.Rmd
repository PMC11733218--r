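---
title: "Models and methods in duoburden"
author: "duoburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in duoburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Birth weight responds to two distinct genetic signals: the child's own
(fetal) genotype, and the mother's genotype acting through the intrauterine
environment.  Because a mother transmits each allele to her child with
probability 1/2, the two genotypes are correlated (r = 0.5 for rare
variants), and a burden scan run in either generation alone estimates a
*marginal* effect that mixes both signals.  `duoburden` implements the full
analysis chain for rare-variant (MAF < 0.1%) gene-burden association with
birth weight in this setting: genotype-call QC, phenotype derivation,
variant collapsing masks, covariate-adjusted carrier burden tests with
exome-wide multiple-testing control, and the weighted-linear-model (WLM)
deconvolution that converts a pair of marginal fetal/maternal estimates
into approximately conditional ones.

# The burden model

Rare qualifying variants in a gene are collapsed to a per-sample carrier
indicator ("dummy genotype"): carrier if any qualifying variant has dosage
at least 1; non-carrier if at least one qualifying call is observed and
none carries; missing only when every qualifying call is missing.  Partial
missingness resolving to the observed evidence is a deliberate choice — the
alternative (propagating missingness from any single site) discards most of
the cohort once a gene holds many variants.  Carrier status is binary, not
an allele count, so the burden coefficient is the mean phenotype difference
per carrier, in SD units.

The association model is ordinary least squares of the standardised
phenotype on carrier status plus covariates (age, age squared, sex in
sex-combined fetal runs, ten ancestry principal components, sequencing
batch; the maternal analysis uses age at first birth — or year of birth
when that is unavailable — in place of reporter age).  Two-sided p-values
come from the t reference at residual degrees of freedom.  Mixed models
(BOLT-LMM, REGENIE) are the biobank-scale tool for the same fit because
they absorb cryptic relatedness; the simulator generates unrelated
samples, so OLS is the correct desk-scale analogue, and published
cross-method comparisons show no method-related bias for this design.
Genes with fewer than 10 carriers are excluded from reporting, and the
exome-wide threshold is 0.05 divided by the total number of testable
(>= 10 carriers) gene-mask combinations; significance is strict
(`p < threshold`).

## Masks

Two discovery masks are built in: `PTV` (stop-gained, splice
donor/acceptor and frameshift consequences collapsed to one class, kept
only when flagged high-confidence by LOFTEE) and `MissensePTV`
(high-confidence PTVs plus missense with CADD >= 25, inclusive).  Named
variants cover the confirmatory-style mask that also admits inframe indels
at CADD >= 25, an experimental-evidence mask for missense variants with
MITER <= -2 (lipodystrophy-level loss of function), and a
clinical-classification mask (pathogenic / likely-pathogenic), plus a
leave-one-out exclusion list on any mask.  Mask relaxation is monotone by
construction: loosening a cutoff can only add qualifying variants and
therefore never reduces a gene's carrier count.

# Genotype QC

The pipeline order is fixed: call-level filters, heterozygous
allele-balance test, variant missingness, optional AD~DP slope and AAscore
filters, MAF restriction.  All thresholds follow the strict inequalities
documented on `qcThresholds()`: SNV calls need DP >= 7 and GQ >= 20
(indels DP >= 10), heterozygous SNVs are set missing when the two-sided
exact binomial probability of their alternate-read count under
Binomial(DP, 1/2) is <= 1e-3, variants with more than 50% missing calls
are dropped, and the rare filter keeps MAF < 0.001 computed within the
analysis cohort after call-level QC (the natural choice when no external
reference panel is attached).

Two choices deserve a note:

* The allele-balance test is two-sided (a true heterozygote deviates in
  either direction) with the minimum-likelihood convention for
  two-sidedness, matching `binom.test`; at the 1e-3 threshold the
  minlike/central conventions agree at realistic depths.
* The AD~DP slope regresses the observed alternate-read count on its
  genotype-expected value, (dosage/2)·DP, with a fitted intercept.  This is
  the reading under which a well-behaved variant has slope 1 across mixed
  genotype classes; a variant whose heterozygous calls carry alternate
  reads with probability p instead of 1/2 trends to slope 2p, so the 0.5
  cutoff catches spurious variants.  All non-missing calls enter the
  regression; when the design is degenerate (all expected values equal) the
  slope is undefined and the variant is retained with a warning rather
  than silently dropped.  The slope and AAscore (> 0.8) filters belong to
  replication-cohort-style QC and default to off.

# Phenotype derivation

One birth weight in kg per sample: pound reports convert at 0.45359237,
repeated reports average, and a sample is excluded when it is from a
multiple birth, when reports disagree by more than 1 kg, or when the value
is < 1 or >= 7 kg.  For offspring birth weight, hospital-source reports
are preferred over self-reports when both exist.  A `regenie`-style toggle
reproduces the confirmatory team's variant of these rules (exclusion at
>= 1 kg, self-reports only), because concordance of the two derivations is
itself a robustness check.  Standardisation to z-scores happens once over
the analysis cohort, before regression, with covariates entering the model
rather than being residualised out (equivalent under OLS).  Standardisation
is overall rather than within sex, with sex as a covariate — the common
convention when stratified and combined runs must share a scale.
Exclusion reasons partition the removed samples and are logged with
(n_before, n_removed, n_after) counts, as is every genotype filter.

# The WLM deconvolution

With mother-child genotype correlation 0.5, marginal estimates project the
conditional effects as

    E[bF_hat] = bf + bm / 2        E[bM_hat] = bm + bf / 2

so the inversion is `bf_adj = (4 bF - 2 bM) / 3`,
`bm_adj = (4 bM - 2 bF) / 3`, with variances
`(16 seF^2 + 4 seM^2 - 16 cov) / 9` (and symmetrically).  The covariance
term covers overlap between the fetal and maternal panels; it defaults to
0 (independent panels) because the overlap covariance in real cohorts is
rarely published, and is exposed as a parameter.  The exact weighting
scheme admits variants for other sample configurations; the duo-design
inversion above is adopted and verified by simulation (below).  Adjusted
p-values use the normal reference — the inputs are already large-sample
estimates — and genes classify as fetal-only / maternal-only / both /
unclassified by the p < 0.05 rule on the adjusted estimates.

Sex dimorphism is tested on summary statistics,
`z = (bF - bM) / sqrt(seF^2 + seM^2)` against the normal reference (the
large-sample two-sample t-test; stratified degrees of freedom are not
recoverable from summaries and are irrelevant at the sample sizes where
stratified fits are attempted).  Directional replication uses the exact
two-sided sign test at probability 1/2, with zero-effect pairs dropped as
signless ties.

# The duo simulator

`simulateDuos()` emulates the statistical structure of a biobank
birth-weight exome study so that every downstream stage is testable
without real data:

* **Transmission.** Mother and father carrier states are independent
  Bernoulli draws per variant; a carrier parent transmits with probability
  1/2; the child dosage is the transmission sum.  Fathers are simulated
  but never emitted — this *mechanism* produces the 0.5 mother-child
  carrier correlation for rare variants instead of imposing it.
* **Phenotype.** The child's latent SD-scale phenotype is the sum of
  per-gene fetal effects (own carrier status) and maternal effects
  (mother's carrier status), small covariate effects (sex -0.12 SD for
  females, 0.002 SD per year of reporter age, 0.01 SD per PC unit, 0.02 SD
  for the second batch — together well under 1% of variance, which is what
  biobank covariates explain of standardised birth weight), and
  Normal(0, 1) noise.  It maps to kg as 3.4 + 0.55 z, the approximate
  European-ancestry birth-weight location and scale.
* **Reports.** The same value surfaces as the child's own report(s)
  (1-2 visits, 0.05 kg visit noise, 5% in pounds, 2% missing) and the
  mother's offspring report (self-report and/or a more precise hospital
  record), with a 1.5% multiple-birth rate; these defaults exercise every
  derivation rule at realistic rates.
* **Reads.** DP ~ Poisson(30); alternate reads Binomial(DP, p) with
  p = 0.5 for hets, ~1 for hom-alt, ~0 for hom-ref; GQ ~ round
  Normal(60, 15) truncated to 0..99; 1% missing calls.  Spurious-variant
  specs override the het p to emulate artefacts that the slope filter
  must catch.
* **Truth.** True betas and true carrier matrices ride along for
  recovery tests.  Identical seed and config give byte-identical outputs,
  including written files (the VCF emitter stamps no dates).

What the simulator does **not** model: relatedness and population
structure (handled by mixed models in real studies, out of scope here),
assortative mating, de novo variants, parent-of-origin effects,
base-level sequencing error, and X-chromosome hemizygosity (all genes are
treated as diploid; burden coding for hemizygous males is an open point in
the field and diploid coding is the conservative default).  Because the
WLM's assumptions hold exactly in the generator, recovery failures
implicate the implementation, not the model — and, conversely, passing
tests say nothing about robustness to the listed violations in real data.
The overlap between fetal and maternal panels defaults to 0 (matching the
SE propagation default); a configurable overlap fraction exists but its
realistic value is unknown.

# Validation studies and problem sizes

Two packaged studies back the test suite and `scripts/acceptance.R`:

* `wlmRecoveryStudy()`: replicate pairs of disjoint 50,000-duo panels, a
  single gene at 0.2% aggregate carrier frequency (two variants, so each
  variant sits safely under the 0.1% MAF cap), truth (0.4, -0.2) SD.  The
  acceptance suite runs 300 replicates; the marginal means land at the
  projected (0.3, 0.0) and the adjusted means at the truth, within
  Monte-Carlo error.  The study runs the real pipeline (report
  generation, derivation, standardisation, collapsing, covariate-adjusted
  OLS); genotype QC is validated separately and defaults to off inside
  the replicate loop, where clean simulated reads make it a no-op at
  material cost.
* `nullCalibrationStudy()`: 6,000-duo cohorts around a null gene at 0.8%
  carrier frequency (~48 carriers, comfortably above the 10-carrier
  reporting floor in both sex strata); 1,000 replicates give the type-I
  error of the burden test and of the dimorphism test at alpha = 0.05.

Numerical conventions used throughout: strict inequalities exactly as
stated on the thresholds; ties in the sign test dropped; collinear
covariates dropped with a warning rather than failing the fit; degenerate
slope designs flagged not-evaluable; standardisation refuses zero-variance
input.  Coordinates are 1-based inclusive everywhere, the 300-kb GWAS
proximity windows are closed intervals measured from gene span edges, and
a conditional-analysis attenuation of more than 10% (in either direction)
of the marginal effect flags a shared signal with the GWAS sentinel.

# Known limitations

The OLS engine assumes unrelated samples; the phenotype reporting model is
far simpler than real recall behaviour; annotations (LOFTEE confidence,
CADD, MITER, AAscore, clinical classes) are consumed as inputs, never
computed; binary traits are out of scope; and the WLM assumes equal
effects across the variants aggregated by a mask — the same strong
assumption its summary-statistic form always carries.
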