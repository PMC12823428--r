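---
title: "Methods: triangulating genetic and proteomic evidence for a binary disease outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangulating genetic and proteomic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## Overview

`triomics` implements a complete evidence-triangulation workflow for a
binary disease outcome (the motivating application is delirium risk in
ageing cohorts): genome-wide logistic association scans with variant QC,
multi-cohort fixed-effects meta-analysis with genomic control,
counterfactual mediation of a risk haplotype through a binary mediator
(dementia-like), a proteome-wide association study (PWAS) on plasma protein
levels, penalized protein selection with stability selection and prediction
evaluation, cis-pQTL two-sample Mendelian randomization (MR), approximate
Bayes factor colocalization, and a final report that joins PWAS, MR,
colocalization and druggability-tier evidence per protein.

Individual-level biobank data cannot be redistributed, so the package ships
a synthetic multi-cohort generator whose statistical structure matches what
the downstream stages assume. Every generating parameter is retained in the
bundle, which is what makes the test suite's parameter-recovery and
calibration claims checkable.

## The synthetic cohort generator

**LD model.** Haplotypes are latent Gaussian AR(1) processes per block:
adjacent variants have latent correlation `block_r` and the correlation
decays as `block_r^distance`. Each latent value is thresholded at the
allele-frequency quantile, two haplotypes are summed to a dosage, so
genotypes are in Hardy–Weinberg proportions by construction. This is the
simplest model that gives a *tunable* r² decay, which is exactly what the
LD-clumping and lead-variant logic needs to be tested against. It does not
reproduce realistic human LD maps (hotspot structure, long-range LD), so
clumping behaviour on real data near complex loci is not covered by these
tests.

**Risk haplotype.** Two variants in one block define a haplotype (an
analogue of a two-variant missense haplotype such as APOE-ε4); a haplotype
copy requires both alleles on the same parental haplotype, which the
generator can count because it simulates haplotypes, not genotypes. The
per-copy log-odds effects on the mediator and directly on the outcome are
parameters; the mediated (indirect) path arises as
`logor_mediator x mediator_logor`.

**Outcome model.** A single logistic draw per subject in haplotype count,
mediator status, age, sex and (optionally) per-SD protein effects; the
intercept is solved numerically so the expected case fraction equals the
requested prevalence. Disease onset is not modelled as a time-to-event
process — the phenotype table carries follow-up and onset times only so the
incident-case definition (first event more than one year after baseline)
can be exercised. All association models downstream are logistic, so a
liability-threshold alternative is unnecessary except for the
heritability-conversion arithmetic, which is a pure formula.

**Proteins.** Standardized protein levels are linear in the dosages of
their declared cis variants plus Gaussian noise; raw "NPX-like" levels are
an affine transform of those. Missingness is missing-completely-at-random
per protein (default rates around 10–20%); informative missingness is
deliberately out of scope because the preprocessing chain (filter at 20%,
mean-impute, inverse-normal) would not distinguish mechanisms anyway.
Cis variants must lie within ±1 Mb (inclusive) of the protein's nominal
gene anchor, matching the cis window used by the MR instrument filter.

**Cohorts and seeds.** A single architecture object fixes variant panel,
frequencies and positions; cohorts simulated from it share the panel, and
an `ancestry_fst_like` scale perturbs allele frequencies on the logit scale
per cohort. One master seed drives derived per-stage streams (frequencies,
haplotypes, covariates, mediator, proteins, outcome) so identical seeds are
bit-reproducible and stages can be reasoned about independently.

## Association scans and QC

Variants pass QC only with minor-allele count strictly greater than 5 in
each of the case and control arms, missingness strictly below 3%, and an
exact Hardy–Weinberg p value at or above 1e-6 (a pQTL-style scan adds a
minor-allele-frequency floor, default 1%). Each dropped variant carries
one primary reason code, assigned in a fixed order (monomorphic, case MAC,
control MAC, missingness, HWE, MAF), which makes QC idempotent and
auditable. The HWE test is the exact conditional test: the p value sums
the probabilities of all heterozygote counts no more probable than the one
observed, given the allele counts; no mid-p correction is applied, and the
implementation canonicalizes the two homozygote labels so the test is
exactly symmetric in them.

Scans fit maximum-likelihood logistic (or OLS for quantitative protein
traits) models per variant with covariates, per-variant complete-case
handling of missing dosages, and optional conditioning columns (e.g. the
haplotype count, for conditional scans) or strata (by subsetting rows).
Wald statistics are reported, matching the delta-method odds-ratio
interval `exp(b) ± 1.96 · se · exp(b)` used throughout. Perfectly
separated fits are flagged and their p values left missing — no silent
zeros and no penalized rescue, so downstream stages can exclude them
explicitly. Genomic inflation is `median(chi²)/0.4549364`.

## Meta-analysis

Fixed-effects inverse-variance pooling with weights `1/se²`. Genomic
control is applied once, per contributing study, by inflating that study's
standard errors by `sqrt(max(lambda, 1))`; a second, meta-level correction
is available behind a flag but off by default — correcting twice for the
same population structure is conservative without additional
justification. Alleles are harmonized to each variant's first-seen
orientation, flipping signs and frequencies for swapped alleles;
palindromic (A/T, C/G) variants are resolved by allele frequency only when
both frequencies are informative (at least 0.08 from 0.5), otherwise
dropped. Variants present in a single study are excluded unless
passthrough is requested, in which case they are flagged rather than
silently pooled.

Lead variants are extracted greedily: take the smallest significant p,
exclude ±500 kb on the same chromosome, repeat. Replication requires
`p < 0.05 / n_leads` with matching effect direction. The
observed-to-liability heritability conversion applies
`h²_liab = h²_obs · K(1-K)/z² · K(1-K)/(P(1-P))` exactly as written, with
`z` the standard-normal density at the prevalence quantile. Note that with
`P = K` the factor collapses to `K(1-K)/z²`, which exceeds 1 for every
prevalence — the conversion never has a fixed point, a property the tests
assert rather than a numerical root that does not exist.

## Mediation

Natural direct and indirect effects of a 0/1/2 exposure on a binary
outcome through a binary mediator are estimated by mediator-density
weighting: fit the mediator model, expand every subject over all
hypothetical exposure levels, weight each expanded row by the ratio of the
mediator density under the hypothetical versus the observed exposure, and
fit one weighted logistic natural-effect model with separate
observed-exposure (direct) and hypothetical-exposure (indirect) terms. No
exposure–mediator interaction is included in the natural-effect model by
default — with the interaction the decomposition is no longer a simple sum
of two coefficients per contrast, and the primary analyses this package
mirrors report a plain two-term decomposition. By construction NDE + NIE
equals the total effect on the log-OR scale exactly, per contrast and per
bootstrap replicate, and the proportion mediated is reported as a ratio of
log odds ratios — the scale on which the decomposition is additive.

Inference is a subject-level bootstrap (default 1,000 replicates; the
coverage test suite uses 200 subjects × 200 replicates × 200 simulations,
sized so that sampling error dominates the small non-collapsibility bias
of the logistic NDE at a rare outcome). E-values,
`E = RR + sqrt(RR(RR-1))` with the odds ratio standing in for the risk
ratio (and protective effects inverted first), quantify the minimum
unmeasured-confounding strength needed to explain the direct effect away;
the approximation is adequate only for rare outcomes, which is the regime
here.

## Proteome-wide association

Preprocessing follows a fixed order: drop proteins with more than 20%
missing entries (exactly 20% is kept), drop zero-variance columns,
mean-impute from observed values, inverse-rank normalize with the Blom
offset `qnorm((r - 3/8)/(n + 1/4))` (average ranks for ties), then
standardize. The Blom offset is one of several standard offsets; nothing
downstream is sensitive to the choice, but it is fixed so results are
reproducible to the digit. One logistic model per protein (covariates age,
sex, BMI; optional haplotype-count adjustment and protein × haplotype
interaction) yields per-SD odds ratios, Bonferroni flags at `0.05/m` and
Benjamini–Hochberg q values. Enrichment uses the one-sided hypergeometric
(Fisher) test of hit overlap against the full tested panel as background
— enrichment direction only, since depletion of a hit set this small is
not interpretable — with BH control across pathways.

## Protein selection and prediction

The cohort splits 80/20 by simple (non-stratified) random sampling. An
L1-penalized logistic model over 100 log-spaced penalties in
`[1e-6, 0.07]` with 10-fold cross-validated binomial deviance (fold labels
seeded and shared across the grid; demographics unpenalized) supplies
`lambda.1se`, the strictest penalty within one standard error of the
minimum CV loss. Stability selection then refits the LASSO at that single
fixed penalty on 100 subsamples, each containing every case and an
equal-size control subsample drawn without replacement (refusing to run if
controls are scarcer than cases); proteins selected in at least half of
the subsamples — frequency exactly 0.5 counts — are retained. Re-using the
scalar `lambda.1se` (not per-feature penalty factors) in every subsample
is the reading adopted here: the subsample halves the controls, so
re-tuning per subsample would confound selection stability with penalty
instability.

Four nested logistic models are refit (demographics; proteins;
proteins + demographics; haplotype + proteins + demographics), with
backward stepwise-AIC elimination over proteins only — demographics and
the haplotype count are never dropped. Elimination is deterministic: the
removal that most lowers AIC is applied, ties broken alphabetically, until
no removal improves AIC. Discrimination on the held-out test set is
reported as ROC AUC (the rank/concordance statistic), PR AUC (trapezoid
over recall of the precision–recall step curve, anchored at recall 0 — a
constant score scores the case prevalence, which is the informative
baseline under heavy class imbalance) and two-sided paired DeLong tests
(placement-value covariance) for AUC differences.

## Mendelian randomization

Instruments are independent cis-pQTLs: genome-wide-significant protein
associations clumped greedily at r² < 0.2 within ±250 kb (LD measured on a
genotype reference; a strict r² < 0.001 mode exists for sensitivity
re-runs near high-LD loci), then filtered to F = β²/se² ≥ 10, association
with fewer than five proteins, and position within ±1 Mb (inclusive) of
the protein's gene. Estimators: Wald ratio (single instrument; first-order
delta-method se, adequate under the F ≥ 10 screen), IVW over per-instrument
ratios, weighted median (500-draw parametric bootstrap se), profile maximum
likelihood under the bivariate normal measurement model, and MR-Egger
(weighted by `1/se_out²`, exposure effects oriented positive, residual sd
floored at 1) with its intercept test; Cochran's Q with `df = k - 1`
summarizes heterogeneity.

The IVW standard error defaults to multiplicative over-dispersion
(`se` scaled by `sqrt(max(Q/df, 1))`), the common two-sample default that
guards against residual heterogeneity; because the floor binds about half
the time under the null, that mode is mildly conservative at small
instrument counts, so a plain fixed-effect mode (`se_model = "fixed"`) is
provided and is the mode under which null p values are exactly uniform —
the calibration suite asserts precisely that, and asserts that the
over-dispersion guard only ever widens intervals. Instruments clumped at
r² < 0.2 are treated as independent in estimation; the strict-clumping
mode is the guard against that approximation. Panels apply BH FDR across
testable proteins on the primary estimator (IVW, or Wald ratio with one
instrument), then re-test significant proteins against a sensitivity
outcome (FDR within the re-tested set) and a replication outcome
(p < 0.05 with matching direction).

## Colocalization and the triangulation report

Per-variant Wakefield log approximate Bayes factors,
`0.5·log(se²/(se²+W²)) + z²W²/(2(se²+W²))`, with prior effect sd `W = 0.2`
for binary-trait log-ORs and `0.15` per SD for protein traits, are combined
under the single-causal-variant five-hypothesis model with per-variant
priors `p1 = p2 = 1e-4`, `p12 = 1e-5`; all sums run in log-sum-exp
arithmetic so z scores of 40 are routine. Both of the circulating PP.H4
threshold conventions are supported: the default report category uses
0.8 (colocalized) / 0.5 (suggestive), and a strict 0.9 reading is a
parameter away — the package surfaces the two conventions rather than
adjudicating between them. Synthetic regions use the generator's block
boundaries (fallback: ±250 kb around the lead pQTL) in place of
recombination-map segments.

The final report includes a protein only when PWAS (p < 0.05) and primary
MR (FDR q < 0.05) agree in direction; each record carries the PWAS
evidence tier (Bonferroni ⊂ FDR ⊂ nominal), the MR sensitivity and
diagnostic flags, the colocalization category and the druggability tier
from a user-supplied table ("Not classified" when absent — the licensed
external druggability resource is not redistributed; tests use a small
synthetic tier fixture).

## Numerical choices and degenerate inputs

* Far-tail p values: `z_from_p` inverts the normal tail in log space,
  stable to p ~ 1e-300; two-sided p values are computed from log tail
  probabilities, never as `2*(1 - pnorm(z))`.
* Logistic fits flag separation (fitted probabilities pinned at 0/1 or
  coefficients beyond ±20) and non-convergence; flagged records are
  excluded from multiplicity denominators and significant sets.
* Monomorphic variants, empty hit sets, empty protein matrices, single
  exposure levels, proteins without instruments, and empty variant
  intersections all return explicit reason codes or errors rather than
  NaNs.
* Simulation sizes in the test suite (e.g. 10 null cohorts of 1,000
  subjects × 1,000 variants for type-I error; 200 mediation simulations of
  500 subjects; 100 stability-selection subsamples over 100 proteins) were
  chosen as the smallest designs whose Monte-Carlo error is well inside
  the asserted tolerance bands.

## Known limitations

The generator omits relatedness, X-chromosome dosage, imputation noise,
realistic LD maps, batch structure in protein assays, and informative
protein missingness; passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to those
real-data complications. Mixed-model association (whole-genome ridge),
random-effects meta-analysis, multi-causal colocalization, MR-PRESSO-style
outlier removal and Cox modelling of incident disease are intentionally
out of scope.
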