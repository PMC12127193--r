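---
title: "Methods: predictive-biomarker stratification with predstrat"
author: "predstrat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predictive-biomarker stratification with predstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predstrat)
```

## The analysis problem

predstrat implements a post-hoc predictive-biomarker analysis for a small
three-arm randomized trial of a topical drug in mild-to-moderate atopic
dermatitis, where plasma proteins quantified at baseline by targeted MRM-MS
are screened for their ability to predict which patients will respond to the
active treatment. The clinical outcome is the percent change from baseline
in the EASI severity score at week 4; a patient is an *EASI50 responder*
when that change is at most -50% (boundary inclusive). The package covers
the full chain: transition-level quality control and absolute
quantification, endpoint computation, single-marker cut-off stratification,
odds-ratio and predictive-value summaries, logistic multi-marker
combinations, and exploratory analytics - plus a seeded synthetic trial
generator so the entire chain is testable without patient-level data, which
trials of this kind rarely release.

## Quantification model

Each target peptide is measured against a stable-isotope-labeled internal
standard (SIS) spiked at a known amount. The endogenous amount is

    endogenous (fmol) = PAR x SIS injected (fmol)

where PAR is the endogenous/SIS peak area ratio. Upstream of quantification,
transitions are excluded when the SIS peak intensity is below 100 counts,
when the SIS peak fails to co-elute with the endogenous peptide, or when the
elution peak is asymmetric; exclusions are attributed to the *first* failing
rule in that order so QC tallies are deterministic. Co-elution and symmetry
are taken as precomputed flags in the transition report: peak-shape scoring
happens in the vendor integration software and is out of scope here.

Calibration series at 50/100/200/400 fmol pass when every PAR lies strictly
inside (0.1, 1) and the squared correlation of PAR against spike level is at
least `r2_min`. The literature on this workflow states the window but no
linearity statistic; we chose R^2 >= 0.9 as the default and exposed it as a
parameter. Collision energies follow the charge-specific linear ramps
`0.031 mz + 1` (2+) and `0.036 mz - 4.8` (3+); other charge states raise an
error rather than defaulting silently.

## Statistical core

**AUROC.** Computed by the rank-sum identity, so ties contribute 1/2; this
equals the trapezoidal area under the empirical ROC curve and is checked in
the tests against exhaustive pair counting.

**Youden cut-offs.** Candidate thresholds are the midpoints between
consecutive sorted unique marker values. Both directions are scanned - "hi"
(level >= threshold predicts response) and "lo" (level <= threshold) - and
the pair maximizing J = sensitivity + specificity - 1 is kept. The
direction-selection rule is our choice (the source analysis reports both
"hi" and "lo" markers without stating how the side was picked); maximizing J
is the natural completion. Ties are broken toward "hi", then the smaller
threshold. A marker value exactly equal to the cut-off is assigned to the
favorable side. Constant markers are degenerate: J = 0, direction undefined.

**DEP screen.** Proteins are kept when the direction-adjusted AUROC
(`max(a, 1 - a)`) against responder status within the active arm strictly
exceeds 0.7, sorted by AUROC with ties broken by protein id. With ~20
active-arm patients this screen has a substantial in-sample false-selection
rate; that is a property of the procedure itself and is quantified in the
tests against a label-permutation oracle rather than "fixed".

**Odds ratios.** From the 2x2 table of stratum membership against responder
status. If any cell is zero, the Haldane-Anscombe correction adds 0.5 to
*all four* cells before forming OR = a'd'/(b'c'). The 95% CI is the Wald
interval on log OR with SE = sqrt(sum of reciprocal corrected cells) and the
exact normal 0.975 quantile (1.959964...), not the rounded 1.96 - the
difference is visible in the upper bound of large corrected ORs. The
p-value is the two-sided Fisher exact test on the *uncorrected* table; the
correction affects only the OR and CI. This reproduces the printed worked
examples: table (4,0,1,15) gives OR 93.0 [3.2, 2699.7] and table (4,1,1,14)
gives OR 56.0 [2.8, 1109.4].

**Benefit indicator.** A stratum shows treatment benefit when the
between-arm (active minus placebo) p-values for *both* the EASI and the IGA
percent-change contrasts are strictly below 0.05. Missing contrasts (a
stratum lacking one arm) give `FALSE`.

**Testing conventions.** Within-arm changes are gated by Shapiro-Wilk at
alpha = 0.05 (configurable; the source is silent on the level): one-sample t
if normality is not rejected, Wilcoxon signed-rank otherwise; an all-zero
change vector reports p = 1 with no test. Between-arm contrasts use Welch's
t by default with a pooled-variance option - the source names "Student's
t-test" without specifying the variance assumption, and Welch is the safer
default for unequal small arms. Baseline balance uses classical one-way
ANOVA. IGA percent change treats the ordinal grade as numeric, matching how
such changes are conventionally reported.

**Logistic combinations.** Two- or three-marker benefit models are fitted by
iteratively reweighted least squares (tolerance 1e-8 on the log-likelihood,
at most 100 iterations) on internally standardized predictors, with an
optional natural-log transform per marker (the convention for strongly
right-skewed abundances). With ~20 patients and strong markers, perfect or
quasi-separation is frequent; it is detected as non-convergence or a
standardized coefficient exceeding 20 in absolute value, and the model is
then refitted with a small ridge penalty (1e-4 on the standardized scale,
never on the intercept) so predicted probabilities (pp) remain usable for
thresholding. The pp threshold reuses the same Youden midpoint rule. Because
the logistic link is monotone, a single-predictor pp threshold selects
exactly the same stratum as the marker-level threshold; this identity is a
test. Multi-marker strata are alternatively formed as boolean unions of the
single-marker cut-offs ("hi on A or lo on B"); both pathways are reported.
Combination rows are ordered by OR p-value, then AUC, then label.

**Exploratory analytics.** Hierarchical clustering z-scores each biomarker,
then uses the Canberra distance with complete linkage (via `stats::dist` and
`stats::hclust`, whose merge-index tie-breaking is deterministic). PCA runs
on standardized columns with a largest-loading-positive sign convention.
Volcano rows carry the log2 ratio of responder over non-responder means and
a pooled-variance t p-value; non-positive group means leave the fold change
missing. Preranked GSEA uses the weighted (exponent 1) running-sum
statistic: members add `|score|/NR`, non-members subtract `1/(N - Nh)`, and
the enrichment score is the signed extremum; when the extremum is attained
at several positions the attainment maximizing the leading edge is used
(last for positive ES, first for negative) so that sign-flip symmetry
mirrors the edge. Significance comes from gene-set membership permutation -
on a preranked list there are no sample labels to permute - with NES = ES /
mean(|null ES| of the same sign), a one-sided within-sign permutation p with
add-one smoothing, and an FDR q comparing each NES against the pooled
normalized null and the observed NES distribution of the same sign.

## The synthetic trial generator

The generator is first-class, tested code: it defines the study conditions
every downstream claim is evaluated under.

* **Design.** 27/27/26 patients (placebo / low dose / high dose) across 5
  sites, assigned by stratified permuted-block randomization with block
  sizes 3 and 6. Arm totals are enforced exactly by a seeded adjustment
  pass after the last (possibly truncated) block.
* **Baseline.** EASI from a truncated normal 8.27 +/- 4.36 on (0, 72]; IGA
  grade 3 with probability 0.405, grade 2 otherwise; itch NRS around
  4.8 +/- 2.1; enrollment dates spanning Aug 2020 - Sep 2021 with season
  derived from the month.
* **Outcome model.** Week-4 percent change in EASI is normal per
  (arm, marker-match) cell. Defaults: placebo mean -2.9 (sd 40), low dose
  -12.2 (sd 40), high-dose marker-matched -75 (sd 25), high-dose unmatched
  +4 (sd 35). With a matched fraction of 0.20 these calibrate the high-dose
  arm mean to about -12% and the responder rates to roughly 24% (high dose)
  and 12% (placebo), the magnitudes a trial of this size and drug class
  reports. The percent change is truncated to [-100, 100*(72 - b)/b] so
  scores stay in range. Week-2 change is a uniform 0.4-0.8 fraction of the
  week-4 change, reflecting a partial effect at the interim visit.
* **Latent strata.** One uniform latent per patient drives all planted
  markers: marker j's favorable stratum is `u < f_j`, so strata are nested
  and the treatment-responsive core is the intersection (`u < min f_j`).
  This encodes the hi/lo/lo structure of a marker panel whose favorable
  fractions were roughly 20%, 37% and 54%. IGA response is coupled to the
  EASI response through a single latent responsiveness variable
  (correlation 0.6 by default, configurable), with grade changes bounded to
  {-2, ..., +1} and grades clipped to 0-4.
* **Proteome.** Log-normal abundances; per-protein log10 medians drawn
  uniformly over 6.5 orders of magnitude (so the across-protein dynamic
  range exceeds 5 orders, matching the reported five-to-seven-step range),
  per-protein log10 spread 0.15-0.35. Planted markers shift by
  `effect_size` within-protein SDs between latent strata on the stated
  side. Abundances are independent of arm, so baselines are balanced by
  construction.
* **Missingness and sets.** Per-arm dropout (default 0) removes all
  post-baseline assessments, which is what makes the full-analysis-set rule
  bite; adherence is 100 minus an exponential with mean 6; biomarker
  consent has probability 0.9. The analysis sets then follow the standard
  rules (SAS: dosed; FAS: dosed with a post-dose assessment; PPS: completed
  with adherence >= 80%; BAS: FAS with consent and data) and nest by
  construction.

**What the generator does not emulate** - and hence what passing tests do
not show about real data: proteins are independent given the latent stratum
(no correlated pathway blocks, no shared pre-analytical batch effects),
measurement error is purely log-normal (no missing-not-at-random censoring
at the assay floor), sites affect only the randomization (no site-level
outcome heterogeneity), and there are no seasonal or demographic effects on
response. Recovery rates measured under the generator are therefore a
best-case calibration of the procedure, not an estimate of clinical
performance.

## Determinism and numerical choices

Every stochastic stage draws its seed from the master seed through
`split_seed()`, an affine hash modulo 2^31 - 1, so toggling one stage never
shifts another's stream and identical configurations give byte-identical
report files (hashes are recorded in `manifest.json`). Degenerate inputs
are handled explicitly rather than by crash: zero-variance markers are
excluded from z-scoring and PCA with warnings, constant combo predictors
are dropped with a warning, empty strata leave PPV or NPV missing, and
zero-variance contrasts report an infinite CI with a missing p-value.

## Problem sizes used by the test suite

The property tests run 1,000 random instances (n <= 30) against the
exhaustive AUROC and Youden oracles, enumerate every 2x2 table with n <= 12
against the hypergeometric Fisher oracle, and use 200 seeded replicates of a
20-active / 25-placebo trial with 100 proteins for marker recovery plus 150
null replicates against a 300-draw arm-permutation oracle for calibration of
the benefit indicator (compared on a 2 SE band with a 2-percentage-point
floor guarding the zero-rate corner). GSEA calibration uses 100 random sets
on a 60-id universe with 200 permutations. These sizes keep the full suite
under a couple of minutes on one core while leaving the Monte-Carlo bands
tight enough to detect real defects.

## Known limitations

Cut-offs, pp thresholds and combination rankings are all in-sample - there
is no cross-validation or train/test split, and the combination search is
not multiplicity-corrected; both mirror the analysis this package
operationalizes and are quantified (not removed) by the permutation tests.
Small strata make corrected odds ratios extremely unstable (the worked
example's CI spans three orders of magnitude), which is faithful to the
method. The QC counts of a real transition report depend on instrument
data we cannot regenerate; only the rule logic is reproducible.
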