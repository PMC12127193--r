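# predstrat

Predictive-biomarker stratification for small randomized trials with
targeted plasma proteomics.

## What this is for

Small proof-of-concept trials often miss their primary endpoint overall yet
contain subgroups that respond strongly. `predstrat` operationalizes the
post-hoc analysis that looks for those subgroups in a three-arm
(placebo / low dose / high dose) topical-drug trial where baseline plasma
proteins were quantified by targeted MRM-MS against stable-isotope internal
standards: QC-filter and quantify the transitions, compute clinical
endpoints, find per-protein cut-offs that split patients into favorable and
unfavorable strata, quantify the treatment benefit inside each stratum, and
search small logistic combinations of markers. It is aimed at
biostatisticians and proteomics analysts who need the whole chain to be
reproducible and testable; since patient-level data from such trials are
rarely public, a seeded synthetic trial generator with planted predictive
markers stands in for real inputs everywhere in the tests.

## The statistics at the core

* **Quantification**: endogenous amount (fmol) = PAR × SIS injected, after
  excluding transitions with SIS intensity < 100 counts, non-co-eluting or
  asymmetric peaks, and calibration series outside 0.1 < PAR < 1 or with
  R² < 0.9 over the 50–400 fmol spike levels.
* **Responder label**: EASI50, i.e. percent change in EASI from baseline
  ≤ −50 at week 4.
* **Cut-offs**: for each protein the threshold and direction (hi/lo)
  maximizing the Youden index *J* = sensitivity + specificity − 1, with
  candidate thresholds at midpoints of consecutive unique values; proteins
  with direction-adjusted AUROC > 0.7 in the active arm form the DEP panel.
* **Stratum summaries**: within the favorable stratum, the active−placebo
  contrasts of ΔEASI and ΔIGA (Welch t by default), %BAS, PPV = a/(a+b),
  NPV = d/(c+d), and the odds ratio a·d/(b·c) with the Haldane–Anscombe
  correction (add 0.5 to all four cells when any is zero), Wald CI on the
  log scale with the exact 0.975 normal quantile, and a Fisher exact p on
  the uncorrected table. Benefit B = 1 iff both contrast p-values < 0.05.
* **Combinations**: logistic models on 2–3 baseline markers (IRLS,
  ridge-stabilized under separation) with Youden-optimal thresholds on the
  predicted probability, alongside boolean-union strata such as
  "A^hi or B^lo"; preranked GSEA, z-scored Canberra/complete-linkage
  clustering, standardized PCA and volcano statistics for exploration.

See `vignettes/predstrat-methods.Rmd` for the full model description and
every default's rationale.

## Worked example

The printed single-marker stratification table with 4 favorable responders,
0 favorable non-responders, 1 unfavorable responder and 15 unfavorable
non-responders contains a zero cell, so the corrected odds ratio applies:

```r
library(predstrat)
odds_ratio_ha(c(a = 4, b = 0, c = 1, d = 15))
#> $odds_ratio
#> [1] 93
#> $ci_low
#> [1] 3.2
#> $ci_high
#> [1] 2700
#> $p_value
#> [1] 0.00103
#> $corrected
#> [1] TRUE
```

Read: after adding 0.5 to every cell, favorable-stratum patients have 93
times the odds of responding (95% CI 3.2–2699.7 — huge because the table is
tiny), and the exact test on the uncorrected counts gives p ≈ 0.001.

A fully synthetic end-to-end run (80 patients, 120 proteins, three planted
markers) and its stratified-marker report:

```r
cfg <- run_config(out_dir = "run1", seed = 1,
                  trial = trial_config(n_proteins = 120))
res <- run_pipeline(cfg)
head(res$tables$markers[, c("stratum", "delta_easi", "delta_easi_p",
                            "pct_bas", "auroc", "ppv", "npv",
                            "odds_ratio", "benefit")], 5)
#>    stratum delta_easi delta_easi_p pct_bas auroc   ppv   npv odds_ratio benefit
#> 1 P0115^lo      -64.3     5.49e-02    30.0 0.867 0.750 0.929       39.0   FALSE
#> 2 P0060^lo      -64.0     3.42e-02    21.4 0.857 0.833 0.875       35.0   FALSE
#> 3 P0003^lo      -86.7     2.15e-05    45.7 0.848 0.700 1.000       53.6    TRUE
#> 4 P0092^lo      -64.6     3.39e-03    60.0 0.848 0.636 1.000       38.3    TRUE
#> 5 P0001^hi      -68.2     2.50e-03    32.9 0.838 0.636 1.000       38.3    TRUE
```

Each row is one candidate marker: its favorable stratum, the
active-vs-placebo difference in week-4 EASI percent change inside that
stratum with its p-value, the stratum's share of the biomarker analysis set,
the active-arm AUROC against responder status, predictive values, the
(corrected where needed) odds ratio, and the dual-endpoint benefit flag.
Two of the generator's planted markers (`P0001^hi`, `P0003^lo`) surface with
benefit = TRUE; the top false positives illustrate the in-sample optimism of
an AUROC screen at n = 20, which the test suite quantifies against
permutation oracles. `run1/` also receives `combo_table.csv` (two-marker
unions and pp thresholds), exploratory outputs, and a `manifest.json` with
content hashes — rerunning the same config reproduces identical files.

A thin CLI wraps the same functions:

```sh
exec/predstrat run-all --out run1 --seed 1
```

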