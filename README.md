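# iopgrs

Additive genetic risk scores (GRS) for intraocular pressure (IOP) in
primary open-angle glaucoma (POAG) case-control cohorts.

A handful of common variants raise IOP additively. For a clinician or
statistical geneticist asking whether that aggregate burden tracks IOP
itself, optic-disc damage (vertical cup-to-disc ratio, VCDR) and the
high-tension vs normal-tension (HTG/NTG) phenotype split, `iopgrs`
provides the full analysis chain as tidyverse-style, tibble-in/tibble-out
functions:

* **Scores** — unweighted GRS (risk-allele count over a nine-variant
  panel, range 0–18) and weighted GRS
  (`sum(dosage_v * ln OR_v)` with per-variant odds ratios from logistic
  regression): `grs_unweighted()`, `grs_weighted()`,
  `estimate_allele_ors()`.
* **Association stages** — multiple linear regression with standardized
  coefficients (`beta = b * sd(x)/sd(y)`; `standardized_lm()` plus
  wrappers `iop_on_variants()`, `iop_on_grs()`, `vcdr_on_grs()`,
  `iop_vcdr_correlation()`), one-way ANOVA with Bonferroni post hoc
  t-tests at `p < 0.05/3` (`anova_bonferroni()`), and age/sex-adjusted
  logistic regression of diagnosis on the GRS
  (`logistic_group_on_grs()`).
* **Cutoff enrichment** — the relative ratio `(a/b)/(A/B)` of
  case:control composition above a score threshold versus the full
  sample, with partition chi-square tests and a full 0–18 threshold scan:
  `relative_ratio()`, `cutoff_table()`, `cutoff_scan()`.
* **Synthetic cohorts** — a calibrated two-liability generator
  (Hardy-Weinberg genotypes, additive latent IOP, a log-normal
  observed-maximum tail above 22 mmHg, VCDR linked to IOP and glaucoma
  status, quota rejection sampling into control/NTG/HTG groups):
  `generator_params()`, `sample_cohort()`, `simulate_case_control()`,
  `calibrate_defaults()`. No participant-level data are deposited for
  cohorts of this design; the generator makes every stage testable end to
  end.

Results are plain tibbles or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()` figures. `run_pipeline()` +
`pipeline_config()` orchestrate simulate → score → associate → cutoff
into a JSON report; a thin CLI lives at `inst/cli/iopgrs.R`.

## Worked example

Simulate a cohort at the default study scale (246 controls, 261 NTG, 255
HTG) and run the stages:

```r
library(iopgrs)

cohort <- sample_cohort(generator_params(), seed = 42)
d <- cohort_data(cohort)   # phenotypes + dosages + unweighted GRS

tidy(iop_on_grs(d))
#> # A tibble: 3 × 6
#>   term      estimate     se beta_standardized statistic  p_value
#>   <chr>        <dbl>  <dbl>             <dbl>     <dbl>    <dbl>
#> 1 age_years   -0.106 0.0212            -0.173     -5.01 6.61e- 7
#> 2 male         3.99  0.591              0.233      6.75 2.89e-11
#> 3 grs          0.443 0.141              0.108      3.14 1.78e- 3
```

Each additional risk allele raises the recorded maximum IOP by ~0.44 mmHg
in this draw (standardized beta 0.11, p = 0.002), with male sex and
younger age also associated — the expected pattern when genetic IOP
elevation drives case status.

```r
anova_bonferroni(d)
#> <grs_anova> F(2, 759) = 3.775, p = 0.02337
#> # A tibble: 3 × 4
#>   group       n  mean    sd
#> 1 control   246  8.67  2.06
#> 2 HTG       255  8.99  2.20
#> 3 NTG       261  8.49  1.99
#> pairwise (threshold p < 0.0167):
#>   pair           p_unadjusted p_bonferroni significant
#> 1 HTG vs control      0.0846        0.254  FALSE
#> 2 NTG vs control      0.341         1      FALSE
#> 3 NTG vs HTG          0.00681       0.0204 TRUE

cutoff_table(d, threshold = 12)[, c("a", "b", "relative_ratio")]
#> # A tibble: 1 × 3
#>       a     b relative_ratio
#> 1    32    24           1.29
```

The HTG group carries the highest mean score (8.99 vs 8.67 in controls;
NTG lowest, as its cases arise from IOP-independent vulnerability), and
participants with GRS ≥ 12 are case-enriched (relative ratio 1.29 against
the whole sample's ratio set to 1). Single cohorts at this sample size
fluctuate — which pairwise contrast clears the Bonferroni threshold
varies by seed; the calibrated *expectations* (control mean IOP
15.0 mmHg, NTG 18.4, GRS 8.7/9.1, IOP–VCDR standardized beta ≈ 0.48) are
reproduced tightly on large strata, as the acceptance script below
demonstrates. On the headline published counts the statistic reproduces
exactly: `relative_ratio(29, 11, 255, 246)` is 2.54.

See `vignette("iopgrs-methods")` for the generative model, its calibrated
defaults and the package's statistical conventions.

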