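# vitdmr

Two-sample Mendelian randomisation (MR) of circulating
25-hydroxyvitamin D (25(OH)D) levels on glioma risk, from summary
statistics only.

Whether vitamin D protects against glioma cannot be settled by
observational studies: sun exposure, season, diet and health behaviour
confound any measured association.  MR uses genetic variants as
instrumental variables — alleles that raise or lower 25(OH)D are
assigned at random at conception — to estimate the causal effect of the
exposure on the outcome free of those confounders.  `vitdmr` implements
the complete summary-statistic pipeline for this question:

* a built-in four-variant 25(OH)D instrument
  (`builtin_sunlight_instruments()`: rs2282679 in *GC*, rs10741657 near
  *CYP2R1*, rs12785878 near *DHCR7*, rs6013897 in *CYP24A1*, coded on
  the 25(OH)D-decreasing allele, with per-allele effects, SEs and
  F-statistics),
* allele harmonization of exposure and outcome tables, with explicit
  handling of palindromic variants and a full audit log,
* three causal estimators on harmonized instruments:
  inverse-variance weighted (IVW),

  β̂ = Σₖ XₖYₖσ_Yₖ⁻² / Σₖ Xₖ²σ_Yₖ⁻² ,  se(β̂) = (Σₖ Xₖ²σ_Yₖ⁻²)^(−1/2),

  bivariate-normal maximum likelihood (Xₖ ~ N(ξₖ, σ_Xₖ²),
  Yₖ ~ N(βξₖ, σ_Yₖ²), which unlike IVW propagates exposure-side error),
  and MR-Egger regression (slope + pleiotropy intercept),
* per-cohort estimation with fixed-effect meta-analysis across the
  eight glioma GWAS cohorts, and forest-plot data export,
* stratified (synthesis vs metabolism variants) and
  exclusion (rs12785878) sensitivity analyses, Bonferroni thresholds,
  and binary-outcome MR power calculations
  (|log OR| = (z₁₋α/₂ + z_power)/√(N·r²·K(1−K))),
* a synthetic multi-cohort data generator with known ground truth
  (`simulate_dataset()`, `scenario_presets()`, `mr_mc_study()`) used to
  verify unbiasedness, coverage, size and pleiotropy detection.

## Worked example

Reproduce a published-style cell from its log-OR and SE — the GBM
maximum-likelihood estimate:

```r
library(vitdmr)
wald_summary(-0.479, 0.186)
#> $or      0.619     # OR 0.62
#> $ci_low  0.430     # 95% CI 0.43 ...
#> $ci_high 0.892     # ... to 0.89
#> $p       0.010     # two-sided P
```

An OR of 0.62 means the odds of GBM are an estimated 38% lower per unit
increase in genetically proxied 25(OH)D; the CI excluding 1 at
P = 0.010 clears the Bonferroni threshold of 0.017 for three tumour
classifications.

Run the full pipeline on a synthetic dataset that mirrors the real
study (four real instruments, eight cohorts, 12,488 cases / 18,169
controls, true OR 0.62):

```r
report <- run_analysis(run_config(scenario = "paper_like", seed = 42))
report
#> MR analysis report
#>      subtype method n_snps n_cohorts   beta    se    or ci_low ci_high      p
#> 1 all_glioma    IVW      4         8 -0.366 0.211 0.693  0.458    1.05 0.0826
#> 2 all_glioma    MLE      4         8 -0.378 0.221 0.685  0.444    1.06 0.0873
#> ...
#> Detectable ORs at target power:
#>     analysis n_cases n_controls   r2 alpha power or_harmful or_protective
#> 1 all_glioma   12488      18169 0.02  0.05   0.8       1.26         0.794
#> Bonferroni-corrected threshold: 0.017
```

This seed's draw estimates OR ≈ 0.69 against a generating truth of
0.62 — within one standard error; the power block shows why: with an
instrument explaining 2% of exposure variance, only ORs beyond
1.26/0.79 are detectable at 80% power.  `write_report()` exports the
report as full-precision JSON or display-rounded TSV, including the
per-cohort forest-plot table and the harmonization log.

Real outcome data are supplied as TSV
(`read_outcome_table()`; columns snp_id, alleles, log-OR, SE, cohort,
subtype) and analysed with
`run_config(exposure = "builtin", outcome = "path.tsv", scenario = NULL)`.
A thin command-line wrapper with `run`, `simulate`, `power` and
`validate` subcommands ships in `inst/cli/mr_pipeline.R`.

## Vignette

`vignettes/vitamin-d-glioma-mr.Rmd` documents the models, assumptions,
numerical choices, the design of the synthetic-data generator, and the
package's known limitations.
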