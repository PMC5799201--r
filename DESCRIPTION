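Package: vitdmr
Title: Two-Sample Mendelian Randomisation of Circulating Vitamin D on
    Glioma Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Summary-statistic Mendelian randomisation pipeline for
    estimating the causal effect of serum 25-hydroxyvitamin D (25(OH)D)
    levels on glioma risk.  Provides allele harmonization of exposure and
    outcome association tables, inverse-variance weighted,
    bivariate-normal maximum likelihood and MR-Egger causal estimators,
    per-cohort fixed-effect meta-analysis with forest-plot data export,
    stratified and leave-out sensitivity analyses, binary-outcome power
    calculations, and a synthetic multi-cohort data generator with known
    ground truth for calibration studies.  Ships the four-SNP 25(OH)D
    instrument set (GC, CYP2R1, DHCR7, CYP24A1) as a built-in fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
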