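---
title: "Summary-statistic Mendelian randomisation of vitamin D and glioma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistic Mendelian randomisation of vitamin D and glioma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the design

Observational studies of circulating 25-hydroxyvitamin D (25(OH)D) and
cancer risk are confounded by behaviour, latitude, season and reverse
causation.  Mendelian randomisation (MR) sidesteps these by using
genetic variants as instrumental variables: alleles are assigned at
conception, so a variant that raises 25(OH)D levels is a randomised,
lifelong "dose" of the exposure.  In the two-sample design only summary
statistics are needed — per-allele effects of each variant on 25(OH)D
from one study population, and per-allele log odds ratios of each
variant on glioma from another.

`vitdmr` implements this design end to end for the glioma question: a
four-variant instrument for 25(OH)D (`builtin_sunlight_instruments()`;
rs2282679 in *GC*, rs10741657 near *CYP2R1*, rs12785878 near *DHCR7*,
rs6013897 in *CYP24A1*, all coded on the 25(OH)D-decreasing allele),
outcome associations from eight glioma GWAS cohorts (FRE, GER, GICC,
MDA, NIH, UCSF-Mayo, UCSF, UK; 12,488 cases and 18,169 controls in
total), and three tumour classifications (all glioma, GBM, non-GBM).

The validity of any MR estimate rests on three assumptions: the
instrument is associated with the exposure (checked by the per-variant
F-statistics), it is independent of confounders, and it affects the
outcome only through the exposure (no horizontal pleiotropy; probed by
MR-Egger and the stratified and exclusion sensitivity analyses).

## Harmonization

Exposure and outcome tables rarely code the same effect allele.
`harmonize_pair()` resolves the four possible orientations — identical
labels, swapped labels (the outcome effect is negated), strand
complement, and complement-plus-swap — and records an explicit action
for every pair; nothing is dropped silently, because a silently lost
SNP changes every downstream estimate.

Palindromic variants (A/T or C/G; rs6013897 is one) cannot be
orientated from labels alone.  The default policy compares effect-allele
frequencies: both must be available and outside the window
0.5 ± `palindromic_freq_window` (default 0.08, conventional in
summary-data MR); frequencies on the same side of 0.5 confirm the
label orientation, opposite sides imply a strand flip, anything else
excludes the variant with reason `"palindromic_ambiguous"`.  The
original studies state only that frequencies were compared, so the
window rule is this package's documented operationalisation, and
`palindromic = "keep"` is available for outcome tables known to be on
the same strand.

Instrument independence is asserted against a user-supplied pairwise
r² matrix (`check_ld_independence()`, threshold 0.001); computing LD
from a reference panel is out of scope, and with no matrix the pairs
are reported unchecked rather than assumed independent.

Estimates are presented per unit *increase* in 25(OH)D
(`orient_to_increasing()`), so OR < 1 reads "higher vitamin D is
protective".  All three estimators are invariant to jointly negating
(x, y), so this is presentation only — a fact the test suite checks.

## The three estimators

For harmonized instrument k, let $X_k$ (SE $\sigma_{X_k}$) be the
exposure association and $Y_k$ (SE $\sigma_{Y_k}$) the outcome log-OR.

**IVW.** The fixed-effects inverse-variance weighted estimate is

$$\hat\beta = \frac{\sum_k X_k Y_k \sigma_{Y_k}^{-2}}
                   {\sum_k X_k^2 \sigma_{Y_k}^{-2}},
\qquad
\mathrm{se}(\hat\beta) = \sqrt{\frac{1}{\sum_k X_k^2 \sigma_{Y_k}^{-2}}},$$

equivalent to weighted regression of $Y$ on $X$ through the origin and,
at a single SNP, the Wald ratio $Y/X$.  Exposure-side error is ignored
(the no-measurement-error approximation).

**Maximum likelihood.** The bivariate-normal errors-in-variables model
$X_k \sim N(\xi_k, \sigma_{X_k}^2)$,
$Y_k \sim N(\beta\,\xi_k, \sigma_{Y_k}^2)$ is maximised over
$(\xi_1,\dots,\xi_K, \beta)$.  Unlike IVW this propagates exposure-side
uncertainty — material here, where the weakest instrument (rs6013897)
has F ≈ 3.  `se(β)` comes from the observed information.

**MR-Egger.** Weighted regression of $Y$ on $X$ *with* an intercept,
after orienting all $X_k \ge 0$.  Under the InSIDE assumption the slope
is a pleiotropy-robust causal estimate and the intercept estimates the
average direct (pleiotropic) effect; a non-zero intercept flags
directional pleiotropy.

Pooling across the eight cohorts follows the source design: IVW and MLE
are estimated within each cohort and combined by fixed-effect
inverse-variance meta-analysis (`fixed_effect_meta()`), with Cochran's
Q and I² logged as diagnostics only.  `forest_data()` exports the
per-cohort ORs, CIs and normalized weights that forest plots are drawn
from.

### Why MR-Egger pools SNP effects first

MR-Egger defaults to the opposite order: each SNP's outcome effect is
first pooled across cohorts (`pool_snp_effects()`) and a single Egger
regression is run on the four pooled effects.  The reason is that a
pleiotropic direct effect belongs to the SNP and is therefore
*identical* in every cohort; per-cohort Egger intercepts are eight
strongly correlated readings of the same quantity, and meta-analysing
them as if independent understates the intercept's standard error by
roughly √8.  In simulation that mis-pooling rejected a true
balanced-pleiotropy null about seven times too often, which is why the
per-cohort order, though available via `egger_order = "per_cohort"`,
is not the default.

## Numerical choices

* **MLE optimisation** — BFGS with the analytic gradient, initialised at
  the IVW solution with $\xi_k = X_k$; parameters scaled by
  (|β₀|, σ_X); gradient tolerance 1e-8 scaled by the total precision
  weight; up to three jittered restarts before an error is raised with
  the optimizer trace.
* **MLE standard error** — numerical Hessian at the optimum
  (`stats::optimHess`, central differences with magnitude-scaled
  steps); the β-information is extracted by Schur complement against
  the diagonal ξ-block, which stays stable as σ_X → 0, where the MLE
  provably collapses to IVW (a tested limit).
* **Egger variance model** — unscaled weighted-least-squares covariance
  multiplied by max(1, residual SD): the standard multiplicative
  random-effects treatment, so balanced pleiotropy widens the intervals
  instead of biasing the test.  P values are two-sided normal by
  default, consistent with IVW/MLE; with only K − 2 = 2 residual
  degrees of freedom the exact reference is t(2), available via
  `t_dist`/`egger_t`, and it is the configuration under which the
  intercept test's size is verified.  With four instruments the
  exact-reference intercept test is calibrated but has very little
  power — Egger results on this instrument set are a consistency check,
  not a powered test.
* **P values** are floored at the smallest positive double so they stay
  in (0, 1]; every reported OR equals exp(β) exactly; CIs are
  `exp(β ± z·se)`.
* **Display rounding** (TSV reports) is β/SE to 3 dp, OR/CI to 2 dp,
  P to 3 dp; JSON reports keep full precision and round-trip exactly.
* **Degenerate inputs** are errors, not NAs: empty instrument sets,
  all-zero exposure effects, fewer than three SNPs for Egger, collinear
  exposure effects, non-positive SEs.

## The synthetic-data generator

`simulate_dataset()` draws data from exactly the bivariate-normal
summary model the estimators assume, which is what makes the
calibration claims sharp: true effects $\xi_k$, observed
$X_k \sim N(\xi_k, \sigma_{X_k}^2)$, and per cohort
$Y_{kc} \sim N(\beta \xi_k + \alpha_k, \sigma_{Y_{kc}}^2)$, with
$\alpha_k$ a per-SNP direct effect shared across cohorts (zero,
balanced around zero, or directional).  Outcome SEs use the standard
binary-trait GWAS approximation
$\sigma_Y = 1/\sqrt{2f(1-f)\,N\,K(1-K)}$, which at glioma-scale cohorts
makes the per-SNP signal weak (|Y/σ_Y| of order one), as in the real
data.

The `paper_like` scenario fixes the exposure side to the four real
instruments, splits 12,488 cases / 18,169 controls evenly across the
eight named cohorts (per-cohort counts are not published), assigns
realistic European effect-allele frequencies (0.28, 0.40, 0.23, 0.21),
and sets the causal effect to log(0.62), the GBM-scale protective
effect.  Its rs12785878 outcome record is emitted with swapped alleles,
as in the source glioma data, so the pipeline's sign-flip harmonization
is exercised end to end.  Pleiotropy scenarios use direct effects of
about OR 1.05 per SNP (balanced: mean 0, SD 0.05; directional:
mean 0.05, SD 0.02) — comparable in size to the causal signal itself.

What the generator does *not* emulate: linkage disequilibrium between
instruments, winner's-curse bias in the exposure effects, sample
overlap between the exposure and outcome studies, non-collapsibility of
the odds ratio, and individual-level case–control sampling (generation
is at the summary level, which is precisely the model the estimators
assume).  Passing calibration tests therefore validates the inference
machinery under its stated assumptions; it cannot certify those
assumptions in real data.

Monte-Carlo problem sizes in the test suite were chosen to make the
binomial tolerance bands meaningful while keeping the suite quick: 500
replicates for coverage, size and pleiotropy calibration, 100 for
stratum exchangeability, 60 for leave-one-out calibration.

## Sensitivity and power

`stratified_analysis()` re-estimates within the synthesis
(rs12785878, rs10741657) and metabolism (rs2282679, rs6013897) variant
groups; agreement between strata argues against pathway-specific
pleiotropy.  `exclusion_analysis()` drops rs12785878 — whose frequency
varies strongly with ancestry — to probe population-stratification
bias, reporting the shift against the full-set estimate.
`bonferroni_threshold(0.05, 3)` gives the 0.017 multiple-testing
threshold for the three tumour classifications.

Power uses the normal approximation for binary-outcome MR: with total
sample N, case fraction K, and instrument variance explained r²,

$$|\log \mathrm{OR}| = \frac{z_{1-\alpha/2} + z_{\mathrm{power}}}
                            {\sqrt{N\,r^2\,K(1-K)}}.$$

`detectable_or()` and `power_at_or()` are exact inverses (tested to
1e-6).  At the all-glioma sample size with r² = 0.02 the detectable ORs
at 80% power are about 1.26 and 0.79 — a reminder that a four-variant,
2%-of-variance instrument can only detect fairly large effects.
Subtype case counts are not published in the main text, so subtype
power needs user-supplied counts.

## Known limitations

* Four instruments is the minimum interesting K: Egger has 2 residual
  df, stratified analyses have 2 SNPs per stratum, and leave-one-out
  removes a quarter of the information.
* The exposure effects are reported on the source study's printed
  per-allele scale; estimates are per unit of that scale, not per
  nmol/L, and no rescaling is attempted.
* The combined-instrument F-statistic quoted by the source study for
  this instrument set has no stated derivation and is not reproduced by
  any operation here; per-SNP F-statistics are.
* Fixed-effect pooling assumes one common causal effect across cohorts;
  Q and I² are reported but a random-effects model is deliberately out
  of scope.
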