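#' Built-in 25(OH)D instrument set
#'
#' Returns the four genetic variants used as instruments for circulating
#' 25-hydroxyvitamin D levels: rs2282679 (*GC*, the vitamin D binding
#' protein), rs10741657 (near *CYP2R1*), rs12785878 (near *DHCR7*) and
#' rs6013897 (*CYP24A1*).  The effect allele is the 25(OH)D-*decreasing*
#' allele, so all exposure effects are negative.  Positions are 1-based
#' NCBI build 37 and are metadata only; they enter no computation.
#'
#' The first two variants act in vitamin D synthesis, the latter two in
#' its transport/metabolism; the `pathway` column records the synthesis
#' (rs12785878, rs10741657) versus metabolism (rs2282679, rs6013897)
#' stratification used by the stratified sensitivity analysis.
#'
#' `glioma_ea`/`glioma_nea` carry the allele labels under which the
#' glioma GWAS meta-analysis reported these SNPs; for rs12785878 they are
#' swapped relative to the exposure orientation, so harmonization against
#' an outcome table in that orientation must sign-flip the outcome effect.
#'
#' No effect-allele frequencies are part of the fixture (`eaf` is `NA`):
#' palindromic-ambiguity resolution by frequency is therefore unavailable
#' for rs6013897 (A/T) unless the user supplies frequencies.
#'
#' @return A `data.frame` with one row per SNP and columns `snp_id`,
#'   `chrom`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta_exposure` (per-allele effect on 25(OH)D), `se_exposure`,
#'   `f_stat` (single-SNP F-statistic), `locus`, `pathway`,
#'   `glioma_ea`, `glioma_nea`.
#' @examples
#' builtin_sunlight_instruments()
#' @export
builtin_sunlight_instruments <- function() {
  data.frame(
    snp_id        = c("rs2282679", "rs10741657", "rs12785878", "rs6013897"),
    chrom         = c("4", "11", "11", "20"),
    position      = c(72608383L, 14914878L, 71167449L, 52742479L),
    effect_allele = c("G", "G", "G", "A"),
    other_allele  = c("T", "A", "T", "T"),
    eaf           = NA_real_,
    beta_exposure = c(-0.047, -0.052, -0.056, -0.027),
    se_exposure   = c(0.013, 0.012, 0.013, 0.015),
    f_stat        = c(13.38, 18.78, 18.29, 3.13),
    locus         = c("GC", "Near CYP2R1", "Near DHCR7", "CYP24A1"),
    pathway       = c("metabolism", "synthesis", "synthesis", "metabolism"),
    glioma_ea     = c("G", "G", "T", "A"),
    glioma_nea    = c("T", "A", "G", "T"),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
.valid_pathways <- c("synthesis", "metabolism", "unknown")

#' @keywords internal
.valid_subtypes <- c("all_glioma", "GBM", "non_GBM")

#' @keywords internal
.paper_cohorts <- c("FRE", "GER", "GICC", "MDA", "NIH",
                    "UCSF-Mayo", "UCSF", "UK")
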