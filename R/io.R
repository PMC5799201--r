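#' @keywords internal
#' Apply a column-mapping dialect and check mandatory columns.
#' `dialect` maps canonical name -> file column name.
.map_columns <- function(df, dialect, mandatory, path) {
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (src %in% names(df) && !canon %in% names(df)) {
      names(df)[names(df) == src] <- canon
    }
  }
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0) {
    stop("format error in '", path, "': missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  df
}

#' Read an exposure-side (SNP to 25(OH)D) association table
#'
#' Tab-separated file with one row per instrument.  Column names can be
#' remapped through `dialect` (canonical name -> file header), since
#' published summary files rarely share a layout; the default dialect
#' accepts the package's own writer plus common GWAS headers.
#'
#' @param path TSV file path.
#' @param dialect Named list mapping canonical column names (`snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf`, `f_stat`, `chrom`, `position`, `locus`, `pathway`) to the
#'   file's headers.
#' @return data.frame of exposure associations (allele strings
#'   upper-cased, one row per SNP).
#' @export
read_exposure_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- utils::modifyList(
    list(snp_id = "SNP", effect_allele = "EA", other_allele = "NEA",
         beta_exposure = "beta", se_exposure = "se", eaf = "EAF"),
    dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df[, intersect(names(df), names(df)), drop = FALSE])
  df <- .map_columns(df, dialect,
                     c("snp_id", "effect_allele", "other_allele",
                       "beta_exposure", "se_exposure"), path)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  bad_se <- which(!is.finite(df$se_exposure) | df$se_exposure <= 0)
  if (length(bad_se) > 0) {
    stop("format error in '", path, "': non-positive se_exposure on row(s) ",
         paste(bad_se, collapse = ", "))
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplication error in '", path, "': duplicate snp_id: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  }
  bad_al <- which(!(df$effect_allele %in% c("A", "C", "G", "T")) |
                  !(df$other_allele %in% c("A", "C", "G", "T")) |
                  df$effect_allele == df$other_allele)
  if (length(bad_al) > 0) {
    stop("format error in '", path, "': invalid allele pair on row(s) ",
         paste(bad_al, collapse = ", "))
  }
  if ("pathway" %in% names(df) &&
      !all(df$pathway %in% .valid_pathways)) {
    stop("vocabulary error in '", path, "': pathway must be one of ",
         paste(.valid_pathways, collapse = ", "))
  }
  if (!"pathway" %in% names(df)) df$pathway <- "unknown"
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  df
}

#' Read an outcome-side (SNP to glioma) association table
#'
#' Tab-separated per-cohort, per-subtype log-OR summary file.  `cohort`
#' and `subtype` may be columns of the file or supplied as constants.
#'
#' @inheritParams read_exposure_table
#' @param cohort,subtype Constants used when the file lacks the column.
#' @return data.frame of outcome associations, retrievably grouped by
#'   `(cohort, subtype)`.
#' @export
read_outcome_table <- function(path, dialect = list(), cohort = NULL,
                               subtype = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- utils::modifyList(
    list(snp_id = "SNP", effect_allele = "EA", other_allele = "NEA",
         beta_outcome = "beta", se_outcome = "se", eaf = "EAF"),
    dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  df <- .map_columns(df, dialect,
                     c("snp_id", "effect_allele", "other_allele",
                       "beta_outcome", "se_outcome"), path)
  if (!"cohort" %in% names(df)) {
    if (is.null(cohort)) stop("format error in '", path,
                              "': no cohort column and no cohort constant supplied")
    df$cohort <- cohort
  }
  if (!"subtype" %in% names(df)) {
    if (is.null(subtype)) stop("format error in '", path,
                               "': no subtype column and no subtype constant supplied")
    df$subtype <- subtype
  }
  if (!all(df$subtype %in% .valid_subtypes)) {
    stop("vocabulary error in '", path, "': subtype must be one of ",
         paste(.valid_subtypes, collapse = ", "), "; got: ",
         paste(setdiff(unique(df$subtype), .valid_subtypes), collapse = ", "))
  }
  if (any(!nzchar(df$cohort))) stop("format error in '", path, "': empty cohort label")
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  bad_se <- which(!is.finite(df$se_outcome) | df$se_outcome <= 0)
  if (length(bad_se) > 0) {
    stop("format error in '", path, "': non-positive se_outcome on row(s) ",
         paste(bad_se, collapse = ", "))
  }
  if ("eaf" %in% names(df)) {
    bad_f <- which(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1))
    if (length(bad_f) > 0) {
      stop("format error in '", path, "': eaf outside (0,1) on row(s) ",
           paste(bad_f, collapse = ", "))
    }
  } else {
    df$eaf <- NA_real_
  }
  df
}

#' @keywords internal
.meta_to_row <- function(m) {
  p <- m$pooled
  data.frame(subtype = m$subtype, method = m$method, n_snps = p$n_snps,
             n_cohorts = nrow(m$components), beta = p$beta, se = p$se,
             or = p$or, ci_low = p$ci_low, ci_high = p$ci_high, p = p$p,
             Q = m$Q, I2 = m$I2, stringsAsFactors = FALSE)
}

#' @keywords internal
#' Main-results table of a report: one row per (subtype, method).
report_main_table <- function(report) {
  rows <- list()
  for (st in names(report$results)) {
    for (m in names(report$results[[st]]$meta)) {
      rows[[paste(st, m)]] <- .meta_to_row(report$results[[st]]$meta[[m]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
report_egger_table <- function(report) {
  rows <- list()
  for (st in names(report$results)) {
    e <- report$results[[st]]$egger
    if (is.null(e)) next
    s <- e$slope
    rows[[st]] <- data.frame(
      subtype = st,
      slope = s$beta, slope_ci_low = log(s$ci_low),
      slope_ci_high = log(s$ci_high), slope_p = s$p,
      intercept = e$intercept$estimate,
      intercept_ci_low = e$intercept$ci_low,
      intercept_ci_high = e$intercept$ci_high,
      intercept_p = e$intercept$p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis report to disk
#'
#' `format = "json"` serializes the full-precision report (it round-trips
#' through [read_report()]).  `format = "tsv"` writes a human-readable
#' multi-section file at the display precision used throughout
#' (beta/SE 3 dp, OR/CI 2 dp, P 3 dp): main results, MR-Egger, forest
#' data per (subtype, method), sensitivity, power and the harmonization
#' log.  Sections absent from the report are marked absent, not errors.
#'
#' @param report An `mr_report` from [run_analysis()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- .report_to_jsonable(report)
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to path: ", path)
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  tsv <- function(df) {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rnd <- function(df, cols3 = c("beta", "se", "p", "Q", "I2", "slope",
                                "slope_p", "intercept", "intercept_p",
                                "intercept_ci_low", "intercept_ci_high",
                                "slope_ci_low", "slope_ci_high",
                                "delta_beta", "weight"),
                  cols2 = c("or", "ci_low", "ci_high")) {
    for (cc in intersect(cols3, names(df))) df[[cc]] <- round(df[[cc]], 3)
    for (cc in intersect(cols2, names(df))) df[[cc]] <- round(df[[cc]], 2)
    df
  }

  w("## mr_report")
  w("## main_results")
  tsv(rnd(report_main_table(report)))
  w("")
  w("## egger")
  eg <- report_egger_table(report)
  if (is.null(eg)) w("# section absent") else tsv(rnd(eg))
  w("")
  w("## forest")
  for (st in names(report$results)) {
    for (m in names(report$results[[st]]$meta)) {
      fd <- forest_data(report$results[[st]]$meta[[m]])
      fd$subtype <- st; fd$method <- m
      tsv(rnd(fd))
      w("")
    }
  }
  w("## sensitivity")
  if (is.null(report$sensitivity)) w("# section absent")
  else {
    for (nm in names(report$sensitivity)) {
      w("# ", nm)
      tsv(rnd(report$sensitivity[[nm]]))
      w("")
    }
  }
  w("## power")
  if (is.null(report$power)) w("# section absent") else tsv(rnd(report$power))
  w("")
  w("## harmonization_log")
  tsv(report$harmonization_log)
  invisible(path)
}

#' @keywords internal
.report_to_jsonable <- function(report) {
  unclass_deep <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), unclass_deep))
    x
  }
  unclass_deep(report)
}

#' Read back a JSON analysis report
#'
#' @param path Path written by [write_report(..., format = "json")].
#' @return The report as nested lists/data.frames; all numeric fields
#'   are preserved at full precision.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
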