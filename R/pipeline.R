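#' Build a run configuration for the end-to-end analysis
#'
#' @param scenario Name of a simulation scenario ([scenario_presets()]),
#'   or `NULL` to read data from files.
#' @param exposure Path to an exposure table, or `"builtin"` for the
#'   shipped 25(OH)D instrument set; ignored when `scenario` is set.
#' @param outcome Path to an outcome table (must carry or be given
#'   `cohort`/`subtype`); ignored when `scenario` is set.
#' @param outcome_dialect,exposure_dialect Column-mapping dialects for
#'   the readers.
#' @param subtypes Subtypes to analyse (subset of `all_glioma`, `GBM`,
#'   `non_GBM`); defaults to whatever the outcome data contains.
#' @param methods Estimators to run.
#' @param meta Pool cohorts by fixed-effect meta-analysis (the
#'   alternative — pooling SNP effects across cohorts before a single
#'   estimation — is available as `meta = "pool_snps_first"` for
#'   comparison).
#' @param strata Stratified sensitivity analysis: column name or named
#'   map (see [stratified_analysis()]); `NULL` disables.
#' @param exclude SNPs for the exclusion sensitivity analysis; `NULL`
#'   disables.
#' @param power_specs Named list of [power_spec()]s (one per analysis).
#' @param alpha Significance/CI level.
#' @param bonferroni_m Number of tests for the multiple-testing
#'   threshold (3 tumour classifications).
#' @param ld_matrix Optional labelled square r^2 matrix (or TSV path).
#' @param ld_threshold Independence cutoff.
#' @param egger_order `"pool_snps_first"` (default; one Egger regression
#'   on cohort-pooled per-SNP effects) or `"per_cohort"`.
#' @param egger_t Use a t(K-2) reference for Egger inference.
#' @param palindromic Palindromic-SNP policy (see [harmonize_pair()]).
#' @param seed Seed for any simulation.
#' @param keep_going Continue past a failing subtype instead of
#'   aborting.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = NULL, exposure = "builtin", outcome = NULL,
                       exposure_dialect = list(), outcome_dialect = list(),
                       subtypes = NULL,
                       methods = c("IVW", "MLE", "Egger"),
                       meta = TRUE,
                       strata = "pathway",
                       exclude = "rs12785878",
                       power_specs = list(all_glioma = power_spec(12488, 18169)),
                       alpha = 0.05, bonferroni_m = 3,
                       ld_matrix = NULL, ld_threshold = 0.001,
                       egger_order = "pool_snps_first", egger_t = FALSE,
                       palindromic = "freq",
                       seed = 1L, keep_going = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a run configuration
#'
#' Always returns (never throws): an empty character vector means the
#' configuration is runnable; otherwise each element names the offending
#' field and a remedy.
#'
#' @param config A [run_config()].
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  known_scen <- c("null", "causal", "balanced_pleiotropy",
                  "directional_pleiotropy", "paper_like")
  if (!is.null(config$scenario)) {
    if (!config$scenario %in% known_scen) {
      add(paste0("scenario: unknown name '", config$scenario,
                 "'; use one of ", paste(known_scen, collapse = ", ")))
    }
  } else {
    if (!identical(config$exposure, "builtin") &&
        (is.null(config$exposure) || !file.exists(config$exposure))) {
      add("exposure: supply 'builtin' or an existing file path")
    }
    if (is.null(config$outcome)) {
      add("outcome: supply an outcome table path or set a scenario")
    } else if (!file.exists(config$outcome)) {
      add(paste0("outcome: file not found: ", config$outcome))
    }
  }
  if (length(config$methods) == 0 ||
      !all(config$methods %in% c("IVW", "MLE", "Egger"))) {
    add("methods: need at least one of IVW, MLE, Egger")
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    add("alpha: must lie in (0, 1)")
  }
  if (!is.numeric(config$bonferroni_m) || config$bonferroni_m < 1) {
    add("bonferroni_m: must be >= 1")
  }
  if (!is.null(config$subtypes) &&
      !all(config$subtypes %in% .valid_subtypes)) {
    add(paste0("subtypes: must be a subset of ",
               paste(.valid_subtypes, collapse = ", ")))
  }
  if (!is.null(config$power_specs) &&
      !all(vapply(config$power_specs, inherits, logical(1), "power_spec"))) {
    add("power_specs: every entry must be a power_spec()")
  }
  problems
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments;
#' `power_specs` is a map of name -> {n_cases, n_controls, r2, alpha,
#' power}.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$power_specs)) {
    y$power_specs <- lapply(y$power_specs, function(p) do.call(power_spec, p))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Run the full summary-statistic MR analysis
#'
#' Executes read (or simulate), harmonize, orient to the
#' increasing-25(OH)D scale, per-cohort estimation, fixed-effect
#' pooling, MR-Egger pleiotropy testing, stratified and exclusion
#' sensitivity analyses, and power calculation, and assembles an
#' `mr_report`.  Identical configuration and seed give an identical
#' report.
#'
#' @param config A [run_config()].
#' @return Object of class `mr_report` with components `results` (per
#'   subtype: `meta` per method, `egger`), `sensitivity`, `power`
#'   (detectable ORs per supplied spec), `bonferroni_threshold`,
#'   `ld_check`, `harmonization_log`, `provenance`.
#' @export
run_analysis <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }

  input_files <- character(0)
  if (!is.null(config$scenario)) {
    sim <- simulate_dataset(scenario_presets(config$scenario, seed = config$seed))
    exposure <- sim$exposure
    outcome <- sim$outcome
  } else {
    exposure <- if (identical(config$exposure, "builtin"))
      builtin_sunlight_instruments()
    else read_exposure_table(config$exposure, config$exposure_dialect)
    outcome <- read_outcome_table(config$outcome, config$outcome_dialect)
    input_files <- c(exposure = if (identical(config$exposure, "builtin"))
      "builtin" else config$exposure, outcome = config$outcome)
  }

  ld <- config$ld_matrix
  if (is.character(ld) && length(ld) == 1) {
    ld <- as.matrix(utils::read.delim(ld, row.names = 1, check.names = FALSE))
  }
  ld_check <- withCallingHandlers(
    check_ld_independence(exposure$snp_id, ld, config$ld_threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  if (isTRUE(any(ld_check$independent == FALSE))) {
    dep <- ld_check[which(ld_check$independent == FALSE), ]
    stop("instruments not independent at r2 >= ", config$ld_threshold, ": ",
         paste(paste(dep$snp_a, dep$snp_b, sep = "/"), collapse = ", "))
  }

  h_all <- suppressWarnings(
    harmonize_dataset(exposure, outcome, palindromic = config$palindromic))
  hlog <- unique(h_all[, c("snp_id", "action", "sign_change",
                           "exclusion_reason")])
  rownames(hlog) <- NULL

  subtypes <- config$subtypes
  if (is.null(subtypes)) subtypes <- unique(h_all$subtype)

  results <- list(); sensitivity <- list()
  for (st in subtypes) {
    h <- h_all[h_all$subtype == st, , drop = FALSE]
    h <- orient_to_increasing(h)
    step <- function() {
      n_active <- length(unique(h$snp_id[h$action != "excluded"]))
      message("subtype ", st, ": ", n_active, " instrument(s), ",
              length(unique(h$cohort)), " cohort(s)")
      fit <- estimate_by_cohort(h, methods = config$methods,
                                alpha = config$alpha,
                                egger_order = config$egger_order,
                                egger_t = config$egger_t)
      res <- list(meta = fit$meta, egger = fit$egger)
      sens <- list()
      if (!is.null(config$strata)) {
        sens$stratified <- stratified_analysis(
          h, strata = config$strata,
          methods = setdiff(config$methods, "Egger"), alpha = config$alpha)
      }
      if (!is.null(config$exclude) && length(config$exclude) > 0) {
        sens$exclusion <- exclusion_analysis(
          h, drop = intersect(config$exclude, unique(h$snp_id)),
          methods = setdiff(config$methods, "Egger"), alpha = config$alpha)
      }
      list(res = res, sens = sens)
    }
    got <- if (config$keep_going) tryCatch(step(), error = function(e) {
      warning("subtype ", st, " failed: ", conditionMessage(e))
      NULL
    }) else step()
    if (is.null(got)) next
    results[[st]] <- got$res
    for (nm in names(got$sens)) sensitivity[[paste(st, nm, sep = ".")]] <- got$sens[[nm]]
  }
  if (length(results) == 0) stop("estimation failed for every subtype")

  power <- NULL
  if (!is.null(config$power_specs) && length(config$power_specs) > 0) {
    power <- do.call(rbind, lapply(names(config$power_specs), function(nm) {
      sp <- config$power_specs[[nm]]
      d <- detectable_or(sp)
      data.frame(analysis = nm, n_cases = sp$n_cases,
                 n_controls = sp$n_controls, r2 = sp$r2, alpha = sp$alpha,
                 power = sp$power, or_harmful = unname(d["or_harmful"]),
                 or_protective = unname(d["or_protective"]),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    results = results,
    sensitivity = if (length(sensitivity)) sensitivity else NULL,
    power = power,
    bonferroni_threshold = bonferroni_threshold(config$alpha,
                                                config$bonferroni_m),
    ld_check = ld_check,
    harmonization_log = hlog,
    provenance = list(
      package_version = as.character(utils::packageVersion("vitdmr")),
      seed = config$seed,
      scenario = config$scenario,
      input_files = as.list(input_files),
      methods = config$methods,
      alpha = config$alpha
    )
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR analysis report\n")
  print(report_main_table(x), digits = 3)
  eg <- report_egger_table(x)
  if (!is.null(eg)) {
    cat("\nMR-Egger (pooled):\n")
    print(eg, digits = 3)
  }
  if (!is.null(x$power)) {
    cat("\nDetectable ORs at target power:\n")
    print(x$power, digits = 3)
  }
  cat("\nBonferroni-corrected threshold: ",
      format(round(x$bonferroni_threshold, 3)), "\n", sep = "")
  invisible(x)
}
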