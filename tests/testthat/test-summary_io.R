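test_that("builtin instrument set matches the published table and is byte-stable", {
  instr <- builtin_sunlight_instruments()
  expect_equal(nrow(instr), 4)
  expect_identical(instr, builtin_sunlight_instruments())
  expect_true(all(instr$beta_exposure < 0))  # decreasing-allele orientation
  expect_true(all(instr$se_exposure > 0))
  expect_true(all(instr$f_stat > 0))
  expect_true(all(instr$effect_allele != instr$other_allele))
  expect_true(all(c(instr$effect_allele, instr$other_allele) %in% c("A", "C", "G", "T")))

  gc <- instr[instr$snp_id == "rs2282679", ]
  expect_equal(gc$beta_exposure, -0.047)
  expect_equal(gc$se_exposure, 0.013)
  expect_equal(gc$f_stat, 13.38)
  expect_equal(instr$f_stat[instr$snp_id == "rs6013897"], 3.13)
  expect_equal(instr$pathway[instr$snp_id == "rs12785878"], "synthesis")
  expect_setequal(instr$snp_id[instr$pathway == "synthesis"],
                  c("rs12785878", "rs10741657"))
  expect_setequal(instr$snp_id[instr$pathway == "metabolism"],
                  c("rs2282679", "rs6013897"))
})

test_that("exposure reader enforces the table contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  instr <- builtin_sunlight_instruments()
  write.table(instr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_exposure_table(f)
  expect_equal(back$beta_exposure, instr$beta_exposure)
  expect_equal(back$snp_id, instr$snp_id)
  expect_equal(back[back$snp_id == "rs2282679", "se_exposure"], 0.013)

  # header-only file -> empty result
  writeLines("snp_id\teffect_allele\tother_allele\tbeta_exposure\tse_exposure", f)
  expect_equal(nrow(read_exposure_table(f)), 0)

  # zero SE names the offending row
  bad <- instr; bad$se_exposure[2] <- 0
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_exposure_table(f), "row\\(s\\) 2")

  # duplicate snp_id
  dup <- rbind(instr, instr[1, ])
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_exposure_table(f), "duplicate snp_id: rs2282679")

  # missing mandatory column is named
  write.table(instr[, setdiff(names(instr), "se_exposure")], f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_exposure_table(f), "se_exposure")

  # dialect remaps foreign headers; alleles are upper-cased
  alt <- data.frame(rsid = "rs1", A1 = "a", A2 = "g", b = 0.1, sb = 0.02)
  write.table(alt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_exposure_table(f, dialect = list(
    snp_id = "rsid", effect_allele = "A1", other_allele = "A2",
    beta_exposure = "b", se_exposure = "sb"))
  expect_equal(got$effect_allele, "A")
  expect_equal(got$other_allele, "G")
})

test_that("outcome reader groups by cohort/subtype and validates values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  base <- make_outcome(paste0("rs", 1:4), rep("A", 4), rep("G", 4),
                       rnorm(4, 0, 0.05), rep(0.05, 4))
  multi <- do.call(rbind, lapply(paste0("CO", 1:8), function(cc) {
    b <- base; b$cohort <- cc; b
  }))
  write.table(multi, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_outcome_table(f)
  expect_equal(nrow(got), 32)
  expect_equal(length(unique(got$cohort)), 8)
  expect_equal(nrow(got[got$cohort == "CO3", ]), 4)

  # subtype supplied as a constant propagates to all records
  noc <- base[, setdiff(names(base), "subtype")]
  write.table(noc, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_outcome_table(f, subtype = "GBM")
  expect_true(all(got$subtype == "GBM"))

  # vocabulary and range errors
  bad <- base; bad$subtype <- "astrocytoma"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_outcome_table(f), "vocabulary error")
  bad <- base; bad$eaf <- c(0.3, 1.2, 0.3, 0.3)
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_outcome_table(f), "eaf")
  bad <- base; bad$se_outcome[1] <- -0.01
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_outcome_table(f), "se_outcome")
})

test_that("reports round-trip through JSON and degrade gracefully in TSV", {
  rep1 <- suppressMessages(run_analysis(
    run_config(scenario = "null", seed = 11, methods = c("IVW", "Egger"))))

  jf <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, jf, format = "json")
  back <- read_report(jf)
  ivw <- rep1$results$all_glioma$meta$IVW$pooled
  expect_equal(back$results$all_glioma$meta$IVW$pooled$beta, ivw$beta)
  expect_equal(back$results$all_glioma$meta$IVW$pooled$se, ivw$se)
  expect_equal(back$results$all_glioma$egger$intercept$p,
               rep1$results$all_glioma$egger$intercept$p)
  # every reported OR is exp(beta)
  expect_equal(back$results$all_glioma$meta$IVW$pooled$or, exp(ivw$beta))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep1, tf, format = "tsv")
  lines <- readLines(tf)
  expect_true(any(grepl("^## main_results$", lines)))
  expect_true(any(grepl("^## harmonization_log$", lines)))

  # a report lacking the sensitivity section is written, with the
  # section marked absent
  rep2 <- rep1; rep2$sensitivity <- NULL; rep2$power <- NULL
  write_report(rep2, tf, format = "tsv")
  lines <- readLines(tf)
  expect_true(any(grepl("# section absent", lines, fixed = TRUE)))

  expect_error(write_report(rep1, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})

test_that("main results table carries one row per (method, subtype)", {
  rep1 <- suppressMessages(run_analysis(
    run_config(scenario = "null", seed = 3, methods = c("IVW", "MLE"))))
  tab <- vitdmr:::report_main_table(rep1)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$method, c("IVW", "MLE"))
  expect_equal(tab$or, exp(tab$beta))
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
})
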