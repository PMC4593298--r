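test_that("concentration_grid prepends the control and hits both endpoints", {
  expect_equal(concentration_grid(conc_range(0.1, 100, 4)),
               c(0, 0.1, 1, 10, 100))
  expect_equal(concentration_grid(conc_range(5, 5, 1)), c(0, 5))
  expect_equal(concentration_grid(conc_range(1, 3, 3, log_spaced = FALSE)),
               c(0, 1, 2, 3))
  expect_error(conc_range(0, 10, 3), "log")
  expect_error(conc_range(10, 1, 3), "high")
  g <- concentration_grid(conc_range(0.37, 81.2, 9))
  expect_identical(g[1], 0)
  expect_identical(g[2], 0.37)
  expect_identical(g[length(g)], 81.2)
  expect_true(all(diff(g) > 0))
})

test_that("an empty compound reproduces the control at every concentration", {
  study <- run_study("sixcurrent_demo", compound_spec("inert"),
                     conc_range(0.1, 100, 3),
                     pacing_protocol(frequency = 1))
  tab <- study$table
  expect_equal(nrow(tab), 4)
  expect_identical(tab$conc_uM[1], 0)
  expect_identical(tab$delta_apd90_pct[1], 0)
  expect_true(all(abs(tab$delta_apd90_pct) < 0.1))
  expect_true(all(tab$messages == ""))
  expect_true(all(tab$converged))
})

test_that("hERG-only block prolongs APD90 monotonically over the sweep", {
  study <- run_study(
    "sixcurrent_demo",
    compound_spec("hERG blocker", channel_block("hERG", pic50 = 6)),
    conc_range(0.1, 100, 4), pacing_protocol(frequency = 1))
  tab <- study$table
  expect_true(all(diff(tab$factor_IKr) < 0))
  expect_false(anyNA(tab$delta_apd90_pct))
  expect_true(all(diff(tab$delta_apd90_pct) > 0))
  expect_true(all(tab$delta_apd90_pct[-1] > 0))
  # rows ascending with the control first
  expect_true(all(diff(tab$conc_uM) > 0))
})

test_that("near-total hERG block at fast pacing is flagged, with absent delta", {
  study <- run_study(
    "sixcurrent_demo",
    compound_spec("potent hERG blocker", channel_block("hERG", pic50 = 8)),
    conc_range(0.01, 30, 3), pacing_protocol(frequency = 2))
  top <- study$table[nrow(study$table), ]
  expect_true(grepl("REPOLARISATION_FAILURE|ALTERNANS", top$messages))
  expect_true(is.na(top$delta_apd90_pct))
  expect_true(is.na(top$apd90_ms))
})

test_that("warm start is an optimisation, not a result-changer", {
  cmp <- compound_spec("hERG blocker", channel_block("hERG", pic50 = 6))
  rng <- conc_range(1, 1, 1)
  prot <- pacing_protocol(frequency = 1)
  warm <- run_study("sixcurrent_demo", cmp, rng, prot, warm_start = TRUE)
  cold <- run_study("sixcurrent_demo", cmp, rng, prot, warm_start = FALSE)
  expect_lt(abs(warm$table$apd90_ms[2] - cold$table$apd90_ms[2]), 1)
})

test_that("export_csv writes a deterministic spreadsheet set", {
  study <- run_study("sixcurrent_demo",
                     compound_spec("x", channel_block("hERG", pic50 = 6)),
                     conc_range(0.3, 30, 3), pacing_protocol(frequency = 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  files <- export_csv(study, d1)
  expect_true(file.exists(file.path(d1, "summary.csv")))
  expect_true(file.exists(file.path(d1, "metadata.csv")))

  smry <- utils::read.csv(file.path(d1, "summary.csv"))
  expect_equal(nrow(smry), 4)  # control + 3
  expect_true(all(c("conc_uM", "factor_IKr", "apd90_ms", "delta_apd90_pct",
                    "converged", "paces_run", "messages") %in% names(smry)))
  # one trace file per concentration
  expect_length(grep("^trace_conc_", basename(files)), 4)

  # re-export is byte-identical
  export_csv(study, d2)
  expect_identical(readBin(file.path(d1, "summary.csv"), "raw", 1e6),
                   readBin(file.path(d2, "summary.csv"), "raw", 1e6))
})

test_that("absent APD90 exports as an empty cell with a populated message", {
  study <- run_study(
    "sixcurrent_demo",
    compound_spec("potent", channel_block("hERG", pic50 = 8)),
    conc_range(30, 30, 1), pacing_protocol(frequency = 2))
  d <- withr::local_tempdir()
  export_csv(study, d)
  lines <- readLines(file.path(d, "summary.csv"))
  top <- strsplit(lines[3], ",")[[1]]
  header <- strsplit(lines[1], ",")[[1]]
  expect_identical(top[match("apd90_ms", header)], "")
  expect_match(lines[3], "REPOLARISATION_FAILURE|ALTERNANS")
})

test_that("run_study validates inputs and records metadata", {
  expect_error(run_study("nope", compound_spec("x"), conc_range(1, 10, 2)),
               "unknown model")
  study <- run_study("sixcurrent_demo", compound_spec("inert"),
                     conc_range(1, 1, 1), pacing_protocol(frequency = 1))
  expect_identical(study$metadata$model, "sixcurrent_demo")
  expect_s3_class(study, "ap_study")
  out <- summary(study)
  expect_equal(nrow(out), 2)
})
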