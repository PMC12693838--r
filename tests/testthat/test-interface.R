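test_that("IBI and steps CSVs round-trip with value equality", {
  sim <- simulate_ibi(ibi_config(duration = 900, gap_fraction = 0.05,
                                 movement_minutes = 2, seed = 101))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_ibi_csv(sim$series, f1, seed = 101)
  back <- read_ibi_csv(f1)
  expect_equal(back$t_ms, sim$series$t_ms)
  expect_equal(back$ibi_ms, sim$series$ibi_ms)
  write_steps_csv(sim$steps, f2, seed = 101)
  expect_equal(read_steps_csv(f2)$steps, sim$steps$steps)
})

test_that("panel CSVs round-trip through the long format", {
  sim <- simulate_panel(panel_config(12, 4, variables = c("x", "y", "d"),
                                     binary_specs = list(d = 0.5),
                                     seed = 102))
  f <- tempfile(fileext = ".csv")
  write_panel_csv(sim$panel, f, seed = 102)
  back <- read_panel_csv(f)
  orig <- sim$panel[order(sim$panel$person_id, sim$panel$day_index), ]
  for (v in c("x", "y", "d", "age", "gender"))
    expect_equal(back[[v]], orig[[v]], tolerance = 1e-6)
})

test_that("malformed panel input fails with a schema error", {
  f <- tempfile(fileext = ".csv")
  writeLines("person_id,day_index,value", f)   # missing 'variable' column
  expect_error(read_panel_csv(f), "schema error")
  writeLines("person_id,day_index,variable,value", f)  # header only
  expect_error(read_panel_csv(f), "no data rows")
})

test_that("unknown run-config keys are rejected, not warned about", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_persosn: 10"), f)  # deliberate typo
  expect_error(read_run_config(f), "unknown run_config key.*n_persosn")
})

test_that("the simulate and preprocess runners produce consistent files", {
  outdir <- file.path(tempdir(), "rt-run")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 11", paste0("outdir: ", outdir), "duration: 3600",
               "n_persons: 40", "n_obs_per_person: 5"), f)
  files <- run_simulate(f)
  expect_true(all(file.exists(files)))
  ## same seed twice gives identical files
  sums1 <- tools::md5sum(files)
  run_simulate(f)
  expect_identical(unname(tools::md5sum(files)), unname(sums1))

  f2 <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("ibi_csv: ", files[1]), paste0("steps_csv: ", files[2]),
               paste0("outdir: ", outdir)), f2)
  suppressMessages(out <- run_preprocess(f2))
  recs <- read.csv(out[3])
  expect_equal(nrow(recs), 1)
  expect_true(all(c("rmssd", "sdnn", "hf", "lf", "vlf", "lf_hf",
                    "log_rmssd", "n_valid_segments") %in% names(recs)))
  segs <- read.csv(out[1])
  expect_equal(nrow(segs), 60)               # full nocturnal tiling
  expect_equal(sum(segs$status == "kept"), 12)  # one hour of data
})

test_that("the associate runner writes a correlation report and ICC table", {
  outdir <- file.path(tempdir(), "rt-assoc")
  psim <- simulate_panel(panel_config(
    150, 6, variables = c("stress", "rmssd", "diagnosis"),
    between_corr = matrix(c(1, -0.3, 0, -0.3, 1, 0, 0, 0, 1), 3),
    binary_specs = list(diagnosis = 0.3), seed = 103))
  dir.create(outdir, showWarnings = FALSE)
  pf <- file.path(outdir, "panel.csv")
  write_panel_csv(psim$panel, pf, seed = 103)
  f <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("panel_csv: ", pf), paste0("outdir: ", outdir),
               "hrv_metric: rmssd", "lag: same_day"), f)
  out <- run_associate(f)
  rep_tab <- read.csv(out[1])
  expect_true("biserial" %in% rep_tab$type)
  expect_true(all(c("within", "between") %in%
                    rep_tab$level[rep_tab$x == "stress"]))
  icc_tab <- read.csv(out[2])
  expect_equal(icc_tab$variable, "rmssd")
  expect_true(icc_tab$icc > 0 && icc_tab$icc < 1)
})

test_that("the associate runner lists available variables on a bad name", {
  outdir <- file.path(tempdir(), "rt-assoc2")
  psim <- simulate_panel(panel_config(20, 3, seed = 104))
  dir.create(outdir, showWarnings = FALSE)
  pf <- file.path(outdir, "panel.csv")
  write_panel_csv(psim$panel, pf)
  f <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("panel_csv: ", pf), paste0("outdir: ", outdir),
               "hrv_metric: nope"), f)
  expect_error(run_associate(f), "not in panel.*available")
})

test_that("the power runner writes the sweep row it was asked for", {
  outdir <- file.path(tempdir(), "rt-power")
  f <- tempfile(fileext = ".yaml")
  writeLines(c(paste0("outdir: ", outdir), "seed: 12", "n_reps: 100",
               "n_persons: 50", "true_between_r: 0.9",
               "test_level: between"), f)
  path <- run_power(f)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 1)
  expect_gt(tab$power, 0.9)
})
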