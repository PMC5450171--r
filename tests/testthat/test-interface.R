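test_that("the pipeline runs the bundled study end to end", {
  out <- withr::local_tempdir()
  res <- suppressMessages(
    run_pipeline(study$runs, study$factors, out_dir = out, seed = 4))
  expect_named(res$fits, study_responses)
  # five optima, all inside the coded cube
  for (r in study_responses) {
    o <- res$optima[[r]]
    expect_true(all(o$coded >= -1 - 1e-9 & o$coded <= 1 + 1e-9))
  }
  expect_s3_class(res$joint, "rsm_optimum")
  expect_true(res$joint$value > 0 && res$joint$value <= 1)

  expect_true(all(file.exists(file.path(out,
    c("report.md", "optima.csv", "joint_optimum.csv", "pipeline.log",
      paste0("model_", study_responses, ".json"))))))
  log <- readLines(file.path(out, "pipeline.log"))
  for (stage in c("stage design", "stage fit", "stage optimize",
                  "stage joint-optimize", "stage report"))
    expect_true(any(grepl(stage, log, fixed = TRUE)), info = stage)
})

test_that("pipeline reruns produce byte-identical model artifacts", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (o in c(out1, out2))
    suppressMessages(run_pipeline(study$runs, study$factors,
                                  responses = "yield", out_dir = o, seed = 1))
  f1 <- file.path(out1, "model_yield.json")
  f2 <- file.path(out2, "model_yield.json")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("pipeline errors name the offending response column", {
  bad <- study$runs
  bad$yield <- NA_real_
  expect_error(
    suppressMessages(run_pipeline(bad, study$factors, responses = "yield")),
    "'yield'")
  expect_error(
    suppressMessages(run_pipeline(study$runs, study$factors,
                                  responses = "nope")),
    "'nope'")
  expect_error(
    suppressMessages(run_pipeline(study$runs[, 1:5], study$factors)),
    "no response")
})

test_that("simulate-then-analyze round trip reproduces a noiseless truth", {
  truth <- published_surface("tpc")
  xp <- gen_bbd_experiment(truth, sd = 0, n_center = 5, seed = 10)
  nat <- decode_runs(as.data.frame(xp), study$factors)
  res <- suppressMessages(run_pipeline(nat, study$factors, responses = "tpc"))
  expect_equal(fit_coef_vector(res$fits$tpc), published_coefs$tpc,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("model JSON round trip preserves predictions and fit statistics", {
  fit <- fit_study("abts")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  pts <- matrix(runif(40, -1, 1), ncol = 4)
  expect_equal(predict(back, pts), predict(fit, pts), tolerance = 1e-12)
  expect_equal(back$r2, fit$r2, tolerance = 1e-12)
  expect_equal(back$adj_r2, fit$adj_r2, tolerance = 1e-12)
  expect_equal(back$factors$ethanol_pct$high, 70)
  # optimization works on the deserialized model
  expect_equal(unname(maximize_in_box(back)$coded),
               unname(maximize_in_box(fit)$coded), tolerance = 1e-6)
})

test_that("factor specs round trip through YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- {name: ethanol_pct, unit: '%', low: 30, center: 50, high: 70}",
    "- {name: temperature_c, unit: degC, low: 60, center: 70, high: 80}",
    "- {name: solvent_ratio, unit: g/mL, low: 10, center: 20, high: 30}",
    "- {name: time_h, unit: h, low: 2, center: 3, high: 4}"), yml)
  fs <- read_factor_specs(yml)
  expect_equal(names(fs), names(study$factors))
  expect_equal(fs$solvent_ratio$center, 20)

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(fs, function(f) f[c("name", "unit", "low", "center", "high")]),
    jsn, auto_unbox = TRUE)
  fs2 <- read_factor_specs(jsn)
  expect_equal(fs2$time_h$low, 2)

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(study$runs[, -2], csv, row.names = FALSE)
  expect_error(read_design_csv(csv, fs), "ethanol_pct")
})

test_that("fit reports carry the published-style summaries", {
  fit <- fit_study("yield")
  rep <- fit_report(fit)
  expect_true(any(grepl("R2 = 0.9120", rep, fixed = TRUE)))
  expect_true(any(grepl("38.94", rep, fixed = TRUE)))
  expect_true(any(grepl("lack of fit", rep, fixed = TRUE)))
  expect_true(any(grepl("solvent_ratio", rep, fixed = TRUE)))
})
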