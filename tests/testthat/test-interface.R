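fast_pipeline_config <- function(...) {
  pipeline_config(gc_order = 2, gc_minutes = 0.5, window_max_s = 3,
                  sample_interval_s = 1, seed = 1L, ...)
}

make_test_cohort <- function(dir, seed = 5) {
  cfg <- test_config(session_duration = 40)
  simulate_cohort(cfg, n_animals = 2, sessions_per_animal = 2, seed = seed,
                  dir = dir, keep_sessions = FALSE)$manifest
}

test_that("the pipeline configuration round-trips losslessly through YAML", {
  cfg <- fast_pipeline_config(bin_width_logspeed = 0.2, stages = c("preprocess"))
  path <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  cfg2 <- read_pipeline_config(path)
  expect_equal(cfg2, cfg)
  writeLines(c(readLines(path), "mystery_knob: 3"), path)
  expect_error(read_pipeline_config(path), "unknown key")
  expect_error(pipeline_config(lmm_method = "bayes"), "REML or ML")
})

test_that("a simulate -> analyze round trip emits every declared output", {
  dir <- file.path(tempdir(), "pipe_rt")
  unlink(dir, recursive = TRUE)
  manifest <- make_test_cohort(file.path(dir, "data"))
  out <- run_pipeline(fast_pipeline_config(), manifest, file.path(dir, "res"))
  expect_length(out$failures, 0L)
  expect_true(file.exists(file.path(dir, "res", "preprocess",
                                    paste0(manifest$session_id[1], ".csv"))))
  expect_true(file.exists(file.path(dir, "res", "tuning", "logspeed_tuning.csv")))
  expect_true(file.exists(file.path(dir, "res", "dynamics", "window_scans.csv")))
  expect_true(file.exists(file.path(dir, "res", "granger", "gc_per_animal.csv")))
  expect_true(length(list.files(file.path(dir, "res", "lmm"),
                                pattern = "coefficients")) >= 1)
  # every stage declares its provenance (config hash + seed)
  for (st in c("preprocess", "tuning", "dynamics", "granger", "lmm")) {
    prov <- jsonlite::read_json(file.path(dir, "res", st, "provenance.json"))
    expect_match(prov$config_hash, "^[0-9a-f]{32}$")
    expect_equal(prov$seed, 1L)
  }
})

test_that("re-running with the same seed and config is byte-identical", {
  dir <- file.path(tempdir(), "pipe_det")
  unlink(dir, recursive = TRUE)
  manifest <- make_test_cohort(file.path(dir, "data"))
  run_pipeline(fast_pipeline_config(), manifest, file.path(dir, "res1"))
  run_pipeline(fast_pipeline_config(), manifest, file.path(dir, "res2"))
  for (f in c("preprocess/m01_s001.csv", "tuning/logspeed_tuning.csv",
              "dynamics/window_scans.csv", "granger/gc_per_session.csv")) {
    expect_same_file(file.path(dir, "res1", f), file.path(dir, "res2", f))
  }
})

test_that("disabling the Granger stage omits only its outputs", {
  dir <- file.path(tempdir(), "pipe_toggle")
  unlink(dir, recursive = TRUE)
  manifest <- make_test_cohort(file.path(dir, "data"))
  cfg <- fast_pipeline_config(stages = c("preprocess", "tuning", "dynamics"))
  run_pipeline(cfg, manifest, file.path(dir, "res"))
  expect_false(dir.exists(file.path(dir, "res", "granger")))
  expect_true(file.exists(file.path(dir, "res", "tuning", "logspeed_tuning.csv")))
})

test_that("input validation reports malformed cohorts with row detail", {
  dir <- file.path(tempdir(), "pipe_val")
  unlink(dir, recursive = TRUE)
  manifest <- make_test_cohort(file.path(dir, "data"))
  expect_equal(nrow(validate_inputs(manifest)), 0L)

  # pose file with one frame fewer than the TTL count
  pose <- read_pose_csv(manifest$pose_path[1])
  write_pose_simple(pose[-nrow(pose), ], manifest$pose_path[1])
  v <- validate_inputs(manifest)
  expect_true("pose_frame_mismatch" %in% v$check)
  expect_equal(sum(v$session_id == manifest$session_id[1]), 1L)

  # non-monotone photometry timestamps are flagged with row numbers
  d <- utils::read.csv(manifest$photometry_path[2])
  d$time_s[10] <- d$time_s[12]
  utils::write.csv(d, manifest$photometry_path[2], row.names = FALSE)
  v2 <- validate_inputs(manifest)
  expect_true("non_monotone_time" %in% v2$check)
  expect_match(v2$detail[v2$check == "non_monotone_time"], "1[01]")
})

test_that("per-session failures are isolated and reported", {
  dir <- file.path(tempdir(), "pipe_fail")
  unlink(dir, recursive = TRUE)
  manifest <- make_test_cohort(file.path(dir, "data"))
  writeLines("time_s,f470\n0,1", manifest$photometry_path[1])
  expect_error(
    run_pipeline(fast_pipeline_config(stages = "preprocess"), manifest,
                 file.path(dir, "res")),
    "failures")
  # the healthy sessions were still processed
  expect_true(file.exists(file.path(dir, "res", "preprocess",
                                    paste0(manifest$session_id[2], ".csv"))))
})
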