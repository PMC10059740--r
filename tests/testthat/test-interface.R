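# File formats and the command-line pipeline.

test_that("recording files round-trip at format precision", {
  day <- generate_day(scenario_config(sample_rate = 2), p_fever = 0.02,
                      seed = 21)
  path <- recording_path(withr::local_tempdir(), day$stream$date)
  write_recording(day$stream, path)
  back <- read_recording(path)
  expect_equal(back$date, day$stream$date)
  expect_equal(back$sample_rate_hz, 2)
  expect_equal(length(back$t_r1_max), length(day$stream$t_r1_max))
  expect_lt(max(abs(back$t_r1_max - day$stream$t_r1_max)), 0.005 + 1e-9)
  expect_lt(max(abs(back$t_r2_mean - day$stream$t_r2_mean)), 0.005 + 1e-9)
})

test_that("recording reader recovers the 9 Hz grid despite 1 ms rounding", {
  s <- make_stream(c(rep(26, 50), rep(36, 20), rep(26, 30)), rate = 9)
  path <- file.path(withr::local_tempdir(), "2022-04-22.csv")
  write_recording(s, path)
  back <- read_recording(path)
  expect_equal(back$sample_rate_hz, 9)
  expect_equal(back$date, as.Date("2022-04-22"))
})

test_that("recording reader rejects malformed files with line numbers", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "2022-04-22.csv")

  writeLines("time_s,t_r1_max_c,t_r2_mean_c", p)
  expect_warning(empty <- read_recording(p), "header only")
  expect_equal(length(empty$t_r1_max), 0)

  writeLines(c("time_s,t_r1_max_c,t_r2_mean_c",
               "0.000,26.00,20.00", "0.111,26.01"), p)
  expect_error(read_recording(p), "line 3")

  writeLines(c("time_s,t_r1_max_c,t_r2_mean_c",
               "0.000,26.00,20.00", "0.222,26.01,20.00",
               "0.111,26.02,20.00"), p)
  expect_error(read_recording(p), "non-monotonic")

  writeLines(c("time_s,t_r1_max_c,t_r2_mean_c",
               "0.000,26.00,20.00", "0.111,26.01,20.00",
               "0.500,26.02,20.00", "0.611,26.03,20.00"), p)
  expect_error(read_recording(p), "inconsistent sampling")

  writeLines(c("wrong,header,here", "0.000,26.00,20.00"), p)
  expect_error(read_recording(p), "header")
})

test_that("detections round-trip with empty FTI durations", {
  dets <- data.frame(
    date = as.Date("2022-04-22") + c(0, 0, 1),
    method = c("TTI", "FTI", "TTI"),
    detect_time_s = c(34200.111, 34200.778, 50000),
    temp_c = c(36.53, 36.21, 34.1),
    duration_s = c(2.333, NA, 1.222),
    peak_time_s = NA_real_
  )
  p <- file.path(withr::local_tempdir(), "det.csv")
  write_detections(dets, p)
  raw <- readLines(p)
  expect_equal(raw[1], "date,method,detect_time_s,temp_c,duration_s")
  expect_true(endsWith(raw[3], ","))  # FTI duration field left empty
  back <- read_detections(p)
  expect_equal(back$method, dets$method)
  expect_equal(back$temp_c, dets$temp_c)
  expect_equal(back$duration_s, dets$duration_s, tolerance = 1e-9)
  expect_equal(back$date, dets$date)
})

test_that("ARI series round-trip and reject negative incidence", {
  ari <- data.frame(week_index = 1:4,
                    incidence_per_100k = c(120.5, 0, 431.25, 88))
  p <- file.path(withr::local_tempdir(), "ari.csv")
  write_ari(ari, p)
  expect_equal(read_ari(p), ari)
  expect_error(write_ari(transform(ari, incidence_per_100k = -1), p), ">= 0")
  writeLines(c("week_index,incidence_per_100k", "1,-5"), p)
  expect_error(read_ari(p), ">= 0")
})

test_that("scenario config files round-trip", {
  cfg <- scenario_config(p_front = 0.65, sample_rate = 3,
                         fever_ari_slope = 3e-5, seed = 7)
  p <- file.path(withr::local_tempdir(), "config.txt")
  write_scenario_config(cfg, p)
  back <- read_scenario_config(p)
  expect_equal(back, cfg)

  writeLines(c("p_front = 0.5", "no_such_key = 1"), p)
  expect_error(read_scenario_config(p), "unknown config key")
  writeLines("what even is this", p)
  expect_error(read_scenario_config(p), "malformed line 1")
})

test_that("cli simulate is byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.txt")
  write_scenario_config(scenario_config(sample_rate = 1), cfgp)
  a <- file.path(dir, "a"); b <- file.path(dir, "b")
  expect_equal(cli(c("simulate", "--config", cfgp, "--weeks", "1",
                     "--days-per-week", "2", "--seed", "1", "--out", a)), 0L)
  expect_equal(cli(c("simulate", "--config", cfgp, "--weeks", "1",
                     "--days-per-week", "2", "--seed", "1", "--out", b)), 0L)
  fa <- list.files(a, recursive = TRUE)
  expect_setequal(fa, list.files(b, recursive = TRUE))
  for (f in fa)
    expect_identical(readLines(file.path(a, f)), readLines(file.path(b, f)),
                     label = f)
})

test_that("cli detect on a baseline-only study writes a header-only file", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.txt")
  write_scenario_config(
    scenario_config(hourly_rate_profile = rep(0, 24), short_pass_rate = 0,
                    hot_object_rate = 0, sample_rate = 1), cfgp)
  out <- file.path(dir, "study")
  expect_equal(cli(c("simulate", "--config", cfgp, "--weeks", "1",
                     "--days-per-week", "1", "--seed", "2", "--out", out)), 0L)
  det <- file.path(dir, "det.csv")
  expect_equal(cli(c("detect", "--method", "both", "--in", out,
                     "--out", det)), 0L)
  expect_equal(readLines(det), "date,method,detect_time_s,temp_c,duration_s")
})

test_that("cli full chain produces a sane correlation report", {
  # scaled down for suite runtime: 4 weeks at 3 Hz instead of a full-rate
  # multi-month study (the acceptance tests exercise the full scale)
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.txt")
  write_scenario_config(scenario_config(sample_rate = 3), cfgp)
  out <- file.path(dir, "study")
  det <- file.path(dir, "det.csv")
  wk <- file.path(dir, "weekly.csv")
  js <- file.path(dir, "corr.json")
  expect_equal(cli(c("simulate", "--config", cfgp, "--weeks", "4",
                     "--seed", "3", "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "ari.csv")))
  expect_true(file.exists(file.path(out, "config.txt")))
  expect_equal(cli(c("detect", "--method", "both", "--in", out,
                     "--out", det)), 0L)
  dets <- read_detections(det)
  expect_setequal(unique(dets$method), c("TTI", "FTI"))
  expect_equal(cli(c("summarize", "--in", det, "--by", "week",
                     "--out", wk)), 0L)
  expect_equal(cli(c("correlate", "--summaries", wk, "--ari",
                     file.path(out, "ari.csv"), "--statistic", "frac_fever",
                     "--out", js)), 0L)
  rep <- jsonlite::read_json(js)
  expect_lte(abs(rep$pearson_r), 1)
  expect_equal(rep$n_points, 4)
})

test_that("cli rejects bad invocations", {
  expect_equal(cli(character(0)), 1L)
  expect_equal(cli("frobnicate"), 1L)
  expect_equal(cli(c("simulate", "--weeks", "1")), 1L)           # missing flags
  expect_equal(cli(c("detect", "--bogus", "x")), 1L)             # unknown flag
  expect_equal(cli(c("detect", "--in", "/nonexistent", "--out", "y")), 1L)
})
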