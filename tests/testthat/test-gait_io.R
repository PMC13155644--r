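test_that("gait_ts validates uniform sampling and channel lengths", {
  ts <- gait_ts(c(0, 0.001, 0.002), list(emg = c(1, 2, 3)))
  expect_equal(ts$rate, 1000)
  expect_error(gait_ts(c(0, 0.001, 0.003), list(emg = 1:3)),
               "non-uniform sampling at index 2")
  expect_error(gait_ts(c(0, 0.001, 0.002), list(emg = 1:2)),
               "length mismatch")
  expect_error(gait_ts(0.5, list(emg = 1)), "rate")
  expect_equal(gait_ts(0.5, list(emg = 1), rate = 100)$rate, 100)
})

test_that("read_timeseries parses CSV and sto/mot dialects identically", {
  d <- withr::local_tempdir()
  csv <- file.path(d, "trial.csv")
  writeLines(c("time,emg_a,grf", "0,0.1,700", "0.001,0.2,710", "0.002,0.3,705"), csv)
  ts <- read_timeseries(csv)
  expect_equal(ts$rate, 1000)
  expect_equal(names(ts$channels), c("emg_a", "grf"))
  expect_equal(ts$channels$emg_a, c(0.1, 0.2, 0.3))

  sto <- file.path(d, "trial.sto")
  writeLines(c("trial", "nRows=3", "nColumns=3", "endheader",
               "time\temg_a\tgrf", "0\t0.1\t700", "0.001\t0.2\t710",
               "0.002\t0.3\t705"), sto)
  ts2 <- read_timeseries(sto)
  expect_equal(ts2$channels, ts$channels)
  expect_equal(ts2$time, ts$time)

  dup <- file.path(d, "dup.csv")
  writeLines(c("time,a,a", "0,1,2", "0.01,1,2"), dup)
  expect_error(read_timeseries(dup), "duplicate column names: a")
})

test_that("write/read round trip is lossless to 1e-9 in both dialects", {
  d <- withr::local_tempdir()
  set.seed(1)
  ts <- gait_ts((0:99) / 500,
                list(emg = rnorm(100) * 1e-3, vertical_grf = runif(100, 0, 900)))
  for (dialect in c("csv", "sto_mot")) {
    path <- file.path(d, paste0("rt.", dialect))
    write_timeseries(ts, path, dialect)
    back <- read_timeseries(path, dialect)
    for (ch in names(ts$channels))
      expect_equal(back$channels[[ch]], ts$channels[[ch]], tolerance = 1e-9)
  }
  # single-sample series round-trips too
  one <- gait_ts(0, list(x = 3.14159), rate = 100)
  p1 <- file.path(d, "one.csv")
  write_timeseries(one, p1, "csv")
  expect_equal(utils::read.csv(p1)$x, 3.14159, tolerance = 1e-9)
  expect_error(write_timeseries(structure(list(time = 0:1, channels = list(),
                                               rate = 1),
                                          class = "gait_ts"),
                                file.path(d, "bad.csv"), "csv"),
               "empty channel map")
})

test_that("load_trial validates required channels and metadata", {
  d <- withr::local_tempdir()
  p <- make_small_participant(seed = 5, steps = 8, modeling = TRUE)
  files <- write_participant(p, d, dialect = "sto_mot")
  meta <- list(participant_id = "TP", session = 2, trial_kind = "baseline",
               body_mass = p$meta$body_mass, height = p$meta$height)
  entry <- list(analog_file = "TP_baseline_analog.sto",
                mech_file = "TP_baseline_mech.sto", meta = meta)
  trial <- load_trial(entry, base_dir = d)
  expect_s3_class(trial, "gait_trial")
  expect_true("vertical_grf" %in% names(trial$analog$channels))
  expect_true(all(c("knee_moment", "knee_axial_interseg") %in%
                    names(trial$mech$channels)))
  expect_equal(trial$meta$body_mass, p$meta$body_mass)

  # missing vertical GRF is named in the error
  ts <- trial$analog
  ts$channels$vertical_grf <- NULL
  nogrf <- file.path(d, "nogrf.sto")
  write_timeseries(ts, nogrf, "sto_mot")
  expect_error(load_trial(list(analog_file = nogrf, meta = meta), d),
               "vertical_grf")
})

test_that("read_trial_config loads trials and merges config overrides", {
  d <- withr::local_tempdir()
  p <- make_small_participant(seed = 6, steps = 8, modeling = FALSE)
  write_participant(p, d, dialect = "csv")
  cfgfile <- file.path(d, "study.json")
  jsonlite::write_json(list(
    config = list(grf_threshold = 25),
    trials = list(list(
      analog_file = "TP_baseline_analog.csv",
      meta = list(participant_id = "TP", session = 2,
                  trial_kind = "baseline",
                  body_mass = p$meta$body_mass, height = p$meta$height)))),
    cfgfile, auto_unbox = TRUE, digits = NA)
  loaded <- read_trial_config(cfgfile)
  expect_length(loaded$trials, 1)
  expect_s3_class(loaded$trials[[1]], "gait_trial")
  expect_equal(loaded$config$grf_threshold, 25)
  expect_equal(loaded$config$window_size, 50)
})

test_that("channel order does not affect stance means", {
  p <- make_small_participant(seed = 9, steps = 8, modeling = FALSE)
  tr <- p$baseline
  perm <- rev(seq_along(tr$analog$channels))
  tr2 <- tr
  tr2$analog$channels <- tr$analog$channels[perm]
  cfg <- default_config()
  m1 <- gaitretrain:::trial_stance_means(tr, cfg)$means
  m2 <- gaitretrain:::trial_stance_means(tr2, cfg)$means
  expect_equal(m1[, colnames(m1)], m2[, colnames(m1)])
})
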