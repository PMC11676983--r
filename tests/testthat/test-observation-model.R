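test_that("predicted fluorescence is affine in the reporter concentration", {
  sys <- tmsdr_system(ka = 1e-3, kd = 1e-4)
  tt <- seq(0, 100, by = 10)

  # synthetic trajectories with pinned reporter levels
  mk_traj <- function(x4) {
    structure(data.frame(time_s = tt, x1_nM = 10 - x4, x2_nM = 10 - x4,
                         x3_nM = x4, x4_nM = x4),
              class = c("tmsdr_trajectory", "data.frame"),
              initial = reaction_state(10, 10))
  }
  expect_equal(predict_fluorescence(mk_traj(0), sys, 100, 1000)$signal,
               rep(100, length(tt)))
  expect_equal(predict_fluorescence(mk_traj(10), sys, 100, 1000)$signal,
               rep(1000, length(tt)))
  expect_equal(predict_fluorescence(mk_traj(5), sys, 100, 300)$signal,
               rep(200, length(tt)))
  expect_error(predict_fluorescence(mk_traj(5), sys, 300, 100),
               class = "tmsdr_config_error")

  # reporter species selects the column
  sysX3 <- tmsdr_system(ka = 1e-3, kd = 1e-4, reporter_species = "X3")
  tr <- mk_traj(5)
  tr$x3_nM <- rep(2.5, length(tt))
  expect_equal(predict_fluorescence(tr, sysX3, 0, 1000)$signal,
               rep(250, length(tt)))
})

test_that("normalization inverts the affine observation model", {
  tt <- seq(0, 5400, by = 10)
  sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4)
  init <- default_init()
  traj <- simulate_tmsdr(sys, init, tt)
  pred <- predict_fluorescence(traj, sys, 100, 1000)
  calib <- calibration_set(
    fluorescence_trace(tt, rep(100, length(tt)), "baseline"),
    fluorescence_trace(tt, rep(1000, length(tt)), "positive_control"))

  # noiseless round trip recovers reporter(t)/x1_0 essentially exactly
  r <- normalize_to_substitution(pred, calib)
  expect_lt(max(abs(r$ratio - traj$x4_nM / 10)), 1e-12)

  # baseline maps to ~0, positive control to ~1
  expect_equal(normalize_to_substitution(calib$baseline[[1]], calib)$ratio,
               rep(0, length(tt)))
  expect_equal(normalize_to_substitution(calib$positive_control[[1]], calib)$ratio,
               rep(1, length(tt)))
})

test_that("normalization is affine-invariant and idempotent", {
  tt <- seq(0, 300, by = 10)
  raw <- 100 + 900 * seq(0, 1, length.out = length(tt))
  mk_calib <- function(a, b) calibration_set(
    fluorescence_trace(tt, a * 100 + b + 0 * tt, "baseline"),
    fluorescence_trace(tt, a * 1000 + b + 0 * tt, "positive_control"))

  r0 <- normalize_to_substitution(fluorescence_trace(tt, raw, "reaction"),
                                  mk_calib(1, 0))
  for (tf in list(c(2, 50), c(0.3, -20))) {
    r1 <- normalize_to_substitution(
      fluorescence_trace(tt, tf[1] * raw + tf[2], "reaction"),
      mk_calib(tf[1], tf[2]))
    expect_equal(r1$ratio, r0$ratio, tolerance = 1e-12)
  }

  # already-normalized trace with baseline 0 / control 1 is a fixed point
  unit_calib <- calibration_set(
    fluorescence_trace(tt, rep(0, length(tt)), "baseline"),
    fluorescence_trace(tt, rep(1, length(tt)), "positive_control"))
  again <- normalize_to_substitution(
    fluorescence_trace(tt, r0$ratio, "reaction"), unit_calib)
  expect_equal(again$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("calibration rejects a positive control at or below baseline", {
  tt <- seq(0, 100, by = 10)
  expect_error(
    calibration_set(fluorescence_trace(tt, rep(500, 11), "baseline"),
                    fluorescence_trace(tt, rep(400, 11), "positive_control")),
    class = "tmsdr_data_error")
})

test_that("replicate aggregation computes pointwise mean and sample SD", {
  tt <- c(0, 10, 20)
  mk <- function(v) data.frame(time_s = tt, ratio = v)

  # identical replicates: mean is the trace, SD is 0
  agg <- aggregate_replicates(list(mk(c(0, 0.5, 1)), mk(c(0, 0.5, 1)),
                                   mk(c(0, 0.5, 1))))
  expect_equal(agg$mean, c(0, 0.5, 1))
  expect_equal(agg$sd, c(0, 0, 0))
  expect_identical(attr(agg, "n_replicates"), 3L)

  # hand arithmetic: values {0, 1, 2} at each point -> mean 1, sample SD 1
  agg2 <- aggregate_replicates(list(mk(rep(0, 3)), mk(rep(1, 3)), mk(rep(2, 3))))
  expect_equal(agg2$mean, rep(1, 3))
  expect_equal(agg2$sd, rep(1, 3))

  # single replicate: SD 0 with a warning and a flag
  expect_warning(agg1 <- aggregate_replicates(list(mk(c(0, 0.5, 1)))),
                 "single replicate")
  expect_equal(agg1$sd, c(0, 0, 0))
  expect_true(attr(agg1, "single_replicate"))

  expect_error(
    aggregate_replicates(list(mk(c(0, 0.5, 1)),
                              data.frame(time_s = c(0, 10, 30),
                                         ratio = c(0, 0.5, 1)))),
    class = "tmsdr_data_error")
})

test_that("trace CSVs round-trip and encode role/replicate in the file name", {
  dir <- withr::local_tempdir()
  tr <- fluorescence_trace(seq(0, 100, 10), rnorm(11, 500, 10),
                           label = "reaction", replicate_id = 2L)
  path <- file.path(dir, "reaction_2.csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$signal, tr$signal, tolerance = 1e-9)
  expect_identical(attr(back, "label"), "reaction")
  expect_identical(attr(back, "replicate_id"), 2L)

  bad <- file.path(dir, "mystery.csv")
  write_trace_csv(tr, bad)
  expect_error(read_trace_csv(bad), class = "tmsdr_data_error")
  expect_identical(attr(read_trace_csv(bad, label = "baseline"), "label"),
                   "baseline")
})
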