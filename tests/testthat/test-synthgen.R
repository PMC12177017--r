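# Synthetic cohort generator: determinism, signal model, quantisation,
# bout structure, fixture round-trips.

test_that("identical seeds give bit-identical individuals", {
  cfg <- cohort_config(seed = 7L)
  a <- simulate_individual(cfg, "ind01", "scute1", 123L)
  b <- simulate_individual(cfg, "ind01", "scute1", 123L)
  expect_identical(a, b)
  c <- simulate_individual(cfg, "ind01", "scute1", 124L)
  expect_false(identical(a$trace$ax, c$trace$ax))
})

test_that("motionless flat behaviour reads gravity on the heave axis", {
  cfg <- single_behaviour_config()
  sim <- simulate_individual(cfg, "indA", "scute3", 1L)
  step <- 2 * cfg$dynamic_range_g / (2^cfg$resolution_bits - 1)
  expect_true(all(sim$trace$ax == 0))  # 0 lies on the quantisation grid
  expect_true(all(sim$trace$ay == 0))
  expect_true(all(abs(sim$trace$az - 1) <= step / 2 + 1e-12))
})

test_that("outputs lie on the ADC grid and inside the dynamic range", {
  cfg <- cohort_config(seed = 3L, dynamic_range_g = 2, resolution_bits = 8)
  sim <- simulate_individual(cfg, "ind01", "scute1", 5L)
  step <- 2 * 2 / (2^8 - 1)
  for (axis in c("ax", "ay", "az")) {
    v <- sim$trace[[axis]]
    expect_true(all(abs(v) <= 2 + 1e-12))
    expect_true(all(abs(v / step - round(v / step)) < 1e-9))
  }
})

test_that("quantisation error of a noise-free posture is at most half a grid step", {
  cfg <- single_behaviour_config(pitch_deg = 17, roll_deg = -23, duration_s = 4)
  sim <- simulate_individual(cfg, "indA", "scute3", 2L)
  p <- 17 * pi / 180; r <- -23 * pi / 180
  truth <- c(sin(p), cos(p) * sin(r), cos(p) * cos(r))
  step <- 2 * cfg$dynamic_range_g / (2^cfg$resolution_bits - 1)
  expect_true(all(abs(sim$trace$ax - truth[1]) <= step / 2 + 1e-12))
  expect_true(all(abs(sim$trace$ay - truth[2]) <= step / 2 + 1e-12))
  expect_true(all(abs(sim$trace$az - truth[3]) <= step / 2 + 1e-12))
})

test_that("mean rectified surge oscillation matches the mean-|sin| oracle", {
  # Independent oracle: dense numerical integration of |A sin| over one period.
  oracle <- 0.5 * mean(abs(sin(2 * pi * seq(0, 1, length.out = 1e5 + 1)[-1])))
  expect_equal(oracle, 2 * 0.5 / pi, tolerance = 1e-4)  # sanity on the oracle
  cfg <- single_behaviour_config(osc_freq_hz = 1, osc_amp_g = 0.5,
                                 duration_s = 10)
  sim <- simulate_individual(cfg, "indA", "scute3", 3L)
  dyn <- sim$trace$ax - mean(sim$trace$ax)
  step <- 2 * cfg$dynamic_range_g / (2^cfg$resolution_bits - 1)
  expect_lt(abs(mean(abs(dyn)) - oracle), step / 2)
})

test_that("a cohort yields two traces per individual and one annotation set", {
  cfg <- cohort_config(n_individuals = 8, seed = 11L)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort$traces, 16)
  expect_length(cohort$annotations, 8)
  expect_setequal(
    unique(vapply(cohort$traces, `[[`, character(1), "position")),
    c("scute1", "scute3"))
})

test_that("null position effect makes the two placements identical", {
  cfg <- cohort_config(
    n_individuals = 4, seed = 9L, individual_sd = 0,
    position_effect = list(scute1 = list(gain = 1, noise_sd_g = 0),
                           scute3 = list(gain = 1, noise_sd_g = 0)))
  cohort <- simulate_cohort(cfg)
  expect_identical(cohort$traces$ind01_scute1$ax, cohort$traces$ind01_scute3$ax)
  expect_identical(cohort$traces$ind01_scute1$az, cohort$traces$ind01_scute3$az)
})

test_that("annotated bouts tile the recording without gaps or overlap", {
  cfg <- cohort_config(seed = 21L, duration_s = 300)
  sim <- simulate_individual(cfg, "ind01", "scute3", 77L)
  b <- sim$annotations$bouts
  expect_equal(sum(b$stop_utc - b$start_utc), 300)
  expect_equal(b$start_utc[-1], b$stop_utc[-nrow(b)])
  expect_equal(b$start_utc[1], sim$trace$t[1])
})

test_that("too-short recordings and malformed transition matrices error", {
  expect_error(cohort_config(duration_s = 10), "duration_s too short")
  expect_error(cohort_config(transition_weights = matrix(1, 2, 3)), "square")
  expect_error(cohort_config(transition_weights = matrix(0, 5, 5)),
               "positive sum")
})

test_that("fixtures round-trip through the ingest readers", {
  cfg <- cohort_config(n_individuals = 4, seed = 13L, duration_s = 120)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_fixture(cohort$traces["ind01_scute3"], cohort$annotations["ind01"], dir)
  tr <- read_accel_csv(file.path(dir, "ind01_scute3.csv"))
  orig <- cohort$traces$ind01_scute3
  expect_lt(max(abs(tr$ax - orig$ax)), 1e-6)
  expect_lt(max(abs(tr$az - orig$az)), 1e-6)
  expect_lt(max(abs(tr$t - orig$t)), 1e-3)
  expect_lt(abs(tr$sample_rate_hz - 100), 0.1)
  expect_identical(tr$individual_id, "ind01")
  expect_identical(tr$position, "scute3")
  ann <- read_annotation_csv(file.path(dir, "ind01_annotations.csv"))
  expect_identical(ann$bouts$behaviour, cohort$annotations$ind01$bouts$behaviour)
  expect_lt(max(abs(ann$bouts$start_utc - cohort$annotations$ind01$bouts$start_utc)),
            1e-3)
})

test_that("an empty cohort writes nothing and a 10 s trace writes 1000 rows", {
  dir <- withr::local_tempdir()
  expect_no_error(write_fixture(list(), list(), dir))
  expect_length(list.files(dir), 0)
  tr <- make_trace(10, 100, t0 = 1704067200)
  write_fixture(list(tr), list(), dir)
  rows <- readLines(file.path(dir, "indA_scute3.csv"))
  expect_length(rows, 1001)  # header + duration x rate
})
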