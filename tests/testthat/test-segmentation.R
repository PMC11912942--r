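test_that("noise-free contacts are recovered to within one sample", {
  cfg <- tiny_config(strides_per_trial = 8, noise_sd = 0)
  tr <- simulate_trial(cfg, "TD", "Dry", "Normal", seed = 3)
  ics <- detect_initial_contacts(tr$accel_vertical, tr$imu_rate_hz,
                                 expected_stride_s = 1.0)
  expect_length(ics, length(tr$true_initial_contacts_s))
  expect_lt(max(abs(ics - tr$true_initial_contacts_s)),
            1 / tr$imu_rate_hz + 1e-9)
})

test_that("unsegmentable traces raise errors", {
  expect_error(detect_initial_contacts(rep(0, 500), 142, 1),
               "unsegmentable")
  expect_error(detect_initial_contacts(rnorm(100), 142, -1), "positive")
})

test_that("most contacts are matched within 30 ms at default noise", {
  # smaller companion of the 50-trial acceptance check
  cfg <- simulation_config(strides_per_trial = 20)
  hits <- misses <- 0
  for (s in 1:10) {
    tr <- simulate_trial(cfg, "CP", "Wet", "Slow", seed = 100 + s)
    ics <- detect_initial_contacts(tr$accel_vertical, tr$imu_rate_hz,
                                   expected_stride_s = 1.1 / 0.75)
    d <- vapply(tr$true_initial_contacts_s,
                function(t0) min(abs(ics - t0)), numeric(1))
    hits <- hits + sum(d <= 0.030)
    misses <- misses + sum(d > 0.030)
  }
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("the 3-SD stride-time outlier rule matches direct arithmetic", {
  # all equal: SD = 0, nothing deviates
  expect_equal(flag_stride_outliers(rep(1, 10)), rep(FALSE, 10))

  # 50 strides of 1 s plus one of 2 s: mean ~1.0196, SD ~0.140, the 2 s
  # stride deviates ~7 SD, the rest ~0.14 SD
  d <- c(rep(1, 50), 2)
  expect_equal(which(flag_stride_outliers(d)), 51L)

  # a 5 s stride among four 1 s strides deviates only 1.79 SD: kept
  expect_equal(flag_stride_outliers(c(1, 1, 1, 1, 5)), rep(FALSE, 5))

  expect_error(flag_stride_outliers(c(1, 1)), "at least 3")
})

test_that("stride sets derive durations and retained indices coherently", {
  ics <- c(0, 1, 2, 3.1, 4.1, 10, 11)
  ss <- build_stride_set(ics)
  expect_s3_class(ss, "stride_set")
  expect_equal(ss$stride_durations_s, diff(ics))
  expect_equal(ss$outlier_flags,
               flag_stride_outliers(diff(ics)))
  expect_equal(ss$retained_stride_indices, which(!ss$outlier_flags))
  expect_error(build_stride_set(c(1, 1)), "strictly increasing")
})

test_that("time normalization is exact for constant and linear envelopes", {
  rate <- 2000
  n <- 8000
  t <- (seq_len(n) - 1) / rate
  ss <- build_stride_set(c(0.2, 1.3, 2.4, 3.5))

  const_env <- make_env_trial(n = n, values = c(TA = 0.3, MG = 0.3,
                                                RF = 0.3, ST = 0.3))
  sm <- build_stride_matrix(const_env, ss, "RF/ST")
  expect_equal(dim(sm$muscle_1), c(3, 101))
  expect_true(all(sm$muscle_1 == 0.3))

  lin <- sapply(1:4, function(i) 0.1 + 0.05 * t)
  colnames(lin) <- c("TA", "MG", "RF", "ST")
  sm2 <- build_stride_matrix(make_env_trial(n = n, envelopes = lin), ss,
                             "TA/MG")
  grid_t <- 0.2 + seq(0, 1, length.out = 101) * 1.1
  expect_equal(sm2$muscle_1[1, ], 0.1 + 0.05 * grid_t, tolerance = 1e-12)
  expect_equal(sm2$muscle_1[1, c(1, 101)],
               0.1 + 0.05 * c(0.2, 1.3))  # endpoints exact
})

test_that("interpolation round trip on a band-limited profile is accurate", {
  rate <- 2000
  t <- seq(0, 1.5, by = 1 / rate)
  f <- function(x) 0.5 + 0.3 * sin(2 * pi * x / 1.5) +
    0.15 * cos(6 * pi * x / 1.5)
  env <- sapply(1:4, function(i) f(t))
  colnames(env) <- c("TA", "MG", "RF", "ST")
  ss <- build_stride_set(c(0, 0.75, 1.5))
  sm <- build_stride_matrix(make_env_trial(n = length(t), envelopes = env),
                            ss, "RF/ST")
  truth <- f(0.75 + seq(0, 1, length.out = 101) * 0.75)
  expect_lt(max(abs(sm$muscle_1[2, ] - truth)) / diff(range(truth)), 0.01)
})

test_that("dropping outlier strides leaves the retained rows untouched", {
  rate <- 100
  n <- 2800
  set.seed(4)
  env <- matrix(abs(rnorm(n * 4, 0.5, 0.1)), n, 4,
                dimnames = list(NULL, c("TA", "MG", "RF", "ST")))
  etr <- make_env_trial(n = n, rate = rate, envelopes = env)
  ics <- c(0:10, 25, 26, 27)  # one 15 s outlier stride among 1 s strides
  ss <- build_stride_set(ics)
  expect_true(any(ss$outlier_flags))
  sm <- build_stride_matrix(etr, ss, "RF/ST")
  # rows equal per-stride interpolation done in isolation
  for (r in seq_along(sm$stride_ids)) {
    i <- sm$stride_ids[r]
    one <- build_stride_matrix(
      etr, structure(list(initial_contact_times_s = ics[i:(i + 1)] ,
                          stride_durations_s = diff(ics)[i],
                          outlier_flags = FALSE,
                          retained_stride_indices = 1L),
                     class = "stride_set"), "RF/ST")
    expect_equal(sm$muscle_1[r, ], one$muscle_1[1, ])
  }
})

test_that("segmentation plus interpolation reproduces the profile", {
  # wide bursts relative to the 6 Hz envelope bandwidth so the filter is
  # effectively transparent and the check isolates segmentation fidelity
  cfg <- tiny_config(
    strides_per_trial = 40, stride_time_mean_s = 1.5, stride_time_cv = 0.02,
    burst_centers = list(TA = 0.25, MG = 0.6, RF = 0.3, ST = 0.75),
    burst_widths = list(TA = 0.15, MG = 0.15, RF = 0.15, ST = 0.15),
    burst_amplitudes = list(TA = 1, MG = 1, RF = 1, ST = 1),
    noise_sd = 0)
  tr <- simulate_trial(cfg, "TD", "Dry", "Normal", seed = 8)
  etr <- process_trial(tr)
  ss <- build_stride_set(tr$true_initial_contacts_s)
  sm <- build_stride_matrix(etr, ss, "RF/ST")
  prof <- make_activation_profile("RF", cfg, "TD", "Dry", "Normal")
  truth <- sqrt(2 / pi) * prof(seq(0, 1, length.out = 101))
  est <- colMeans(sm$muscle_1)
  expect_lt(sqrt(mean((est - truth)^2)) / sqrt(mean(truth^2)), 0.02)
})

test_that("strides outside the recording are dropped, never padded", {
  etr <- make_env_trial(n = 2000)  # covers 1 s at 2000 Hz
  ss <- build_stride_set(c(0, 0.45, 0.9, 1.35, 1.8))
  sm <- build_stride_matrix(etr, ss, "RF/ST")
  expect_equal(sm$stride_ids, c(1L, 2L))
  ss_out <- build_stride_set(c(2, 3, 4))
  expect_error(build_stride_matrix(etr, ss_out, "RF/ST"),
               "no retained stride")
  expect_error(build_stride_matrix(etr, ss, "TA/RF"), "unknown pairing")
})
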