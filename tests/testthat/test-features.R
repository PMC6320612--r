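test_that("rms matches closed forms", {
  expect_lt(abs(rms(sine_wave(100, 2, amp = 3)) - 3 / sqrt(2)) / (3 / sqrt(2)),
            0.001)
  expect_equal(rms(rep(-4.2, 100)), 4.2)
  x <- rnorm(500)
  expect_equal(rms(c(x, x)), rms(x))          # concatenation invariance
  expect_error(rms(numeric(0)), "empty")
})

test_that("band_energy isolates a pure tone and matches the FFT oracle", {
  x <- sine_wave(75, 8)
  total <- fft_band_power(x, 1024, 0, 512)
  expect_gt(band_energy(x, 50, 100, fs = 1024) / total, 0.99)
  expect_lt(band_energy(x, 100, 200, fs = 1024) / total, 0.01)
  expect_equal(band_energy(x, 50, 100, fs = 1024),
               fft_band_power(x, 1024, 50, 100), tolerance = 0.01)
  expect_equal(band_energy(rep(0, 4096), 10, 200, fs = 1024), 0)
  expect_error(band_energy(x, 400, 600, fs = 1024), "Nyquist|band edges")
})

test_that("band_energy is flat for white noise and partitions total power", {
  set.seed(7)
  x <- rnorm(60 * 1024)
  e1 <- band_energy(x, 50, 100, fs = 1024)
  e2 <- band_energy(x, 150, 200, fs = 1024)
  expect_lt(abs(e1 - e2) / e1, 0.10)
  # Parseval-style partition over [0, fs/2)
  edges <- seq(0, 512, by = 64)
  y <- rnorm(10 * 1024)
  parts <- vapply(seq_len(length(edges) - 1), function(i)
    band_energy(y, edges[i], edges[i + 1], fs = 1024), numeric(1))
  expect_lt(abs(sum(parts) - mean(y^2)) / mean(y^2), 0.01)
})

test_that("burst detection finds planted plateaus, ordered by RMS, and matches exhaustive search", {
  fs <- 1024
  env <- rep(0.01, 12 * fs)
  centers <- c(2, 5.5, 9)
  heights <- c(3, 2, 1)
  for (i in 1:3) {
    a <- round((centers[i] - 0.5) * fs) + 1
    env[a:(a + fs - 1)] <- heights[i]
  }
  b <- detect_bursts(env, fs = fs)
  expect_equal(nrow(b), 3)
  expect_equal(b$rms, sort(b$rms, decreasing = TRUE))
  expect_equal(b$start_s + 0.5, centers, tolerance = 0.26)
  # greedy equals the exhaustive best triple (plateaus separated > 1 s)
  expect_equal(sort(b$start_s), exhaustive_bursts(env, fs))
  # non-overlap by construction
  expect_true(all(diff(sort(b$start_s)) >= 1))
})

test_that("burst tie-break on a constant envelope picks the earliest windows", {
  b <- detect_bursts(rep(2, 6 * 1024), fs = 1024)
  expect_equal(b$start_s, c(0, 1, 2))
  expect_equal(b$rms, rep(2, 3))
  expect_equal(b$var, rep(0, 3))
})

test_that("a single burst in silence dominates; short signals yield fewer bursts", {
  fs <- 1024
  env <- rep(0, 20 * fs)
  env[(5 * fs + 2):(6 * fs - 2)] <- 4   # burst strictly inside one window
  b <- detect_bursts(env, fs = fs)
  expect_gt(b$rms[1], 3.9)
  expect_lt(max(b$rms[-1]), 1e-9)
  expect_equal(b$start_s[1] + 0.5, 5.5, tolerance = 0.26)
})

test_that("active intervals follow the 1.5x whole-trial-RMS rule", {
  fs <- 1024
  # 25% duty square wave, high = 3 x low: threshold falls between the levels
  low <- 1; high <- 3
  env <- rep(c(rep(high, fs), rep(low, 3 * fs)), 5)
  act <- active_intervals(env, fs = fs)
  expect_equal(act$active_duration, 5, tolerance = 0.01)   # quarter of 20 s
  # quiet RMS recovers the low level
  expect_equal(quiet_rms(env, act, fs = fs), low, tolerance = 0.05)
  # constant envelope never exceeds 1.5 x its own RMS
  act_c <- active_intervals(rep(5, 4 * fs), fs = fs)
  expect_equal(nrow(act_c$intervals), 0)
  expect_equal(act_c$active_duration, 0)
  # no active intervals: quiet RMS is the whole-trial RMS
  expect_equal(quiet_rms(rep(5, 4 * fs), act_c, fs = fs), 5)
  # zero envelope
  expect_equal(active_intervals(rep(0, 2048), fs = 1024)$active_duration, 0)
  # fully active complement is empty: 0 with a warning
  expect_warning(
    q <- quiet_rms(env, data.frame(start_s = 0, end_s = 20), fs = fs),
    "no quiet")
  expect_equal(q, 0)
})

test_that("dominant_rms averages per-interval RMS of the filtered signal", {
  fs <- 1024
  x <- c(rep(2, fs), rep(0, fs), rep(4, fs))
  iv <- data.frame(start_s = c(0, 2), end_s = c(1, 3))
  expect_equal(dominant_rms(x, iv, fs = fs), 3)            # mean of 2 and 4
  expect_equal(dominant_rms(x, iv[1, , drop = FALSE], fs = fs), 2)
  expect_equal(dominant_rms(x, iv[0, ], fs = fs), 0)
})

test_that("feature vectors have the documented length and vanish on zero input", {
  zero <- emg_recording(rep(0, 4 * 1024), 1024)
  sf <- static_features(zero)
  expect_equal(names(sf), c("rms_env", "rms_filt", "e_50_100", "e_100_200"))
  expect_equal(unname(unlist(sf)), rep(0, 4))
  df <- dynamic_features(emg_recording(rep(0, 8 * 1024), 1024))
  expect_equal(ncol(df), 11)
  expect_equal(unname(unlist(df)), rep(0, 11))
})

test_that("features scale predictably with signal amplitude", {
  rec <- gen_dynamic_trial(6, 7, config = fast_config(), seed = 31)
  rec2 <- rec
  rec2$samples <- 3 * rec$samples
  f1 <- dynamic_features(rec)
  f2 <- dynamic_features(rec2)
  rms_cols <- c("rms_env", "p2p", "rms_quiet", "burst_rms_1", "burst_rms_2",
                "burst_rms_3", "dom_rms")
  var_cols <- c("burst_var_1", "burst_var_2", "burst_var_3")
  expect_equal(unlist(f2[rms_cols]), 3 * unlist(f1[rms_cols]),
               tolerance = 1e-5)
  expect_equal(unlist(f2[var_cols]), 9 * unlist(f1[var_cols]),
               tolerance = 1e-5)
  expect_equal(f2$t_active, f1$t_active)
  # static features: RMS-type scale by a, energies by a^2
  srec <- gen_static_trial(3, 2, config = fast_config(), seed = 32)
  srec2 <- srec
  srec2$samples <- 2 * srec$samples
  s1 <- static_features(srec)
  s2 <- static_features(srec2)
  expect_equal(s2$rms_env, 2 * s1$rms_env, tolerance = 1e-5)
  expect_equal(s2$rms_filt, 2 * s1$rms_filt, tolerance = 1e-5)
  expect_equal(s2$e_50_100, 4 * s1$e_50_100, tolerance = 1e-5)
  expect_equal(s2$e_100_200, 4 * s1$e_100_200, tolerance = 1e-5)
})

test_that("synthetic dynamic trials expose their scheduled bursts to the detector", {
  cfg <- fast_config()
  rec <- gen_dynamic_trial(8, 10, config = cfg, seed = 33)
  env <- emg_envelope(rec)
  b <- detect_bursts(env)
  sched <- attr(rec, "burst_times_s")
  for (s in b$start_s + 0.5)
    expect_lt(min(abs(s - sched)), 0.26)
})
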