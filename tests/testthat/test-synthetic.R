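test_that("baseline amplitude follows the activity mapping", {
  cfg <- fast_config()
  # activity 0: instrumentation noise floor only
  r0 <- gen_baseline(0, config = cfg, seed = 61)
  expect_lte(rms(r0), 1.1 * cfg$noise_floor_uV)
  # RMS ratio between activity 10 and 5 matches the configured mapping
  r10 <- gen_baseline(10, duration_s = 20, config = cfg, seed = 62)
  r5 <- gen_baseline(5, duration_s = 20, config = cfg, seed = 63)
  expected <- sqrt(cfg$noise_floor_uV^2 + (10 * cfg$activity_gain_uV)^2) /
    sqrt(cfg$noise_floor_uV^2 + (5 * cfg$activity_gain_uV)^2)
  expect_lt(abs(rms(r10) / rms(r5) - expected) / expected, 0.05)
  # different seeds: different paths, same RMS within 10%
  ra <- gen_baseline(6, config = cfg, seed = 64)
  rb <- gen_baseline(6, config = cfg, seed = 65)
  expect_gt(mean(abs(ra$samples - rb$samples)), 0)
  expect_lt(abs(rms(ra) - rms(rb)) / rms(ra), 0.10)
})

test_that("spasm trains are a no-op at severity 0 and energetic above it", {
  cfg <- fast_config()
  base <- gen_baseline(2, config = cfg, seed = 66)
  expect_identical(gen_spasms(base, 0, config = cfg, seed = 1), base)
  s2 <- gen_spasms(base, 2, config = cfg, seed = 67)
  s8 <- gen_spasms(base, 8, config = cfg, seed = 67)
  e2 <- band_energy(emg_bandpass(s2), 50, 100)
  e8 <- band_energy(emg_bandpass(s8), 50, 100)
  expect_gt(e8, e2)
})

test_that("spasm discharges are quasi-regular (interval CV < 0.3)", {
  cfg <- fast_config()
  long_base <- gen_baseline(0, duration_s = 120, config = cfg, seed = 68)
  for (sev in c(1, 4, 9)) {
    sp <- gen_spasms(long_base, sev, config = cfg, seed = 68 + sev)
    gaps <- diff(attr(sp, "spasm_times_s"))
    expect_gt(length(gaps), 5)
    expect_lt(sd(gaps) / mean(gaps), 0.3)
  }
})

test_that("dynamic trials encode modulation depth and activity in the envelope", {
  cfg <- fast_config()
  # no modulation: near-constant envelope, burst RMS spread < 10%
  flat <- gen_dynamic_trial(6, 0, config = cfg, seed = 71)
  b <- detect_bursts(emg_envelope(flat))
  expect_lt((max(b$rms) - min(b$rms)) / max(b$rms), 0.10)
  # full modulation: scheduled bursts recovered within 0.25 s
  mod <- gen_dynamic_trial(6, 10, config = cfg, seed = 72)
  bm <- detect_bursts(emg_envelope(mod))
  for (s in bm$start_s + 0.5)
    expect_lt(min(abs(s - attr(mod, "burst_times_s"))), 0.26)
  # higher activity: larger envelope RMS
  lo <- gen_dynamic_trial(3, 5, config = cfg, seed = 73)
  hi <- gen_dynamic_trial(10, 5, config = cfg, seed = 73)
  expect_gt(rms(emg_envelope(hi)), rms(emg_envelope(lo)))
})

test_that("cohort scores are zero-inflated, reproducible and asymmetry-controlled", {
  sc <- draw_cohort_scores(1000, "static", seed = 81)
  zero_frac <- mean(c(sc$spasm_severity_left, sc$spasm_severity_right) == 0)
  expect_gt(zero_frac, 0.55)
  expect_lt(zero_frac, 0.65)
  expect_identical(draw_cohort_scores(50, "dynamic", seed = 5),
                   draw_cohort_scores(50, "dynamic", seed = 5))
  cfg0 <- generator_config(asymmetry_sd = 0)
  sym <- draw_cohort_scores(200, "static", config = cfg0, seed = 82)
  expect_true(all(laterality(sym$activity_level_left,
                             sym$activity_level_right) == 0))
  expect_true(all(laterality(sym$spasm_severity_left,
                             sym$spasm_severity_right) == 0))
})

test_that("generated cohorts are finite, score-consistent and seed-deterministic", {
  cfg <- fast_config()
  coh <- gen_cohort(4, "static", config = cfg, seed = 83)
  expect_s3_class(coh, "emg_cohort")
  expect_equal(nrow(coh$trials), 8)
  expect_length(coh$recordings, 8)
  for (r in coh$recordings) {
    expect_true(all(is.finite(r$samples)))
    expect_gte(length(r$samples), 2 * r$fs)
  }
  expect_true(all(coh$trials$activity_level %in% 0:10))
  expect_true(all(coh$trials$spasm_severity %in% 0:10))
  coh2 <- gen_cohort(4, "static", config = cfg, seed = 83)
  expect_identical(coh$trials, coh2$trials)
  expect_identical(coh$recordings[[5]]$samples, coh2$recordings[[5]]$samples)
})

test_that("cohort features correlate monotonically with their driving scores", {
  coh <- gen_cohort(60, "static", seed = 84)
  f <- cohort_features(coh)
  expect_gt(cor(f$activity_level, f$rms_env, method = "spearman"), 0.9)
  expect_gt(cor(f$spasm_severity, f$e_50_100, method = "spearman"), 0.8)
})
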