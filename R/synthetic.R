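#' Configuration of the synthetic sEMG generator
#'
#' Collects every tunable of the synthetic cohort generator, with defaults
#' chosen to emulate the statistical structure of functional-evaluation
#' recordings: band-limited stochastic baseline EMG whose amplitude encodes
#' the activity level, superimposed quasi-periodic motor-unit action
#' potential (MUAP) trains encoding spasm severity, multi-burst amplitude
#' envelopes encoding amplitude modulation, and heavily zero-inflated score
#' distributions.
#'
#' Amplitude mappings: during static (isometric) tests the EMG amplitude is
#' linearly related to muscle output, so the activity mapping is linear
#' (`rms = activity_gain_uV * score` above a broadband instrumentation noise
#' floor). During dynamic tests the relationship between the features and
#' the scores is non-linear; the burst-amplitude mapping is concave
#' (`peak = burst_peak_base_uV + burst_peak_gain_uV * (score/10)^burst_peak_exponent`),
#' which is why a linear model shows a systematic bias trend and the bagged
#' trees do not.
#'
#' @param fs sampling rate, Hz.
#' @param static_duration_s duration of a static (rest) trial, s.
#' @param dynamic_duration_s duration of a dynamic trial, s.
#' @param emg_band_hz physiological band of the baseline EMG carrier, Hz.
#' @param noise_floor_uV RMS of the broadband instrumentation noise floor.
#' @param activity_gain_uV static-test EMG RMS per activity-score point.
#' @param muap_amp_uV peak amplitude of the biphasic MUAP template.
#' @param muap_sigma_ms width parameter of the MUAP template (total width
#'   about 6 sigma).
#' @param muap_rate_hz_per_score MUAP discharge rate per spasm-score point.
#' @param muap_jitter_cv coefficient of variation of the quasi-regular
#'   inter-spike intervals.
#' @param burst_times_s centers of the scheduled activity bursts of a
#'   dynamic trial (three lifting bursts and a fourth on returning upright).
#' @param burst_sigma_s temporal width of each burst, s.
#' @param burst_peak_base_uV,burst_peak_gain_uV,burst_peak_exponent concave
#'   mapping from activity level to burst peak amplitude.
#' @param quiet_floor_frac inter-burst envelope level at maximal amplitude
#'   modulation, as a fraction of the burst peak.
#' @param quiet_decay_exponent shape of the modulation-depth mapping.
#' @param amp_jitter_sd log-normal trial-to-trial amplitude jitter (sd of
#'   log amplitude).
#' @param static_activity_probs,static_spasm_probs,dynamic_activity_probs,
#'   dynamic_modulation_probs class-frequency tables over scores 0..10
#'   (each must sum to 1; spasm defaults are zero-inflated with 60% zeros).
#' @param asymmetry_sd sd of the rounded Gaussian left/right score offset;
#'   0 makes both sides identical (all laterality scores 0).
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(fs = 1024,
                             static_duration_s = 20,
                             dynamic_duration_s = 15,
                             emg_band_hz = c(100, 250),
                             noise_floor_uV = 2,
                             activity_gain_uV = 16,
                             muap_amp_uV = 500,
                             muap_sigma_ms = 2.5,
                             muap_rate_hz_per_score = 0.2,
                             muap_jitter_cv = 0.12,
                             burst_times_s = c(2, 5.5, 9, 12.5),
                             burst_sigma_s = 0.35,
                             burst_peak_base_uV = 10,
                             burst_peak_gain_uV = 140,
                             burst_peak_exponent = 0.35,
                             quiet_floor_frac = 0.08,
                             quiet_decay_exponent = 2.5,
                             amp_jitter_sd = 0.08,
                             static_activity_probs = zero_inflated_probs(0.35, 0.78),
                             static_spasm_probs = zero_inflated_probs(0.60, 0.70),
                             dynamic_activity_probs = discretized_normal_probs(4, 2.5),
                             dynamic_modulation_probs = discretized_normal_probs(3.5, 2.5),
                             asymmetry_sd = 0.8) {
  cfg <- list(fs = fs, static_duration_s = static_duration_s,
              dynamic_duration_s = dynamic_duration_s,
              emg_band_hz = emg_band_hz, noise_floor_uV = noise_floor_uV,
              activity_gain_uV = activity_gain_uV, muap_amp_uV = muap_amp_uV,
              muap_sigma_ms = muap_sigma_ms,
              muap_rate_hz_per_score = muap_rate_hz_per_score,
              muap_jitter_cv = muap_jitter_cv, burst_times_s = burst_times_s,
              burst_sigma_s = burst_sigma_s,
              burst_peak_base_uV = burst_peak_base_uV,
              burst_peak_gain_uV = burst_peak_gain_uV,
              burst_peak_exponent = burst_peak_exponent,
              quiet_floor_frac = quiet_floor_frac,
              quiet_decay_exponent = quiet_decay_exponent,
              amp_jitter_sd = amp_jitter_sd,
              static_activity_probs = static_activity_probs,
              static_spasm_probs = static_spasm_probs,
              dynamic_activity_probs = dynamic_activity_probs,
              dynamic_modulation_probs = dynamic_modulation_probs,
              asymmetry_sd = asymmetry_sd)
  stopifnot(fs > 0, static_duration_s > 0, dynamic_duration_s > 0,
            length(emg_band_hz) == 2L, emg_band_hz[1] < emg_band_hz[2],
            emg_band_hz[2] < fs / 2)
  for (nm in c("static_activity_probs", "static_spasm_probs",
               "dynamic_activity_probs", "dynamic_modulation_probs")) {
    p <- cfg[[nm]]
    if (length(p) != 11L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be 11 non-negative frequencies summing to 1",
           call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @param p0 probability mass on score 0.
#' @param decay geometric decay ratio across scores 1..10.
#' @export
zero_inflated_probs <- function(p0, decay) {
  tail_probs <- decay^(1:10)
  c(p0, (1 - p0) * tail_probs / sum(tail_probs))
}

#' @rdname generator_config
#' @param mean,sd parameters of the Gaussian that is discretized onto the
#'   integer scores 0..10.
#' @export
discretized_normal_probs <- function(mean, sd) {
  p <- exp(-((0:10) - mean)^2 / (2 * sd^2))
  p / sum(p)
}

# Band-limited unit-RMS Gaussian carrier emulating the physiological
# surface-EMG spectrum (4th-order Butterworth band-pass, zero phase).
emg_carrier <- function(n, fs, band_hz) {
  flt <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate baseline (rest) sEMG for a given activity level
#'
#' Broadband Gaussian instrumentation noise plus a band-limited stochastic
#' EMG component whose RMS grows linearly with the activity-level score
#' (EMG amplitude is linearly related to muscle output in isometric
#' conditions). Activity level 0 yields the instrumentation noise floor
#' only.
#'
#' @param activity_level integer score 0-10.
#' @param duration_s trial duration, s; defaults to the configured static
#'   trial duration.
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @param muscle,side,test,subject_id metadata for the recording.
#' @return an [emg_recording]; the mapped EMG component RMS is attached as
#'   attribute `"emg_rms_uV"` for oracle tests.
#' @export
gen_baseline <- function(activity_level, duration_s = NULL,
                         config = generator_config(), seed = NULL,
                         muscle = "paraspinal_L2", side = NA, test = "rest_sitting",
                         subject_id = NA) {
  stopifnot(activity_level %in% 0:10)
  if (is.null(duration_s)) duration_s <- config$static_duration_s
  n <- round(duration_s * config$fs)
  target <- config$activity_gain_uV * activity_level
  with_seed(seed, {
    x <- rnorm(n, sd = config$noise_floor_uV)
    if (activity_level > 0)
      x <- x + target * emg_carrier(n, config$fs, config$emg_band_hz)
    rec <- emg_recording(x, fs = config$fs, muscle = muscle, side = side,
                         test = test, subject_id = subject_id)
    attr(rec, "emg_rms_uV") <- target
    rec
  })
}

# Biphasic MUAP template (peak-normalized first derivative of a Gaussian),
# total width about 6 sigma.
muap_template <- function(fs, sigma_ms) {
  sigma <- sigma_ms / 1000
  t <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
  w <- (t / sigma) * exp(-t^2 / (2 * sigma^2))
  w / max(abs(w))
}

#' Superimpose a muscle-spasm MUAP train on a recording
#'
#' Muscle spasms appear in resting sEMG as large action potentials fired at
#' quasi-regular intervals by synchronized motor units. The generator adds
#' biphasic MUAP templates (about 15 ms wide) at quasi-regular times whose
#' rate grows with the spasm-severity score; severity 0 returns the input
#' unchanged.
#'
#' @param rec baseline [emg_recording].
#' @param spasm_severity integer score 0-10.
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return the recording with the MUAP train added; discharge times (s) are
#'   attached as attribute `"spasm_times_s"`.
#' @export
gen_spasms <- function(rec, spasm_severity, config = generator_config(),
                       seed = NULL) {
  stopifnot(spasm_severity %in% 0:10)
  if (spasm_severity == 0) return(rec)
  n <- length(rec$samples)
  fs <- rec$fs
  dur <- n / fs
  rate <- config$muap_rate_hz_per_score * spasm_severity
  mu <- 1 / rate
  with_seed(seed, {
    gaps <- rnorm(ceiling(dur / mu) + 20L, mean = mu,
                  sd = config$muap_jitter_cv * mu)
    gaps <- pmax(gaps, 0.2 * mu)
    times <- runif(1) * mu + cumsum(gaps)
    times <- times[times < dur - 0.02]
    tmpl <- muap_template(fs, config$muap_sigma_ms)
    half <- (length(tmpl) - 1L) %/% 2L
    x <- rec$samples
    for (tt in times) {
      amp <- config$muap_amp_uV * (1 + 0.1 * rnorm(1))
      center <- round(tt * fs)
      a <- center - half
      b <- a + length(tmpl) - 1L
      if (a >= 1L && b <= n) x[a:b] <- x[a:b] + amp * tmpl
    }
    out <- rec
    out$samples <- x
    attr(out, "spasm_times_s") <- times
    out
  })
}

#' Generate one static (rest) trial
#'
#' Convenience composition of [gen_baseline()] and [gen_spasms()].
#'
#' @inheritParams gen_baseline
#' @param spasm_severity integer score 0-10.
#' @return an [emg_recording] with generator attributes.
#' @export
gen_static_trial <- function(activity_level, spasm_severity,
                             config = generator_config(), seed = NULL, ...) {
  with_seed(seed, {
    rec <- gen_baseline(activity_level, config = config, ...)
    gen_spasms(rec, spasm_severity, config = config)
  })
}

#' Generate one dynamic (movement) trial
#'
#' The amplitude envelope of a dynamic trial holds a scheduled sequence of
#' activity bursts (three associated with the lifting task and a fourth
#' with returning to the upright position) over a quiet inter-burst level.
#' The burst peak amplitude grows (concavely) with the activity level; the
#' modulation depth — peak relative to the inter-burst level — grows with
#' the amplitude-modulation score, so that a score of 0 gives a
#' near-constant envelope. A band-limited Gaussian carrier is modulated by
#' this envelope, on top of the instrumentation noise floor.
#'
#' @param activity_level,amplitude_modulation integer scores 0-10.
#' @inheritParams gen_baseline
#' @return an [emg_recording]; attributes `"burst_times_s"` (scheduled
#'   burst centers), `"peak_uV"` and `"quiet_uV"` record the ground truth.
#' @export
gen_dynamic_trial <- function(activity_level, amplitude_modulation,
                              config = generator_config(), seed = NULL,
                              muscle = "paraspinal_L2", side = NA,
                              test = "fce_lifting", subject_id = NA) {
  stopifnot(activity_level %in% 0:10, amplitude_modulation %in% 0:10)
  fs <- config$fs
  n <- round(config$dynamic_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    jitter <- exp(config$amp_jitter_sd * rnorm(1))
    peak <- (config$burst_peak_base_uV + config$burst_peak_gain_uV *
               (activity_level / 10)^config$burst_peak_exponent) * jitter
    quiet <- peak * (config$quiet_floor_frac +
                       (1 - config$quiet_floor_frac) *
                       (1 - amplitude_modulation / 10)^config$quiet_decay_exponent)
    bump <- rowSums(vapply(config$burst_times_s, function(tb)
      exp(-(t - tb)^2 / (2 * config$burst_sigma_s^2)), numeric(n)))
    bump <- pmin(bump, 1)
    env <- quiet + (peak - quiet) * bump
    x <- rnorm(n, sd = config$noise_floor_uV) +
      env * emg_carrier(n, fs, config$emg_band_hz)
    rec <- emg_recording(x, fs = fs, muscle = muscle, side = side,
                         test = test, subject_id = subject_id)
    attr(rec, "burst_times_s") <- config$burst_times_s
    attr(rec, "peak_uV") <- peak
    attr(rec, "quiet_uV") <- quiet
    rec
  })
}

#' Draw the ground-truth score table of a synthetic cohort
#'
#' Samples per-trial left-side scores from the configured class-frequency
#' tables and derives the right-side scores by adding a rounded Gaussian
#' offset (sd `asymmetry_sd`, clipped to the scale), which exercises the
#' laterality derivation. Exposed separately from [gen_cohort()] so the
#' score distribution can be checked cheaply at large n.
#'
#' @param n_trials number of trials (left/right recording pairs).
#' @param protocol `"static"` or `"dynamic"`.
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return a data frame with one row per trial and columns
#'   `trial_id`, plus `<score_type>_left` / `<score_type>_right` for the two
#'   score types of the protocol.
#' @export
draw_cohort_scores <- function(n_trials, protocol = c("static", "dynamic"),
                               config = generator_config(), seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(n_trials >= 1)
  probs <- if (protocol == "static")
    list(activity_level = config$static_activity_probs,
         spasm_severity = config$static_spasm_probs)
  else
    list(activity_level = config$dynamic_activity_probs,
         amplitude_modulation = config$dynamic_modulation_probs)
  with_seed(seed, {
    out <- data.frame(trial_id = seq_len(n_trials))
    for (st in names(probs)) {
      left <- sample(0:10, n_trials, replace = TRUE, prob = probs[[st]])
      offset <- if (config$asymmetry_sd > 0)
        round(rnorm(n_trials, 0, config$asymmetry_sd)) else 0L
      right <- pmin(pmax(left + offset, 0L), 10L)
      out[[paste0(st, "_left")]] <- left
      out[[paste0(st, "_right")]] <- right
    }
    out
  })
}

#' Generate a score-annotated synthetic cohort
#'
#' Draws ground-truth scores with [draw_cohort_scores()] and generates the
#' left and right recordings of every trial ([gen_static_trial()] or
#' [gen_dynamic_trial()]). Fully reproducible for a given seed.
#'
#' @inheritParams draw_cohort_scores
#' @param test test-condition label for all trials; defaults to
#'   `"rest_sitting"` (static) or `"fce_lifting"` (dynamic).
#' @return an object of class `emg_cohort`: a list with `trials` (data
#'   frame, one row per recording: `trial_id`, `subject_id`, `test`,
#'   `muscle`, `side` and the two ground-truth score columns),
#'   `recordings` (list of [emg_recording] parallel to the rows),
#'   `protocol` and `config`.
#' @export
gen_cohort <- function(n_trials, protocol = c("static", "dynamic"),
                       config = generator_config(), seed = NULL, test = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(test))
    test <- if (protocol == "static") "rest_sitting" else "fce_lifting"
  with_seed(seed, {
    scores <- draw_cohort_scores(n_trials, protocol, config)
    rows <- list()
    recs <- list()
    k <- 0L
    for (i in seq_len(n_trials)) {
      for (side in c("left", "right")) {
        k <- k + 1L
        subj <- sprintf("S%04d", i)
        if (protocol == "static") {
          act <- scores[[paste0("activity_level_", side)]][i]
          spa <- scores[[paste0("spasm_severity_", side)]][i]
          recs[[k]] <- gen_static_trial(act, spa, config = config,
                                        side = side, test = test,
                                        subject_id = subj)
          rows[[k]] <- data.frame(trial_id = i, subject_id = subj,
                                  test = test, muscle = recs[[k]]$muscle,
                                  side = side, activity_level = act,
                                  spasm_severity = spa)
        } else {
          act <- scores[[paste0("activity_level_", side)]][i]
          am <- scores[[paste0("amplitude_modulation_", side)]][i]
          recs[[k]] <- gen_dynamic_trial(act, am, config = config,
                                         side = side, test = test,
                                         subject_id = subj)
          rows[[k]] <- data.frame(trial_id = i, subject_id = subj,
                                  test = test, muscle = recs[[k]]$muscle,
                                  side = side, activity_level = act,
                                  amplitude_modulation = am)
        }
      }
    }
    structure(list(trials = do.call(rbind, rows), recordings = recs,
                   protocol = protocol, config = config),
              class = "emg_cohort")
  })
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %s: %d recordings (%d trials x 2 sides), %g s @ %g Hz\n",
              x$protocol, nrow(x$trials), nrow(x$trials) / 2L,
              length(x$recordings[[1L]]$samples) / x$config$fs, x$config$fs))
  invisible(x)
}

#' Extract the feature table of a cohort
#'
#' Runs the static or dynamic feature extractor over every recording of a
#' synthetic cohort and binds the results to the trial metadata and
#' ground-truth scores.
#'
#' @param cohort an `emg_cohort` from [gen_cohort()].
#' @param ... forwarded to [static_features()] / [dynamic_features()].
#' @return a data frame: trial metadata and score columns followed by the
#'   feature columns.
#' @export
cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "emg_cohort"))
  fun <- if (cohort$protocol == "static") static_features else dynamic_features
  feats <- do.call(rbind, lapply(cohort$recordings, fun, ...))
  cbind(cohort$trials, feats)
}

#' Write a synthetic session to disk
#'
#' Materializes a small synthetic cohort in the package's on-disk layout:
#' one recording CSV per trial side, a YAML session manifest and a
#' long-format ground-truth score table — the inputs the command-line
#' pipeline consumes.
#'
#' @param dir output directory (created if needed).
#' @inheritParams gen_cohort
#' @return invisibly, a list with the manifest and score file paths.
#' @export
simulate_session <- function(dir, n_trials, protocol = c("static", "dynamic"),
                             config = generator_config(), seed = NULL,
                             test = NULL) {
  protocol <- match.arg(protocol)
  cohort <- gen_cohort(n_trials, protocol, config = config, seed = seed,
                       test = test)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- cohort$trials
  files <- character(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    files[k] <- sprintf("trial%03d_%s.csv", tr$trial_id[k], tr$side[k])
    write_recording(cohort$recordings[[k]], file.path(dir, files[k]))
  }
  manifest <- list(
    subject_id = "synthetic_cohort",
    protocol = "custom",
    trials = lapply(seq_len(nrow(tr)), function(k)
      list(test = tr$test[k], muscle = paste(tr$muscle[k], tr$trial_id[k]),
           side = tr$side[k], file = files[k]))
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  score_cols <- intersect(score_types, names(tr))
  scores <- do.call(rbind, lapply(score_cols, function(st)
    data.frame(subject = tr$subject_id, test = tr$test,
               muscle = paste(tr$muscle, tr$trial_id), side = tr$side,
               score_type = st, value = tr[[st]])))
  scores_path <- file.path(dir, "scores.csv")
  write_scores(scores, scores_path)
  invisible(list(manifest = manifest_path, scores = scores_path, dir = dir))
}
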