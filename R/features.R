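#' Root-mean-square amplitude
#'
#' @param x numeric vector or any signal object with a `samples` field.
#' @return `sqrt(mean(x^2))`, in the units of `x` (microvolts here).
#' @export
rms <- function(x) {
  s <- as_samples(x)
  if (length(s) == 0L) stop("cannot take the RMS of an empty series", call. = FALSE)
  sqrt(mean(s^2))
}

#' Band-limited signal power from an averaged periodogram
#'
#' Estimates the power spectral density by averaging periodograms over 1 s
#' rectangular windows with 50% overlap (a trailing partial window is
#' discarded) and integrates it over `[f_lo, f_hi)`. The value is a power
#' (microvolts squared), independent of trial duration, so that trials of
#' different lengths are comparable.
#'
#' @param x signal object or numeric vector.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @param fs sampling rate, needed only when `x` is a bare vector.
#' @param window_s periodogram window length in seconds.
#' @param overlap fractional window overlap.
#' @return band power in the squared units of `x`.
#' @export
band_energy <- function(x, f_lo, f_hi, fs = NULL, window_s = 1, overlap = 0.5) {
  s <- as_samples(x)
  fs <- signal_fs(x, fs)
  if (f_lo < 0 || f_hi <= f_lo || f_hi > fs / 2)
    stop("band edges must satisfy 0 <= f_lo < f_hi <= fs/2", call. = FALSE)
  nwin <- round(window_s * fs)
  if (length(s) < nwin)
    stop("signal shorter than one periodogram window", call. = FALSE)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq.int(1L, length(s) - nwin + 1L, by = step)
  nyq_bin <- nwin %/% 2L + 1L
  psd <- numeric(nyq_bin)
  for (st in starts) {
    seg <- s[st:(st + nwin - 1L)]
    p <- (Mod(fft(seg))^2) / (fs * nwin)          # two-sided PSD, uV^2/Hz
    p1 <- p[seq_len(nyq_bin)]
    if (nwin %% 2L == 0L) p1[2:(nyq_bin - 1L)] <- 2 * p1[2:(nyq_bin - 1L)]
    else p1[2:nyq_bin] <- 2 * p1[2:nyq_bin]
    psd <- psd + p1
  }
  psd <- psd / length(starts)
  freqs <- (seq_len(nyq_bin) - 1L) * fs / nwin
  df <- fs / nwin
  sum(psd[freqs >= f_lo & freqs < f_hi]) * df
}

#' Detect the main bursts of EMG activity
#'
#' Slides a 1 s rectangular window in steps of 0.25 s over the EMG envelope,
#' computes the envelope RMS in each window, and greedily selects the
#' non-overlapping windows with the largest RMS values (up to `n_bursts`),
#' ties broken by earlier start time. Short or flat signals may yield fewer
#' than `n_bursts` windows; downstream feature vectors pad the missing
#' entries with zeros.
#'
#' @param env an [emg_envelope] (or numeric vector plus `fs`).
#' @param n_bursts maximum number of bursts to return.
#' @param window_s window length, s.
#' @param step_s window step, s.
#' @param fs sampling rate for bare vectors.
#' @return a data frame with one row per burst, ordered by descending
#'   envelope RMS: `start_s`, `end_s`, `rms` (uV), `var` (uV^2).
#' @export
detect_bursts <- function(env, n_bursts = 3, window_s = 1, step_s = 0.25,
                          fs = NULL) {
  s <- as_samples(env)
  fs <- signal_fs(env, fs)
  nwin <- round(window_s * fs)
  if (length(s) < nwin + round(step_s * fs))
    stop("envelope too short for burst detection (need > 1 window + 1 step)",
         call. = FALSE)
  starts <- seq.int(1L, length(s) - nwin + 1L, by = round(step_s * fs))
  w_rms <- vapply(starts, function(st) sqrt(mean(s[st:(st + nwin - 1L)]^2)),
                  numeric(1))
  ord <- order(-w_rms, starts)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= n_bursts) break
    if (all(abs(starts[i] - starts[sel]) >= nwin)) sel <- c(sel, i)
  }
  out <- data.frame(
    start_s = (starts[sel] - 1L) / fs,
    end_s = (starts[sel] - 1L) / fs + window_s,
    rms = w_rms[sel],
    var = vapply(sel, function(i) {
      seg <- s[starts[i]:(starts[i] + nwin - 1L)]
      mean((seg - mean(seg))^2)
    }, numeric(1))
  )
  stopifnot(all(diff(sort(out$start_s)) >= window_s - 1e-9))  # non-overlap
  out
}

#' Detect intervals of muscle activity
#'
#' A sample is active when the envelope exceeds 1.5 times the envelope RMS
#' computed over the entire trial. Returns the maximal runs of active
#' samples and the total active duration.
#'
#' @inheritParams detect_bursts
#' @param threshold_factor multiple of the whole-trial envelope RMS.
#' @return a list: `intervals` (data frame `start_s`, `end_s`),
#'   `active_duration` in seconds, and the `threshold` used (uV).
#' @export
active_intervals <- function(env, threshold_factor = 1.5, fs = NULL) {
  s <- as_samples(env)
  fs <- signal_fs(env, fs)
  if (length(s) == 0L) stop("empty envelope", call. = FALSE)
  thr <- threshold_factor * sqrt(mean(s^2))
  act <- s > thr
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  intervals <- data.frame(start_s = (starts[keep] - 1L) / fs,
                          end_s = ends[keep] / fs)
  list(intervals = intervals,
       active_duration = sum(act) / fs,
       threshold = thr)
}

# Logical mask of active samples for an interval table.
interval_mask <- function(n, fs, intervals) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(n, round(intervals$end_s[i] * fs))
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

#' Envelope RMS while the muscle is silent or minimally active
#'
#' RMS of the envelope over the complement of the active intervals. A fully
#' active trial has no quiet samples; the function then returns 0 with a
#' warning.
#'
#' @param env an [emg_envelope] or numeric vector.
#' @param active interval table as returned by [active_intervals()] (either
#'   the list or its `intervals` element).
#' @param fs sampling rate for bare vectors.
#' @return quiet-period envelope RMS, uV.
#' @export
quiet_rms <- function(env, active, fs = NULL) {
  s <- as_samples(env)
  fs <- signal_fs(env, fs)
  intervals <- if (is.data.frame(active)) active else active$intervals
  quiet <- !interval_mask(length(s), fs, intervals)
  if (!any(quiet)) {
    warning("no quiet samples: muscle active for the whole trial", call. = FALSE)
    return(0)
  }
  sqrt(mean(s[quiet]^2))
}

#' Average RMS of the band-passed EMG over the active intervals
#'
#' For each active interval, the RMS of the band-passed signal within that
#' interval is computed; the values are averaged across intervals. Returns 0
#' when no interval is active.
#'
#' @param filtered an `emg_filtered` object (or numeric vector).
#' @inheritParams quiet_rms
#' @return mean per-interval RMS, uV.
#' @export
dominant_rms <- function(filtered, active, fs = NULL) {
  s <- as_samples(filtered)
  fs <- signal_fs(filtered, fs)
  intervals <- if (is.data.frame(active)) active else active$intervals
  if (nrow(intervals) == 0L) return(0)
  vals <- vapply(seq_len(nrow(intervals)), function(i) {
    a <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    b <- min(length(s), round(intervals$end_s[i] * fs))
    sqrt(mean(s[a:b]^2))
  }, numeric(1))
  mean(vals)
}

#' Static-test feature vector
#'
#' Features used to score the static (rest) tests: the envelope RMS
#' (`rms_env`, the activity-level proxy) and the three spasm-severity model
#' inputs — the RMS of the band-passed EMG (`rms_filt`) and the signal power
#' in the 50-100 Hz and 100-200 Hz bands (`e_50_100`, `e_100_200`).
#'
#' @param rec an [emg_recording].
#' @param envelope_from rectify the `"raw"` recording (default) or the
#'   `"filtered"` signal before low-pass filtering.
#' @param ... filter parameters forwarded to [emg_bandpass()].
#' @return a one-row data frame with columns
#'   `rms_env`, `rms_filt`, `e_50_100`, `e_100_200`.
#' @export
static_features <- function(rec, envelope_from = c("raw", "filtered"), ...) {
  envelope_from <- match.arg(envelope_from)
  check_min_duration(rec)
  filt <- emg_bandpass(rec, ...)
  env <- emg_envelope(if (envelope_from == "raw") rec else filt)
  data.frame(
    rms_env = rms(env),
    rms_filt = rms(filt),
    e_50_100 = band_energy(filt, 50, 100),
    e_100_200 = band_energy(filt, 100, 200)
  )
}

#' Dynamic-test feature vector
#'
#' The 11 features used to score the dynamic (movement) tests: envelope RMS,
#' peak-to-peak range of the band-passed EMG, quiet-period envelope RMS,
#' active duration, the envelope RMS of the three main bursts (descending),
#' the average RMS of the band-passed EMG over the active intervals, and the
#' envelope variance within each of the three main bursts. Missing bursts
#' (flat signals) contribute zeros.
#'
#' @inheritParams static_features
#' @return a one-row data frame with columns `rms_env`, `p2p`, `rms_quiet`,
#'   `t_active`, `burst_rms_1..3`, `dom_rms`, `burst_var_1..3`.
#' @export
dynamic_features <- function(rec, envelope_from = c("raw", "filtered"), ...) {
  envelope_from <- match.arg(envelope_from)
  check_min_duration(rec)
  filt <- emg_bandpass(rec, ...)
  env <- emg_envelope(if (envelope_from == "raw") rec else filt)
  act <- active_intervals(env)
  bursts <- detect_bursts(env)
  pad <- function(v) c(v, rep(0, 3))[1:3]
  b_rms <- pad(bursts$rms)
  b_var <- pad(bursts$var)
  data.frame(
    rms_env = rms(env),
    p2p = diff(range(filt$samples)),
    rms_quiet = if (nrow(act$intervals) > 0L) quiet_rms(env, act) else rms(env),
    t_active = act$active_duration,
    burst_rms_1 = b_rms[1], burst_rms_2 = b_rms[2], burst_rms_3 = b_rms[3],
    dom_rms = dominant_rms(filt, act),
    burst_var_1 = b_var[1], burst_var_2 = b_var[2], burst_var_3 = b_var[3]
  )
}

dynamic_feature_names <- c("rms_env", "p2p", "rms_quiet", "t_active",
                           "burst_rms_1", "burst_rms_2", "burst_rms_3",
                           "dom_rms", "burst_var_1", "burst_var_2",
                           "burst_var_3")
spasm_feature_names <- c("rms_filt", "e_50_100", "e_100_200")
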