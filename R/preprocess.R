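#' Elliptic band-pass filtering of raw sEMG
#'
#' Applies an 8th-order elliptic band-pass filter with passband edges at 20
#' and 400 Hz to suppress low-frequency motion artifacts and high-frequency
#' instrumentation noise. The filter is applied forward-backward
#' ([signal::filtfilt()]) so the output is zero-phase: burst timing is
#' preserved, at the cost of doubling the effective attenuation and passband
#' ripple (in dB). `order` refers to the designed filter, as is conventional.
#'
#' @param rec an [emg_recording] (or any object with `samples` and `fs`).
#' @param low_hz,high_hz passband edge frequencies in Hz.
#' @param order order of the designed band-pass filter (must be even).
#' @param ripple_db passband ripple of the elliptic design, dB.
#' @param atten_db stopband attenuation of the elliptic design, dB.
#' @return an object of class `emg_filtered` carrying the filtered samples,
#'   `fs`, and the source recording's metadata.
#' @export
emg_bandpass <- function(rec, low_hz = 20, high_hz = 400, order = 8,
                         ripple_db = 0.5, atten_db = 60) {
  x <- as_samples(rec)
  fs <- signal_fs(rec)
  if (fs <= 2 * high_hz)
    stop(sprintf("fs = %g Hz too low: the %g Hz passband edge must lie below Nyquist",
                 fs, high_hz), call. = FALSE)
  if (order %% 2 != 0)
    stop("band-pass `order` must be even (two edges per biquad pair)", call. = FALSE)
  # forward-backward IIR filtering needs a few settling lengths of data; the
  # slow edge (low_hz) dictates the transient scale
  settle <- ceiling(fs / low_hz)
  if (length(x) < 3 * settle)
    stop(sprintf("signal too short for stable filtering: %d samples, need >= %d",
                 length(x), 3 * settle), call. = FALSE)
  flt <- signal::ellip(order / 2, ripple_db, atten_db,
                       c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- signal::filtfilt(flt, x)
  structure(
    list(samples = y, fs = fs, muscle = rec$muscle, side = rec$side,
         test = rec$test, subject_id = rec$subject_id),
    class = "emg_filtered"
  )
}

#' sEMG envelope by rectification and elliptic low-pass filtering
#'
#' The envelope is obtained by full-wave rectifying the signal and low-pass
#' filtering the result with a 7th-order elliptic filter, cut-off 10 Hz,
#' applied forward-backward. A 10 Hz cut-off preserves the fast amplitude
#' modulation components that matter for spasm scoring. Small negative
#' excursions caused by IIR ringing are clipped to zero: an envelope is an
#' amplitude by definition.
#'
#' By default the envelope is computed from the raw recording (pass the
#' [emg_recording]); passing an `emg_filtered` object rectifies the
#' band-passed signal instead — both conventions are in use in the field.
#'
#' @param x an [emg_recording] or `emg_filtered` object.
#' @param cutoff_hz low-pass cut-off frequency, Hz.
#' @param order order of the elliptic low-pass design.
#' @param ripple_db,atten_db elliptic design parameters, dB.
#' @return an object of class `emg_envelope` (non-negative samples, `fs`,
#'   source metadata).
#' @export
emg_envelope <- function(x, cutoff_hz = 10, order = 7, ripple_db = 0.5,
                         atten_db = 60) {
  s <- as_samples(x)
  fs <- signal_fs(x)
  if (cutoff_hz >= fs / 2)
    stop("envelope cut-off must lie below Nyquist", call. = FALSE)
  settle <- ceiling(fs / cutoff_hz)
  if (length(s) < 3 * settle)
    stop(sprintf("signal too short for envelope extraction: %d samples, need >= %d",
                 length(s), 3 * settle), call. = FALSE)
  flt <- signal::ellip(order, ripple_db, atten_db, cutoff_hz / (fs / 2),
                       type = "low")
  env <- signal::filtfilt(flt, abs(s))
  env[env < 0] <- 0
  structure(
    list(samples = env, fs = fs, muscle = x$muscle, side = x$side,
         test = x$test, subject_id = x$subject_id),
    class = "emg_envelope"
  )
}
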