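# Independent oracles and small signal builders shared across the suite.

sine_wave <- function(freq, dur_s, fs = 1024, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t)
}

# Brute-force band power from the full-length FFT (two-sided, folded),
# independent of the windowed-periodogram implementation under test.
fft_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (fs * n)
  f <- (seq_len(n) - 1) * fs / n
  f_folded <- pmin(f, fs - f)
  sum(p[f_folded >= f_lo & f_folded < f_hi]) * fs / n
}

# Exhaustive burst search: enumerates every set of three pairwise
# non-overlapping 1 s windows (0.25 s grid) and returns the set whose
# descending-sorted RMS triple is lexicographically largest (the "three
# largest RMS values" selection), ties broken by earlier start times.
exhaustive_bursts <- function(env, fs, window_s = 1, step_s = 0.25) {
  nwin <- round(window_s * fs)
  starts <- seq.int(1L, length(env) - nwin + 1L, by = round(step_s * fs))
  w_rms <- vapply(starts, function(st) sqrt(mean(env[st:(st + nwin - 1L)]^2)),
                  numeric(1))
  better <- function(a, b) {          # lexicographic on (rms desc, start asc)
    if (is.null(b)) return(TRUE)
    ra <- sort(w_rms[a], decreasing = TRUE); rb <- sort(w_rms[b], decreasing = TRUE)
    for (m in 1:3) {
      if (ra[m] > rb[m] + 1e-12) return(TRUE)
      if (ra[m] < rb[m] - 1e-12) return(FALSE)
    }
    sum(starts[a]) < sum(starts[b])
  }
  best <- NULL
  k <- length(starts)
  for (i in 1:(k - 2)) for (j in (i + 1):(k - 1)) {
    if (starts[j] - starts[i] < nwin) next
    for (l in (j + 1):k) {
      if (starts[l] - starts[j] < nwin) next
      if (better(c(i, j, l), best)) best <- c(i, j, l)
    }
  }
  sort((starts[best] - 1L) / fs)
}

# Closed-form OLS with intercept via the normal equations.
ols_oracle <- function(X, y) {
  M <- cbind(1, as.matrix(X))
  drop(solve(t(M) %*% M, t(M) %*% y))
}

# Probe fitter that records which rows each cross-validation fold trained
# on; predicts the training mean.
probe_training_log <- new.env()
fit_probe <- function(features, scores, seed = NULL, ...) {
  probe_training_log$rows <- c(probe_training_log$rows,
                               list(features$.row_id))
  structure(list(mean = mean(scores)), class = "probe_model")
}
predict.probe_model <- function(object, newdata, clip = TRUE, ...) {
  rep(object$mean, nrow(newdata))
}
registerS3method("predict", "probe_model", predict.probe_model,
                 envir = asNamespace("stats"))

# Compact generator configuration for fast unit tests (short static trials,
# dynamic bursts squeezed into 8 s).
fast_config <- function(...) {
  generator_config(static_duration_s = 5, dynamic_duration_s = 8,
                   burst_times_s = c(1.2, 3.2, 5.2, 6.8), ...)
}
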