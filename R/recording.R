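#' Construct a surface EMG recording
#'
#' A single-channel sEMG time series in microvolts together with its
#' acquisition metadata. One recording corresponds to one muscle on one side
#' of the body during one test condition.
#'
#' @param samples numeric vector, amplitude in microvolts.
#' @param fs sampling rate in Hz (the acquisition system used here samples at
#'   1024 Hz).
#' @param muscle muscle label, e.g. `"paraspinal_L2"`.
#' @param side `"left"` or `"right"` (or `NA` when not applicable).
#' @param test test-condition label, e.g. `"rest_sitting"` or
#'   `"fce_lifting_flexed_knees"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs = 1024, muscle = NA_character_,
                          side = NA_character_, test = NA_character_,
                          subject_id = NA_character_) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording samples must be finite and free of NA", call. = FALSE)
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("`side` must be \"left\", \"right\" or NA", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, muscle = as.character(muscle),
         side = as.character(side), test = as.character(test),
         subject_id = as.character(subject_id)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s / %s / %s: %d samples @ %g Hz (%.2f s), RMS %.3g uV\n",
              x$test, x$muscle, x$side, length(x$samples), x$fs,
              length(x$samples) / x$fs, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.emg_recording <- function(x) length(x$samples)

# Extract the sample vector from a recording / filtered signal / envelope,
# or pass a plain numeric vector through.
as_samples <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x) && !is.null(x$samples)) return(x$samples)
  stop("cannot extract samples from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# Sampling rate of a signal object, or `fs` fallback for bare numerics.
signal_fs <- function(x, fs = NULL) {
  if (is.list(x) && !is.null(x$fs)) return(x$fs)
  if (!is.null(fs)) return(fs)
  stop("sampling rate unknown: pass a recording object or supply `fs`",
       call. = FALSE)
}

# Recordings must cover at least 2 s before any feature computation.
check_min_duration <- function(x, min_s = 2) {
  n <- length(as_samples(x))
  fs <- signal_fs(x)
  if (n < min_s * fs)
    stop(sprintf("signal too short: %.2f s, need at least %g s", n / fs, min_s),
         call. = FALSE)
  invisible(TRUE)
}
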