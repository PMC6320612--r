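#' Read sEMG recordings from a delimited text file
#'
#' Accepts the package's on-disk convention: a comma-delimited UTF-8 table
#' with a one-line header whose first column is time in seconds (`time_s`)
#' and whose remaining column(s) hold channel amplitudes in microvolts.
#' A two-column file yields one recording; a wide file yields one recording
#' per value column, all sharing the sampling rate inferred from the time
#' axis (median time step, inverted and rounded to the nearest Hz).
#'
#' Up to 1% missing samples per channel are repaired by linear interpolation
#' (with a warning); more than that rejects the file, as does a
#' non-monotonic time column.
#'
#' @param path file to read.
#' @param channel_meta optional data frame with columns `channel`, `muscle`,
#'   `side` used to label wide-format channels; matched by column name.
#' @param test,subject_id metadata attached to every returned recording.
#' @return an [emg_recording] for a two-column file, otherwise a named list
#'   of recordings.
#' @export
read_recording <- function(path, channel_meta = NULL, test = NA_character_,
                           subject_id = NA_character_) {
  tab <- read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("recording file must have a time column and at least one channel: ",
         path, call. = FALSE)
  tt <- as.numeric(tab[[1L]])
  if (anyNA(tt) || any(diff(tt) <= 0))
    stop("malformed recording file (non-monotonic or non-numeric time column): ",
         path, call. = FALSE)
  fs <- round(1 / median(diff(tt)))
  chans <- names(tab)[-1L]
  recs <- lapply(chans, function(ch) {
    v <- as.numeric(tab[[ch]])
    n_na <- sum(is.na(v))
    if (n_na > 0.01 * length(v))
      stop(sprintf("channel '%s' has %.1f%% missing samples (> 1%%): %s",
                   ch, 100 * n_na / length(v), path), call. = FALSE)
    if (n_na > 0L) {
      warning(sprintf("channel '%s': interpolating %d missing sample(s)",
                      ch, n_na), call. = FALSE)
      v <- approx(tt[!is.na(v)], v[!is.na(v)], xout = tt, rule = 2)$y
    }
    muscle <- ch
    side <- NA_character_
    if (!is.null(channel_meta)) {
      hit <- match(ch, channel_meta$channel)
      if (!is.na(hit)) {
        muscle <- channel_meta$muscle[hit]
        side <- channel_meta$side[hit]
      }
    }
    emg_recording(v, fs = fs, muscle = muscle, side = side, test = test,
                  subject_id = subject_id)
  })
  names(recs) <- chans
  if (length(recs) == 1L) recs[[1L]] else recs
}

#' Write one or more recordings to a delimited text file
#'
#' Inverse of [read_recording()]: writes a `time_s` column followed by one
#' amplitude column per recording. All recordings must share `fs` and length.
#'
#' @param rec an [emg_recording] or a named list of them.
#' @param path destination file.
#' @export
write_recording <- function(rec, path) {
  recs <- if (inherits(rec, "emg_recording")) list(value_uV = rec) else rec
  fs <- unique(vapply(recs, `[[`, numeric(1), "fs"))
  ns <- unique(vapply(recs, function(r) length(r$samples), integer(1)))
  if (length(fs) != 1L || length(ns) != 1L)
    stop("all channels must share sampling rate and length", call. = FALSE)
  out <- data.frame(time_s = (seq_len(ns) - 1) / fs)
  for (nm in names(recs)) out[[nm]] <- recs[[nm]]$samples
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

score_types <- c("activity_level", "spasm_severity", "amplitude_modulation")

#' Read an expert score table
#'
#' Long-format table with columns `subject`, `test`, `muscle`, `side`,
#' `score_type`, `value`. Scores are the EMG expert's 0-10 ordinal ratings;
#' `score_type` must be one of `activity_level`, `spasm_severity` (static
#' tests) or `amplitude_modulation` (dynamic tests). Laterality of activity
#' is derived, never stored.
#'
#' @param path file to read.
#' @return a validated data frame of scored trials.
#' @export
read_scores <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "test", "muscle", "side", "score_type", "value")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty score table: ", path, call. = FALSE)
    return(tab[, need])
  }
  bad_type <- !tab$score_type %in% score_types
  if (any(bad_type))
    stop("unknown score_type in row(s) ",
         paste(which(bad_type), collapse = ", "), ": ",
         paste(unique(tab$score_type[bad_type]), collapse = ", "),
         call. = FALSE)
  v <- tab$value
  bad_val <- is.na(v) | v != round(v) | v < 0 | v > 10
  if (any(bad_val))
    stop("score value outside the 0-10 integer scale in row(s) ",
         paste(which(bad_val), collapse = ", "), call. = FALSE)
  tab$value <- as.integer(v)
  tab[, need]
}

#' @rdname read_scores
#' @param scores data frame as returned by [read_scores()].
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a session manifest
#'
#' A manifest (YAML or JSON, chosen by file extension) lists the recordings
#' of one evaluation session: `subject_id`, `protocol` (`cervical`, `back`
#' or `custom`) and a `trials` list of `(test, muscle, side, file)` entries.
#' Optional `load_cell` file references are carried through untouched; force
#' data is never analyzed here.
#'
#' @param path manifest file (`.yaml`/`.yml` or `.json`).
#' @return a list with `subject_id`, `protocol`, `trials` (data frame) and
#'   any `load_cell` entries.
#' @export
read_manifest <- function(path) {
  man <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::yaml.load_file(path)
  if (is.null(man$subject_id) || is.null(man$protocol) || is.null(man$trials))
    stop("manifest must define subject_id, protocol and trials", call. = FALSE)
  if (!man$protocol %in% c("cervical", "back", "custom"))
    stop("unknown protocol: ", man$protocol, call. = FALSE)
  trials <- man$trials
  if (!is.data.frame(trials))
    trials <- do.call(rbind, lapply(trials, function(tr)
      data.frame(test = tr$test, muscle = tr$muscle, side = tr$side,
                 file = tr$file, stringsAsFactors = FALSE)))
  key <- paste(trials$test, trials$muscle, trials$side)
  if (anyDuplicated(key))
    stop("duplicate (test, muscle, side) triple(s) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  files <- file.path(dirname(path), trials$file)
  missing <- !file.exists(files)
  if (any(missing))
    stop("manifest references missing file(s): ",
         paste(trials$file[missing], collapse = ", "), call. = FALSE)
  man$trials <- trials
  man
}

#' Write feature tables and evaluation reports
#'
#' Plain CSV with a deterministic column order (as passed) and floating
#' point values rendered with 6 significant digits, so that a write/read
#' round trip reproduces every numeric field to that precision.
#'
#' @param x data frame of features or an evaluation report.
#' @param path destination file.
#' @export
write_features <- function(x, path) {
  out <- x
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
write_report <- function(x, path) write_features(x, path)

#' @rdname write_features
#' @export
read_features <- function(path) read.csv(path, stringsAsFactors = FALSE)
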