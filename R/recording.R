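#' Multi-channel telemetry recording
#'
#' Container for a raw telemetry recording: EEG and EMG sampled at a common
#' rate (nominally 500 Hz, in mV) plus an activity channel (counts, nominally
#' 1 Hz). The light cycle defaults to lights on 07:00, lights off 19:00.
#'
#' Invariants enforced at construction: EEG and EMG have equal sample counts
#' and equal rates; the activity channel covers the same duration to within
#' one 20-s epoch; all rates are strictly positive; the recording is at least
#' one epoch long (shorter recordings are rejected, not padded).
#'
#' @param eeg,emg numeric vectors, mV.
#' @param activity numeric vector of activity counts.
#' @param eeg_rate,emg_rate,activity_rate sampling rates, Hz.
#' @param animal_id identifier.
#' @param start_time POSIXct start of recording (GMT).
#' @param lights_on,lights_off clock times, "HH:MM".
#' @param epoch_s scoring epoch length, seconds.
#' @return An object of class `phenomap_recording`.
#' @export
recording <- function(eeg, emg, activity,
                      eeg_rate = 500, emg_rate = 500, activity_rate = 1,
                      animal_id = "animal", start_time = NULL,
                      lights_on = "07:00", lights_off = "19:00",
                      epoch_s = 20) {
  if (is.null(start_time)) {
    start_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  }
  stopifnot(is.numeric(eeg), is.numeric(emg), is.numeric(activity))
  if (eeg_rate <= 0 || emg_rate <= 0 || activity_rate <= 0) {
    stop("sampling rates must be strictly positive", call. = FALSE)
  }
  if (length(eeg) != length(emg)) {
    stop("EEG and EMG must have equal sample counts", call. = FALSE)
  }
  if (eeg_rate != emg_rate) {
    stop("EEG and EMG must share a sampling rate", call. = FALSE)
  }
  dur <- length(eeg) / eeg_rate
  if (dur < epoch_s) {
    stop("recording shorter than one epoch (", epoch_s, " s) rejected",
         call. = FALSE)
  }
  if (abs(length(activity) / activity_rate - dur) > epoch_s) {
    stop("activity duration does not match signal duration within one epoch",
         call. = FALSE)
  }
  structure(
    list(animal_id = animal_id, eeg = eeg, emg = emg, activity = activity,
         eeg_rate = eeg_rate, emg_rate = emg_rate,
         activity_rate = activity_rate,
         start_time = start_time, lights_on = lights_on,
         lights_off = lights_off, epoch_s = epoch_s),
    class = "phenomap_recording"
  )
}

#' @export
print.phenomap_recording <- function(x, ...) {
  cat("<phenomap_recording> ", x$animal_id, "\n", sep = "")
  cat("  EEG/EMG: ", length(x$eeg), " samples @ ", x$eeg_rate, " Hz (",
      round(length(x$eeg) / x$eeg_rate / 3600, 2), " h)\n", sep = "")
  cat("  activity: ", length(x$activity), " samples @ ", x$activity_rate,
      " Hz\n", sep = "")
  cat("  start: ", format(x$start_time, tz = "UTC", usetz = TRUE),
      "; lights ", x$lights_on, "-", x$lights_off, "\n", sep = "")
  invisible(x)
}

#' Number of whole scoring epochs in a recording
#' @param rec a `phenomap_recording`.
#' @export
n_epochs <- function(rec) {
  floor(length(rec$eeg) / (rec$eeg_rate * rec$epoch_s))
}

# sample index range of epoch i (1-based) at a given rate
epoch_slice <- function(i, rate, epoch_s = 20) {
  n <- round(rate * epoch_s)
  ((i - 1L) * n + 1L):(i * n)
}

#' Read a telemetry recording from disk
#'
#' CSV is the canonical interchange format: one file with `eeg`, `emg` and
#' `activity` columns (activity padded with NA to the EEG length) and
#' metadata in `# key=value` comment lines. EDF is accepted for raw signals
#' (16-bit; light-cycle metadata falls back to defaults).
#'
#' @param path file path.
#' @param format "csv" or "edf"; inferred from the extension when missing.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_recording_edf(path))

  meta <- read_meta_comments(path)
  df <- read.csv(path, comment.char = "#")
  for (ch in c("eeg", "emg")) {
    if (!ch %in% names(df)) {
      stop("missing channel '", ch, "' in ", path, call. = FALSE)
    }
  }
  if (!"activity" %in% names(df)) {
    stop("missing channel 'activity' in ", path, call. = FALSE)
  }
  act <- df$activity[!is.na(df$activity)]
  recording(
    eeg = df$eeg, emg = df$emg, activity = act,
    eeg_rate = as.numeric(meta[["eeg_rate"]] %||% 500),
    emg_rate = as.numeric(meta[["emg_rate"]] %||% 500),
    activity_rate = as.numeric(meta[["activity_rate"]] %||% 1),
    animal_id = meta[["animal_id"]] %||% "animal",
    start_time = as.POSIXct(meta[["start_time"]] %||% "2024-01-01 00:00:00",
                            tz = "UTC"),
    lights_on = meta[["lights_on"]] %||% "07:00",
    lights_off = meta[["lights_off"]] %||% "19:00"
  )
}

#' Write a recording to CSV
#' @param rec a `phenomap_recording`.
#' @param path output path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "phenomap_recording"))
  act <- c(rec$activity, rep(NA_real_,
                             max(0L, length(rec$eeg) - length(rec$activity))))
  meta <- c(
    paste0("# animal_id=", rec$animal_id),
    paste0("# eeg_rate=", rec$eeg_rate),
    paste0("# emg_rate=", rec$emg_rate),
    paste0("# activity_rate=", rec$activity_rate),
    paste0("# start_time=", format(rec$start_time, "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC")),
    paste0("# lights_on=", rec$lights_on),
    paste0("# lights_off=", rec$lights_off)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(data.frame(eeg = rec$eeg, emg = rec$emg, activity = act),
            con, row.names = FALSE)
  invisible(path)
}

read_meta_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  as.list(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
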