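#' Per-epoch signal grid
#'
#' The "signal grid": one row per 20-s epoch with timestamp, stage label
#' (`W`, `S`, `P`, `ARTIFACT`, `UNSCORED`), RMS-EMG, its recording-wide
#' z-score, the seven relative band powers (percent of 0.3-80 Hz total) and
#' an artifact flag. Extra columns (scoring ratios, activity) travel along
#' untouched.
#'
#' @param df data frame with at least `epoch`, `timestamp`, `stage`.
#' @param epoch_s epoch length, seconds.
#' @return A tibble of class `phenomap_grid`.
#' @export
epoch_grid <- function(df, epoch_s = 20) {
  df <- as_tibble(df)
  needed <- c("epoch", "timestamp", "stage")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("epoch grid missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$stage), STAGE_TOKENS)
  if (length(bad)) {
    stop("unknown stage token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("rms_emg", "z_rms_emg", BAND_NAMES, "artifact_flag")) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "artifact_flag") {
        df$stage == "ARTIFACT"
      } else {
        NA_real_
      }
    }
  }
  df <- check_band_sums(df)
  structure(df, epoch_s = epoch_s,
            class = c("phenomap_grid", class(df)))
}

BAND_NAMES <- c("delta", "theta", "alpha", "sigma", "beta",
                "low_gamma", "high_gamma")

# relative band powers are percentages; a physically valid row sums to
# at most 100 (plus numerical tolerance) because the notch and sub-band
# margins sit in the denominator only
check_band_sums <- function(df, tol = 0.5) {
  bp <- as.matrix(df[, BAND_NAMES])
  if (all(is.na(bp))) return(df)
  sums <- rowSums(bp)
  bad <- which(is.finite(sums) & sums > 100 + tol)
  if (length(bad)) {
    warning("band-power sums exceed 100% in ", length(bad), " row(s): ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ...", call. = FALSE)
    attr(df, "band_power_violations") <- bad
  }
  df
}

#' Read / write an epoch grid as CSV
#'
#' Lossless round-trip of all grid fields; timestamps are ISO-8601 UTC.
#' Unknown stage tokens are a parse error; rows whose relative band powers
#' sum above 100% raise a warning and are flagged in the
#' `band_power_violations` attribute.
#'
#' @param path CSV path.
#' @return [read_epoch_grid()] returns a `phenomap_grid` tibble.
#' @export
read_epoch_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  if ("artifact_flag" %in% names(df)) {
    df$artifact_flag <- as.logical(df$artifact_flag)
  }
  epoch_grid(df)
}

#' @rdname read_epoch_grid
#' @param grid a `phenomap_grid`.
#' @export
write_epoch_grid <- function(grid, path) {
  df <- as.data.frame(grid)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

clock_minutes <- function(hhmm) {
  p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

#' Split an epoch grid into light- and dark-phase epochs
#'
#' An epoch belongs to the phase containing its start timestamp; the light
#' phase is the half-open interval `[lights_on, lights_off)`. The partition
#' is exhaustive and disjoint.
#'
#' @param grid a `phenomap_grid`.
#' @param lights_on,lights_off clock times "HH:MM".
#' @return A list with elements `light` and `dark`.
#' @export
split_light_dark <- function(grid, lights_on = "07:00", lights_off = "19:00") {
  on_m <- clock_minutes(lights_on)
  off_m <- clock_minutes(lights_off)
  if (on_m == off_m) {
    stop("degenerate light cycle: lights_on equals lights_off", call. = FALSE)
  }
  is_light <- epoch_is_light(grid$timestamp, on_m, off_m)
  list(light = grid[is_light, , drop = FALSE],
       dark = grid[!is_light, , drop = FALSE])
}

epoch_is_light <- function(timestamp, on_m, off_m) {
  mins <- as.integer(format(timestamp, "%H", tz = "UTC")) * 60 +
    as.integer(format(timestamp, "%M", tz = "UTC")) +
    as.integer(format(timestamp, "%S", tz = "UTC")) / 60
  if (on_m < off_m) {
    mins >= on_m & mins < off_m
  } else {                      # light phase wraps midnight
    mins >= on_m | mins < off_m
  }
}
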