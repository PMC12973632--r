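#' Fill per-epoch RMS-EMG into a grid
#'
#' Root-mean-square of the raw EMG samples of each 20-s window.
#'
#' @param rec a [recording()].
#' @param grid a `phenomap_grid` aligned to `rec`.
#' @return The grid with `rms_emg` filled.
#' @export
rms_emg_grid <- function(rec, grid) {
  n <- nrow(grid)
  if (n != n_epochs(rec)) {
    stop("grid and recording have different epoch counts", call. = FALSE)
  }
  grid$rms_emg <- vapply(seq_len(n), function(i) {
    x <- rec$emg[epoch_slice(i, rec$emg_rate, rec$epoch_s)]
    sqrt(mean(x^2))
  }, 0.0)
  grid
}

#' z-score the RMS-EMG over the whole recording
#'
#' Mean and SD are computed over all non-artifact epochs with finite RMS;
#' the SD is the population SD (divide by n), matching the spreadsheet
#' convention of the original workflow (switchable). Artifact epochs get
#' NaN; a zero-SD recording yields all-zero z with a warning.
#'
#' @param grid a grid with `rms_emg`.
#' @param population use population (n) rather than sample (n-1) SD.
#' @return The grid with `z_rms_emg` filled.
#' @export
zscore_rms <- function(grid, population = TRUE) {
  keep <- !grid$artifact_flag & is.finite(grid$rms_emg)
  if (sum(keep) < 2) {
    stop("need at least 2 non-artifact epochs with finite RMS", call. = FALSE)
  }
  x <- grid$rms_emg[keep]
  mu <- mean(x)
  s <- if (population) sqrt(mean((x - mu)^2)) else sd(x)
  z <- rep(NaN, nrow(grid))
  if (s == 0) {
    warning("zero RMS-EMG variance; all z-scores set to 0", call. = FALSE)
    z[keep] <- 0
  } else {
    z[keep] <- (grid$rms_emg[keep] - mu) / s
  }
  grid$z_rms_emg <- z
  grid
}

#' Detect RBD-like events (REM without atonia)
#'
#' An RBD-like event is a REM-scored (`P`) epoch whose z-scored RMS-EMG
#' strictly exceeds the threshold (2 SD by default). Counts are reported for
#' the whole day and per light/dark phase. Animals with no REM epochs at all
#' are flagged for exclusion from RBD statistics.
#'
#' @param grid a scored grid with `z_rms_emg`.
#' @param z_threshold z-score cut, strict.
#' @param lights_on,lights_off clock times for the phase split.
#' @return One-row tibble (class `phenomap_rbd`) with REM/RBD counts per
#'   phase, the RBD ratio, mean REM EMG z, and `excluded_no_rem`.
#' @export
detect_rbd <- function(grid, z_threshold = 2,
                       lights_on = "07:00", lights_off = "19:00") {
  is_rem <- grid$stage == "P"
  is_rbd <- is_rem & is.finite(grid$z_rms_emg) &
    grid$z_rms_emg > z_threshold
  is_light <- epoch_is_light(grid$timestamp, clock_minutes(lights_on),
                             clock_minutes(lights_off))
  n_rem <- sum(is_rem)
  out <- tibble(
    n_rem_epochs = n_rem,
    n_rbd_epochs = sum(is_rbd),
    rbd_ratio = if (n_rem > 0) sum(is_rbd) / n_rem else NA_real_,
    n_rem_light = sum(is_rem & is_light),
    n_rem_dark = sum(is_rem & !is_light),
    n_rbd_light = sum(is_rbd & is_light),
    n_rbd_dark = sum(is_rbd & !is_light),
    mean_emg_rem = if (n_rem > 0) {
      mean(grid$z_rms_emg[is_rem], na.rm = TRUE)
    } else {
      NA_real_
    },
    excluded_no_rem = n_rem == 0
  )
  class(out) <- c("phenomap_rbd", class(out))
  out
}

#' Sleep-architecture summary
#'
#' A bout ("event") is a maximal run of consecutive identical W/S/P labels;
#' artifact or unscored epochs terminate a run and are excluded from the
#' percent-time denominator. Percent time is reported for the whole day and
#' per light/dark phase; bout statistics are over the whole day.
#'
#' @param grid a scored grid.
#' @param lights_on,lights_off clock times.
#' @return tibble with one row per stage: `percent_day`, `percent_light`,
#'   `percent_dark`, `n_bouts`, `mean_bout_s`, `longest_bout_s`.
#' @export
architecture_summary <- function(grid, lights_on = "07:00",
                                 lights_off = "19:00") {
  epoch_s <- attr(grid, "epoch_s") %||% 20
  scored <- grid$stage %in% STAGES
  is_light <- epoch_is_light(grid$timestamp, clock_minutes(lights_on),
                             clock_minutes(lights_off))
  pct <- function(keep) {
    denom <- sum(scored & keep)
    if (denom == 0) return(setNames(rep(NaN, 3), STAGES))
    vapply(STAGES, function(s) 100 * sum(grid$stage == s & keep) / denom, 0.0)
  }
  p_day <- pct(rep(TRUE, nrow(grid)))
  p_light <- pct(is_light)
  p_dark <- pct(!is_light)

  r <- rle(grid$stage)
  runs <- tibble(stage = r$values, len = r$lengths)
  runs <- runs[runs$stage %in% STAGES, ]
  bout <- dplyr::summarise(
    dplyr::group_by(runs, .data$stage),
    n_bouts = dplyr::n(),
    mean_bout_s = mean(.data$len) * epoch_s,
    longest_bout_s = max(.data$len) * epoch_s,
    .groups = "drop"
  )
  out <- dplyr::left_join(
    tibble(stage = STAGES, percent_day = p_day, percent_light = p_light,
           percent_dark = p_dark),
    bout, by = "stage"
  )
  out$n_bouts[is.na(out$n_bouts)] <- 0L
  out
}

# stage classes used for band-power and photometry conditioning: wake,
# NREM, atonic REM, and RBD-like (REM with z-EMG above threshold)
stage_classes <- function(grid, z_threshold = 2) {
  cls <- rep(NA_character_, nrow(grid))
  cls[grid$stage == "W"] <- "W"
  cls[grid$stage == "S"] <- "S"
  rem <- grid$stage == "P"
  rbd <- rem & is.finite(grid$z_rms_emg) & grid$z_rms_emg > z_threshold
  cls[rem & !rbd] <- "P_atonic"
  cls[rbd] <- "P_rbd"
  cls
}

#' Mean band powers per stage class
#'
#' Group means of the relative band powers per stage, with RBD-like epochs
#' (REM, z-EMG above threshold) forming their own class distinct from
#' atonic REM. Empty classes yield NaN with a warning.
#'
#' @param grid a scored grid with band powers and `z_rms_emg`.
#' @param z_threshold RBD z-score cut.
#' @return tibble with `class`, `band`, `mean_power`, `n_epochs`.
#' @export
stage_band_profile <- function(grid, z_threshold = 2) {
  cls <- stage_classes(grid, z_threshold)
  all_classes <- c("W", "S", "P_atonic", "P_rbd")
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(grid)[, BAND_NAMES], class = cls),
    cols = dplyr::all_of(BAND_NAMES),
    names_to = "band", values_to = "power"
  )
  long <- long[!is.na(long$class), ]
  out <- tidyr::complete(
    dplyr::summarise(
      dplyr::group_by(long, .data$class, .data$band),
      mean_power = mean(.data$power, na.rm = TRUE),
      n_epochs = dplyr::n(), .groups = "drop"
    ),
    class = all_classes, band = BAND_NAMES,
    fill = list(mean_power = NaN, n_epochs = 0L)
  )
  if (any(out$n_epochs == 0)) {
    warning("empty stage class(es): ",
            paste(unique(out$class[out$n_epochs == 0]), collapse = ", "),
            call. = FALSE)
  }
  out
}
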