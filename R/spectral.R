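#' Periodogram band scheme
#'
#' The seven frequency bands used for per-epoch relative power: Delta
#' 0.5-4 Hz, Theta 4-8, Alpha 8-12, Sigma 12-16, Beta 16-24, Low Gamma
#' 24-49, High Gamma 51-80; the total-power denominator spans 0.3-80 Hz, so
#' the 49-51 Hz gap and the 0.3-0.5 Hz margin count toward the total but not
#' toward any band. Band intervals are half-open `[f_lo, f_hi)`, so shared
#' edges are never double-counted (4 Hz belongs to Theta).
#'
#' @param bands tibble with columns `band`, `f_lo`, `f_hi`.
#' @param total_range length-2 numeric, Hz.
#' @return A tibble of class `phenomap_bands`.
#' @export
band_scheme <- function(bands = NULL, total_range = c(0.3, 80)) {
  if (is.null(bands)) {
    bands <- tibble(
      band = BAND_NAMES,
      f_lo = c(0.5, 4, 8, 12, 16, 24, 51),
      f_hi = c(4, 8, 12, 16, 24, 49, 80)
    )
  }
  bands <- as_tibble(bands)
  stopifnot(all(c("band", "f_lo", "f_hi") %in% names(bands)))
  o <- order(bands$f_lo)
  b <- bands[o, ]
  if (any(b$f_hi[-nrow(b)] > b$f_lo[-1])) {
    stop("bands overlap", call. = FALSE)
  }
  if (any(b$f_lo < total_range[1]) || any(b$f_hi > total_range[2])) {
    stop("every band must lie inside the total-power range", call. = FALSE)
  }
  structure(bands, total_range = total_range,
            class = c("phenomap_bands", class(bands)))
}

#' Welch spectral-estimation parameters
#'
#' Defaults follow a 1024-point (2^10) segment length with 50% overlap and a
#' Hamming taper; at 500 Hz that is a ~2-s segment inside each 20-s epoch.
#'
#' @param segment_length samples per Welch segment.
#' @param overlap_fraction in `[0, 1)`.
#' @param taper currently only "hamming".
#' @export
spectral_params <- function(segment_length = 1024, overlap_fraction = 0.5,
                            taper = "hamming") {
  stopifnot(segment_length >= 2,
            overlap_fraction >= 0, overlap_fraction < 1)
  taper <- match.arg(taper)
  structure(list(segment_length = as.integer(segment_length),
                 overlap_fraction = overlap_fraction, taper = taper),
            class = "phenomap_spectral_params")
}

#' Welch power spectral density
#'
#' One-sided PSD by Hamming-tapered segment averaging. Used both for the
#' per-epoch band powers and for the scoring features.
#'
#' @param x numeric signal (one epoch, typically).
#' @param rate sampling rate, Hz.
#' @param params a [spectral_params()].
#' @return tibble with `freq` (Hz, bin centers) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, rate, params = spectral_params()) {
  L <- params$segment_length
  if (length(x) < L) {
    stop("signal shorter than one Welch segment (", L, " samples)",
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(L * (1 - params$overlap_fraction))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- as.numeric(signal::hamming(L))
  norm <- rate * sum(w^2)
  n_half <- L %/% 2 + 1L
  acc <- numeric(n_half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    p <- Mod(fft(seg))^2 / norm
    acc <- acc + p[seq_len(n_half)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (even-L) Nyquist
  mult <- rep(2, n_half)
  mult[1] <- 1
  if (L %% 2 == 0) mult[n_half] <- 1
  tibble(freq = (seq_len(n_half) - 1) * rate / L, psd = psd * mult)
}

# integrate a PSD over [f_lo, f_hi) by summing bins whose center lies inside
band_integral <- function(psd, f_lo, f_hi) {
  sum(psd$psd[psd$freq >= f_lo & psd$freq < f_hi])
}

#' Relative band powers of one epoch
#'
#' Each band's integrated power expressed as a percentage of the power in
#' the full 0.3-80 Hz range. An all-zero epoch has no defined ratio and
#' returns NaN with a warning.
#'
#' @param x one epoch of samples.
#' @param rate Hz.
#' @param scheme a [band_scheme()].
#' @param params a [spectral_params()].
#' @return Named numeric vector of percentages, one per band.
#' @export
epoch_band_powers <- function(x, rate, scheme = band_scheme(),
                              params = spectral_params()) {
  psd <- welch_psd(x, rate, params)
  tr <- attr(scheme, "total_range")
  total <- band_integral(psd, tr[1], tr[2])
  out <- setNames(
    vapply(seq_len(nrow(scheme)),
           function(i) band_integral(psd, scheme$f_lo[i], scheme$f_hi[i]),
           0.0),
    scheme$band
  )
  if (total <= 0) {
    warning("zero total power in epoch; band percentages undefined",
            call. = FALSE)
    return(out * NaN)
  }
  100 * out / total
}

#' Per-epoch scoring features
#'
#' Extracts, for every whole epoch of a recording, the EEG power in the
#' scoring delta and theta bands and the total EMG power. Note the scoring
#' theta band (default 6-9 Hz) is distinct from the 4-8 Hz periodogram
#' theta band.
#'
#' @param rec a [recording()].
#' @param delta_band,theta_band length-2 Hz ranges for the scoring features.
#' @param emg_band Hz range over which EMG power is integrated.
#' @param params a [spectral_params()].
#' @return tibble with `epoch`, `delta_power`, `theta_power`, `emg_power`,
#'   `activity` (summed counts per epoch).
#' @export
scoring_features <- function(rec, delta_band = c(0.5, 4),
                             theta_band = c(6, 9), emg_band = c(0.3, 80),
                             params = spectral_params()) {
  n <- n_epochs(rec)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    eeg_i <- rec$eeg[epoch_slice(i, rec$eeg_rate, rec$epoch_s)]
    emg_i <- rec$emg[epoch_slice(i, rec$emg_rate, rec$epoch_s)]
    p_eeg <- welch_psd(eeg_i, rec$eeg_rate, params)
    p_emg <- welch_psd(emg_i, rec$emg_rate, params)
    out[i, 1] <- band_integral(p_eeg, delta_band[1], delta_band[2])
    out[i, 2] <- band_integral(p_eeg, theta_band[1], theta_band[2])
    out[i, 3] <- band_integral(p_emg, emg_band[1], emg_band[2])
  }
  tibble(
    epoch = seq_len(n),
    delta_power = out[, 1], theta_power = out[, 2], emg_power = out[, 3],
    activity = epoch_activity(rec)
  )
}

# summed activity counts per epoch
epoch_activity <- function(rec) {
  n <- n_epochs(rec)
  per_epoch <- round(rec$activity_rate * rec$epoch_s)
  vapply(seq_len(n), function(i) {
    idx <- epoch_slice(i, rec$activity_rate, rec$epoch_s)
    sum(rec$activity[idx[idx <= length(rec$activity)]], na.rm = TRUE)
  }, 0.0)
}

#' Scoring ratios
#'
#' The three factors the stage classifier consumes: the delta ratio (epoch
#' delta power over the recording-level baseline delta power), the
#' theta-to-delta ratio (within-epoch), and the EMG ratio (epoch EMG power
#' over the baseline EMG power). Baselines are medians over non-artifact
#' epochs -- a robustness choice, since the source software never documents
#' its denominator.
#'
#' @param features output of [scoring_features()].
#' @param baselines optional list with `delta` and `emg`; computed as
#'   medians over `keep` epochs when NULL.
#' @param keep logical vector of epochs to include in the baselines
#'   (typically non-artifact).
#' @return `features` with `delta_ratio`, `theta_delta_ratio`, `emg_ratio`
#'   columns added.
#' @export
scoring_ratios <- function(features, baselines = NULL, keep = NULL) {
  if (is.null(keep)) keep <- rep(TRUE, nrow(features))
  if (is.null(baselines)) {
    baselines <- list(delta = median(features$delta_power[keep]),
                      emg = median(features$emg_power[keep]))
  }
  td <- features$theta_power / features$delta_power
  td[features$delta_power <= 0] <- NaN
  dplyr::mutate(
    features,
    delta_ratio = .data$delta_power / baselines$delta,
    theta_delta_ratio = td,
    emg_ratio = .data$emg_power / baselines$emg
  )
}

#' Band powers split by movement state
#'
#' Epochs whose summed activity count is at least 0.1 are labeled `moving`
#' (the active-wake threshold; the comparison is inclusive), the rest
#' `immobile`; returns the mean relative band power per state and band.
#' States with no epochs yield NaN with a warning.
#'
#' @param grid a scored `phenomap_grid` with band-power columns.
#' @param activity per-epoch summed activity; taken from the grid's
#'   `activity` column when NULL.
#' @param threshold activity count defining the moving state.
#' @return tibble with `state`, `band`, `mean_power`, `n_epochs`.
#' @export
movement_state_bands <- function(grid, activity = NULL, threshold = 0.1) {
  if (is.null(activity)) activity <- grid$activity
  stopifnot(length(activity) == nrow(grid))
  state <- ifelse(activity >= threshold, "moving", "immobile")
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(grid)[, BAND_NAMES], state = state),
    cols = dplyr::all_of(BAND_NAMES),
    names_to = "band", values_to = "power"
  )
  out <- tidyr::complete(
    dplyr::summarise(
      dplyr::group_by(long, .data$state, .data$band),
      mean_power = mean(.data$power, na.rm = TRUE),
      n_epochs = dplyr::n(), .groups = "drop"
    ),
    state = c("moving", "immobile"), band = BAND_NAMES,
    fill = list(mean_power = NaN, n_epochs = 0L)
  )
  if (any(out$n_epochs == 0)) {
    warning("no epochs in state(s): ",
            paste(unique(out$state[out$n_epochs == 0]), collapse = ", "),
            call. = FALSE)
  }
  out
}
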