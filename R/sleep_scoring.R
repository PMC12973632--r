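#' Sleep-scoring parameters
#'
#' The anchors are the published "maximum probability" points of the three
#' contributing factors: a delta ratio of 0.5 marks the REM/Wake maximum and
#' 1.0 the NREM maximum; a theta-to-delta ratio of 1.3 marks the Wake/NREM
#' maximum and 3.0 the REM maximum; an EMG ratio of 1.1 marks the REM/NREM
#' maximum and 2.4 the Wake maximum. Membership between anchors is a linear
#' (triangular) interpolation, constant 1 beyond a stage's outermost anchor
#' on its own side. An activity count of at least 0.1 per epoch forces wake.
#' Transition thresholds implement hysteresis: the decoder leaves the current
#' stage only when the candidate's membership score reaches the stated
#' probability (Wake->NREM 0.90, Wake->REM 0.90, NREM->Wake 0.80,
#' NREM->REM 0.90, REM->Wake 0.70, REM->NREM 0.80).
#'
#' Artifact gating: an epoch is an artifact when any EEG or EMG sample
#' exceeds 0.5 mV in magnitude (strict), and a recording with more than 1%
#' artifact epochs (strict) is excluded outright.
#'
#' @param delta_anchors named numeric, `wake_rem` and `nrem`.
#' @param theta_delta_anchors named numeric, `wake_nrem` and `rem`.
#' @param emg_anchors named numeric, `rem_nrem` and `wake`.
#' @param weights factor weights (delta, theta/delta, EMG); must sum to 1.
#' @param activity_wake_threshold summed counts per epoch forcing wake.
#' @param transitions 3x3 matrix of leave-thresholds, rows = from W/S/P.
#' @param artifact_amplitude_mv per-sample artifact threshold, mV.
#' @param artifact_exclusion_fraction recording-exclusion fraction.
#' @param delta_band,theta_band scoring feature bands, Hz (theta 6-9 here;
#'   the 4-8 Hz band belongs to the periodogram scheme).
#' @export
scoring_params <- function(
    delta_anchors = c(wake_rem = 0.5, nrem = 1.0),
    theta_delta_anchors = c(wake_nrem = 1.3, rem = 3.0),
    emg_anchors = c(rem_nrem = 1.1, wake = 2.4),
    weights = c(delta = 1, theta_delta = 1, emg = 1) / 3,
    activity_wake_threshold = 0.1,
    transitions = NULL,
    artifact_amplitude_mv = 0.5,
    artifact_exclusion_fraction = 0.01,
    delta_band = c(0.5, 4), theta_band = c(6, 9)) {
  if (is.null(transitions)) {
    transitions <- matrix(
      c(NA, 0.90, 0.90,
        0.80, NA, 0.90,
        0.70, 0.80, NA),
      nrow = 3, byrow = TRUE, dimnames = list(STAGES, STAGES)
    )
  }
  stopifnot(all(transitions[!is.na(transitions)] > 0),
            all(transitions[!is.na(transitions)] <= 1),
            abs(sum(weights) - 1) < 1e-9,
            all(c(delta_anchors, theta_delta_anchors, emg_anchors) > 0))
  structure(
    list(delta_anchors = delta_anchors,
         theta_delta_anchors = theta_delta_anchors,
         emg_anchors = emg_anchors, weights = weights,
         activity_wake_threshold = activity_wake_threshold,
         transitions = transitions,
         artifact_amplitude_mv = artifact_amplitude_mv,
         artifact_exclusion_fraction = artifact_exclusion_fraction,
         delta_band = delta_band, theta_band = theta_band),
    class = "phenomap_scoring_params"
  )
}

# triangular membership: 1 at `peak`, linear to 0 at `zero_at`, constant 1
# past `peak` away from `zero_at`
tri_membership <- function(x, peak, zero_at) {
  if (zero_at > peak) {            # decays upward
    m <- pmin(1, pmax(0, (zero_at - x) / (zero_at - peak)))
  } else {                         # decays downward
    m <- pmin(1, pmax(0, (x - zero_at) / (peak - zero_at)))
  }
  m[is.na(x)] <- NA_real_
  m
}

# per-stage membership for each factor value; columns W, S, P
factor_memberships <- function(ratios, params) {
  da <- params$delta_anchors
  ta <- params$theta_delta_anchors
  ea <- params$emg_anchors
  list(
    delta = cbind(
      W = tri_membership(ratios$delta_ratio, da[["wake_rem"]], da[["nrem"]]),
      S = tri_membership(ratios$delta_ratio, da[["nrem"]], da[["wake_rem"]]),
      P = tri_membership(ratios$delta_ratio, da[["wake_rem"]], da[["nrem"]])
    ),
    theta_delta = cbind(
      W = tri_membership(ratios$theta_delta_ratio, ta[["wake_nrem"]],
                         ta[["rem"]]),
      S = tri_membership(ratios$theta_delta_ratio, ta[["wake_nrem"]],
                         ta[["rem"]]),
      P = tri_membership(ratios$theta_delta_ratio, ta[["rem"]],
                         ta[["wake_nrem"]])
    ),
    emg = cbind(
      W = tri_membership(ratios$emg_ratio, ea[["wake"]], ea[["rem_nrem"]]),
      S = tri_membership(ratios$emg_ratio, ea[["rem_nrem"]], ea[["wake"]]),
      P = tri_membership(ratios$emg_ratio, ea[["rem_nrem"]], ea[["wake"]])
    )
  )
}

#' Per-epoch stage membership scores
#'
#' Combines the three factor memberships with equal weights into a stage
#' score in `[0, 1]` per stage, then normalizes across stages into
#' probabilities. Factors with undefined (NaN) ratios are dropped from an
#' epoch's weighted mean; epochs where every factor is undefined are marked
#' unscorable. Epochs whose summed activity reaches the wake threshold have
#' their wake score forced to the maximum attainable value (1) before
#' normalization, so EEG/EMG evidence cannot override observed movement.
#'
#' @param ratios output of [scoring_ratios()] (needs `delta_ratio`,
#'   `theta_delta_ratio`, `emg_ratio`, `activity`).
#' @param params a [scoring_params()].
#' @return tibble with raw scores `score_w/s/p`, normalized `p_w/s/p`, and
#'   `scorable`.
#' @export
stage_memberships <- function(ratios, params = scoring_params()) {
  mem <- factor_memberships(ratios, params)
  w <- params$weights
  n <- nrow(ratios)
  score <- matrix(0, n, 3, dimnames = list(NULL, STAGES))
  wsum <- matrix(0, n, 3)
  for (f in names(mem)) {
    m <- mem[[f]]
    ok <- is.finite(m[, 1])
    score[ok, ] <- score[ok, , drop = FALSE] +
      w[[f]] * m[ok, , drop = FALSE]
    wsum[ok, ] <- wsum[ok, ] + w[[f]]
  }
  scorable <- wsum[, 1] > 0
  score[scorable, ] <- score[scorable, , drop = FALSE] /
    wsum[scorable, , drop = FALSE]
  score[!scorable, ] <- NA_real_

  force_w <- !is.na(ratios$activity) &
    ratios$activity >= params$activity_wake_threshold
  score[force_w & scorable, "W"] <- 1

  tot <- rowSums(score)
  p <- score / ifelse(tot > 0, tot, NA_real_)
  tibble(
    epoch = ratios$epoch,
    score_w = unname(score[, "W"]), score_s = unname(score[, "S"]),
    score_p = unname(score[, "P"]),
    p_w = unname(p[, "W"]), p_s = unname(p[, "S"]), p_p = unname(p[, "P"]),
    scorable = scorable & tot > 0
  )
}

#' Flag artifact epochs
#'
#' An epoch is an artifact when any EEG or EMG sample magnitude exceeds the
#' per-recording amplitude threshold (strictly). The recording is marked
#' excluded when the artifact-epoch fraction strictly exceeds the exclusion
#' fraction (1% by default).
#'
#' @param rec a [recording()].
#' @param params a [scoring_params()].
#' @return list with `artifact_flag` (logical per epoch), `fraction`,
#'   `excluded`.
#' @export
flag_artifacts <- function(rec, params = scoring_params()) {
  n <- n_epochs(rec)
  thr <- params$artifact_amplitude_mv
  flag <- vapply(seq_len(n), function(i) {
    idx <- epoch_slice(i, rec$eeg_rate, rec$epoch_s)
    any(abs(rec$eeg[idx]) > thr) || any(abs(rec$emg[idx]) > thr)
  }, TRUE)
  frac <- mean(flag)
  list(artifact_flag = flag, fraction = frac,
       excluded = frac > params$artifact_exclusion_fraction)
}

# deterministic argmax over W/S/P with a fixed canonical tie-break
# (W, then S, then P); independent of internal column order
stage_argmax <- function(scores) {
  STAGES[which.max(scores[STAGES])]
}

#' Hysteresis decoding of the hypnogram
#'
#' Forward-greedy decoding with switch resistance: the state starts at the
#' first scorable epoch's argmax; at each later epoch the decoder switches
#' from the current stage A to the argmax candidate B only when B's
#' membership score reaches the A->B transition threshold, otherwise it
#' stays in A. Artifact epochs keep the label `ARTIFACT` and do not update
#' the state; unscorable epochs are labeled `UNSCORED` likewise.
#'
#' The thresholds are compared against the candidate's membership score
#' (bounded by 1), not the sum-normalized posterior: with triangular
#' memberships sharing anchors across stages, a perfectly stage-typical
#' epoch's normalized posterior is structurally capped near 0.6, below every
#' stated threshold, so posterior-scale thresholds could never fire.
#'
#' @param memberships output of [stage_memberships()].
#' @param params a [scoring_params()].
#' @param artifact_flag optional logical per epoch.
#' @return character vector of stage tokens.
#' @export
decode_hypnogram <- function(memberships, params = scoring_params(),
                             artifact_flag = NULL) {
  n <- nrow(memberships)
  if (n == 0) return(character(0))
  if (is.null(artifact_flag)) artifact_flag <- rep(FALSE, n)
  sc <- cbind(W = memberships$score_w, S = memberships$score_s,
              P = memberships$score_p)
  out <- character(n)
  state <- NA_character_
  tr <- params$transitions
  for (i in seq_len(n)) {
    if (artifact_flag[i]) { out[i] <- "ARTIFACT"; next }
    if (!isTRUE(memberships$scorable[i])) { out[i] <- "UNSCORED"; next }
    cand <- stage_argmax(sc[i, ])
    if (is.na(state)) {
      state <- cand
    } else if (cand != state && sc[i, cand] >= tr[state, cand]) {
      state <- cand
    }
    out[i] <- state
  }
  out
}

#' Score a recording into an epoch grid
#'
#' Full composition: artifact flagging, scoring features and ratios with
#' median baselines over non-artifact epochs, stage memberships, hysteresis
#' decoding, periodogram band powers, RMS-EMG and its recording-wide
#' z-score. A recording whose artifact fraction exceeds the exclusion
#' threshold yields an exclusion report and no hypnogram.
#'
#' @param rec a [recording()].
#' @param params a [scoring_params()].
#' @param scheme a [band_scheme()] for the per-epoch relative powers.
#' @param spectral a [spectral_params()].
#' @return Object of class `phenomap_scoring`: list with `grid` (a
#'   `phenomap_grid`, NULL when excluded), `excluded`, `artifact_fraction`,
#'   `memberships`.
#' @export
score_recording <- function(rec, params = scoring_params(),
                            scheme = band_scheme(),
                            spectral = spectral_params()) {
  art <- flag_artifacts(rec, params)
  if (art$excluded) {
    return(structure(
      list(grid = NULL, excluded = TRUE,
           artifact_fraction = art$fraction, memberships = NULL,
           animal_id = rec$animal_id),
      class = "phenomap_scoring"
    ))
  }
  feats <- scoring_features(rec, delta_band = params$delta_band,
                            theta_band = params$theta_band,
                            params = spectral)
  ratios <- scoring_ratios(feats, keep = !art$artifact_flag)
  mem <- stage_memberships(ratios, params)
  stage <- decode_hypnogram(mem, params, artifact_flag = art$artifact_flag)

  n <- n_epochs(rec)
  bp <- matrix(NA_real_, n, length(BAND_NAMES),
               dimnames = list(NULL, BAND_NAMES))
  for (i in seq_len(n)) {
    eeg_i <- rec$eeg[epoch_slice(i, rec$eeg_rate, rec$epoch_s)]
    bp[i, ] <- suppressWarnings(
      epoch_band_powers(eeg_i, rec$eeg_rate, scheme, spectral)
    )
  }
  grid <- epoch_grid(dplyr::bind_cols(
    tibble(
      epoch = seq_len(n),
      timestamp = rec$start_time + (seq_len(n) - 1) * rec$epoch_s,
      stage = stage,
      artifact_flag = art$artifact_flag
    ),
    as_tibble(bp),
    ratios[, c("delta_ratio", "theta_delta_ratio", "emg_ratio", "activity")]
  ), epoch_s = rec$epoch_s)
  grid <- zscore_rms(rms_emg_grid(rec, grid))

  structure(
    list(grid = grid, excluded = FALSE, artifact_fraction = art$fraction,
         memberships = mem, animal_id = rec$animal_id),
    class = "phenomap_scoring"
  )
}

#' @export
print.phenomap_scoring <- function(x, ...) {
  cat("<phenomap_scoring> ", x$animal_id, "\n", sep = "")
  if (x$excluded) {
    cat("  EXCLUDED: artifact fraction ",
        sprintf("%.1f%%", 100 * x$artifact_fraction),
        " exceeds the exclusion threshold; no hypnogram emitted\n", sep = "")
  } else {
    tab <- table(factor(x$grid$stage, levels = STAGE_TOKENS))
    cat("  ", nrow(x$grid), " epochs: ",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
    cat("  artifact fraction ",
        sprintf("%.2f%%", 100 * x$artifact_fraction), "\n", sep = "")
  }
  invisible(x)
}
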