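#' Simulation configuration
#'
#' Ground-truth generator settings for telemetry, photometry and section
#' images. Defaults encode the study conditions the analysis assumes:
#' 20-s epochs at 500 Hz EEG/EMG and 1 Hz activity; a semi-Markov stage
#' process whose stationary mix puts NREM just above half of all epochs
#' (so the recording-median delta and EMG baselines land on the NREM
#' cluster, the normalization under which the published anchors -- NREM
#' delta ratio 1, wake EMG ratio 2.4, REM theta/delta 3 -- are meaningful);
#' per-stage EEG delta/theta amplitudes and EMG tone placing the three
#' scoring ratios well inside their anchor regions; a fifth of REM epochs
#' carrying wake-level EMG (RBD-like); photometry at 1017 Hz with
#' stage-dependent transient rates and mean shifts on the sensor channels
#' but not the isosbestic; and section images with planted group effects
#' and exact-area clusters.
#'
#' @param ... overrides for any default listed below.
#' @return list of class `phenomap_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    epoch_s = 20, eeg_rate = 500, activity_rate = 1,
    # semi-Markov stage process (dwell means in epochs)
    dwell_epochs = c(W = 15, S = 20, P = 5),
    transitions = matrix(
      c(0, 1, 0,
        0.5, 0, 0.5,
        0.9, 0.1, 0),
      nrow = 3, byrow = TRUE, dimnames = list(STAGES, STAGES)
    ),
    # per-stage EEG component amplitudes, mV
    delta_amp = c(W = 0.020, S = 0.100, P = 0.015),
    theta_amp = c(W = 0.018, S = 0.020, P = 0.035),
    delta_hz = 2.2, theta_hz = 7.3, eeg_noise_sd = 0.008,
    # per-stage EMG tone (sinusoidal carrier amplitude, mV); wake tone is
    # drawn per epoch from a range (movement variability); RBD-like REM
    # epochs carry phasic wake-level bursts from the top of that range
    emg_hz = 62, emg_amp = list(W = c(0.08, 0.30), S = 0.05, P = 0.015,
                                RBD = c(0.30, 0.38)),
    emg_noise_sd = 0.004,
    activity_mean_wake = 2,      # Poisson counts per second during wake
    rbd_fraction = 0.2,
    # photometry
    phot_rate = 1017, phot_base = 100, phot_noise_sd = 0.3,
    drift_amp = 2, drift_period_s = 600,
    transient_amp = 5, transient_tau_s = 0.4,
    da_shift = c(W = 0.5, S = 0, P = 0.3, RBD = 1.5),
    da_rate = c(W = 1, S = 0.3, P = 0.5, RBD = 2),
    ach_shift = c(W = 0.5, S = 0, P = 1.0, RBD = -1.0),
    ach_rate = c(W = 1.5, S = 0.3, P = 1.2, RBD = 0.3),
    # section images
    section_dim = c(40, 40), bg_gray = 180, bg_sd = 6,
    effect_rows = 11:25, effect_cols = 11:25, effect_d = 3,
    microns_per_px = 2.5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "phenomap_sim_config")
}

#' Simulate a hypnogram
#'
#' Semi-Markov draw: dwell times are geometric around the per-stage mean
#' (in epochs), transitions follow the row-normalized matrix. Reproducible
#' per seed.
#'
#' @param cfg a [sim_config()].
#' @param duration_s total duration, seconds (at least one epoch).
#' @param seed RNG seed.
#' @return character vector of stages, one per epoch.
#' @export
simulate_hypnogram <- function(cfg = sim_config(), duration_s, seed = 1) {
  n <- floor(duration_s / cfg$epoch_s)
  if (n < 1) stop("duration shorter than one epoch", call. = FALSE)
  tr <- cfg$transitions
  states <- rownames(tr)
  if (length(states) == 1) return(rep(states, n))
  rs <- rowSums(tr)
  if (any(rs <= 0)) {
    stop("degenerate transition matrix: absorbing state with no exit",
         call. = FALSE)
  }
  tr <- tr / rs
  set.seed(seed)
  out <- character(0)
  s <- sample(states, 1, prob = cfg$dwell_epochs[states])
  while (length(out) < n) {
    dwell <- rgeom(1, 1 / cfg$dwell_epochs[[s]]) + 1L
    out <- c(out, rep(s, dwell))
    s <- sample(states, 1, prob = tr[s, ])
  }
  out[seq_len(n)]
}

# stationary epoch fractions of the semi-Markov process: embedded-chain
# stationary distribution weighted by mean dwell
hypnogram_stationary <- function(cfg = sim_config()) {
  tr <- cfg$transitions
  tr <- tr / rowSums(tr)
  e <- eigen(t(tr))
  i <- which.min(abs(e$values - 1))
  nu <- Re(e$vectors[, i])
  nu <- nu / sum(nu)
  occ <- nu * cfg$dwell_epochs[rownames(tr)]
  occ / sum(occ)
}

# choose which REM epochs lose atonia: a fixed fraction of REM epochs,
# placed within established REM bouts (not the bout-initial epoch) when
# enough candidates exist -- REM onset is defined by atonia, and the
# modeled events are phasic EMG within REM
pick_rbd_epochs <- function(hyp, fraction) {
  rem <- which(hyp == "P")
  if (!length(rem) || fraction <= 0) return(integer(0))
  n_rbd <- round(fraction * length(rem))
  if (n_rbd == 0) return(integer(0))
  initial <- rem[c(TRUE, diff(rem) > 1)]
  non_initial <- setdiff(rem, initial)
  picked <- non_initial[sample.int(length(non_initial),
                                   min(n_rbd, length(non_initial)))]
  if (length(picked) < n_rbd) {
    picked <- c(picked,
                initial[sample.int(length(initial), n_rbd - length(picked))])
  }
  sort(picked)
}

#' Synthesize a telemetry recording from a hypnogram
#'
#' EEG is a per-stage mixture of a delta and a theta sinusoid (random
#' phases per epoch) over a pink-ish (AR(1)) noise floor: NREM is
#' delta-dominant, REM theta-dominant, wake mixed and low-amplitude. EMG is
#' a sinusoidal carrier whose amplitude follows stage-dependent muscle
#' tone, with atonia in REM except the configured fraction of RBD-like
#' epochs at wake-level amplitude; wake tone varies per epoch. Activity is
#' Poisson during wake and zero otherwise.
#'
#' @param hyp stage vector from [simulate_hypnogram()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param animal_id identifier.
#' @param start_time recording start (POSIXct).
#' @return list with `recording` and `truth` (tibble: epoch, stage,
#'   is_rbd).
#' @export
synth_recording <- function(hyp, cfg = sim_config(), seed = 1,
                            animal_id = "sim", start_time = NULL) {
  set.seed(seed + 1L)
  n <- length(hyp)
  spe <- cfg$eeg_rate * cfg$epoch_s
  tt <- seq_len(spe) / cfg$eeg_rate
  is_rbd_epoch <- rep(FALSE, n)
  is_rbd_epoch[pick_rbd_epochs(hyp, cfg$rbd_fraction)] <- TRUE

  eeg <- numeric(n * spe)
  emg <- numeric(n * spe)
  for (i in seq_len(n)) {
    s <- hyp[i]
    idx <- ((i - 1) * spe + 1):(i * spe)
    ph <- runif(2, 0, 2 * pi)
    eeg[idx] <- cfg$delta_amp[[s]] * sin(2 * pi * cfg$delta_hz * tt + ph[1]) +
      cfg$theta_amp[[s]] * sin(2 * pi * cfg$theta_hz * tt + ph[2])
    amp <- if (is_rbd_epoch[i]) {
      runif(1, cfg$emg_amp$RBD[1], cfg$emg_amp$RBD[2])
    } else if (s == "W") {
      runif(1, cfg$emg_amp$W[1], cfg$emg_amp$W[2])
    } else {
      cfg$emg_amp[[s]]
    }
    emg[idx] <- amp * sin(2 * pi * cfg$emg_hz * tt + runif(1, 0, 2 * pi))
  }
  # AR(1) noise floor, low-frequency weighted
  ar <- 0.9
  eeg <- eeg + as.numeric(
    filter(rnorm(n * spe, sd = cfg$eeg_noise_sd * sqrt(1 - ar^2)),
           ar, method = "recursive"))
  emg <- emg + rnorm(n * spe, sd = cfg$emg_noise_sd)

  act_pe <- cfg$activity_rate * cfg$epoch_s
  activity <- numeric(n * act_pe)
  for (i in which(hyp == "W")) {
    activity[((i - 1) * act_pe + 1):(i * act_pe)] <-
      rpois(act_pe, cfg$activity_mean_wake)
  }
  rec <- recording(eeg, emg, activity, eeg_rate = cfg$eeg_rate,
                   emg_rate = cfg$eeg_rate,
                   activity_rate = cfg$activity_rate,
                   animal_id = animal_id, start_time = start_time,
                   epoch_s = cfg$epoch_s)
  list(recording = rec,
       truth = tibble(epoch = seq_len(n), stage = hyp,
                      is_rbd = is_rbd_epoch))
}

#' Synthesize a photometry trace for a class-labeled hypnogram
#'
#' Each channel is a shared baseline plus a shared slow drift (also on the
#' isosbestic), white noise, and -- on the sensor channels only --
#' stage-class-dependent mean shifts and exponential transients whose rate
#' depends on the stage class. Classes are `W`, `S`, `P` and `RBD`.
#'
#' @param classes per-epoch class labels (use `truth` from
#'   [synth_recording()]: stage with RBD epochs relabeled `RBD`).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param max_duration_s cap on trace length (a 30-min session by default).
#' @return list with `trace` (a [photometry_trace()]) and `truth` (the
#'   injected per-class shifts and rates).
#' @export
synth_photometry <- function(classes, cfg = sim_config(), seed = 1,
                             max_duration_s = 1800) {
  set.seed(seed + 2L)
  n_ep <- min(length(classes), floor(max_duration_s / cfg$epoch_s))
  classes <- classes[seq_len(n_ep)]
  rate <- cfg$phot_rate
  spe <- round(rate * cfg$epoch_s)
  n <- n_ep * spe
  cls_sample <- rep(classes, each = spe)

  drift <- cfg$drift_amp *
    sin(2 * pi * seq_len(n) / (rate * cfg$drift_period_s))

  channel <- function(shift, trate) {
    x <- cfg$phot_base + drift + rnorm(n, sd = cfg$phot_noise_sd)
    if (!is.null(shift)) {
      x <- x + shift[cls_sample]
      lambda <- trate[cls_sample] / rate
      events <- rbinom(n, 1, pmin(1, lambda)) * cfg$transient_amp
      kern <- exp(-1 / (cfg$transient_tau_s * rate))
      x <- x + as.numeric(filter(events, kern, method = "recursive"))
    }
    x
  }
  trace <- photometry_trace(
    iso = channel(NULL, NULL),
    ach = channel(cfg$ach_shift, cfg$ach_rate),
    da = channel(cfg$da_shift, cfg$da_rate),
    rate = rate, ttl = 1L
  )
  truth <- tibble(
    class = names(cfg$da_shift),
    da_shift = unname(cfg$da_shift), da_rate = unname(cfg$da_rate),
    ach_shift = unname(cfg$ach_shift), ach_rate = unname(cfg$ach_rate)
  )
  list(trace = trace, truth = truth, classes = classes)
}

# deterministic exact-area blob: grow from a center in increasing
# (distance, angle) order until the requested pixel count is reached
blob_pixels <- function(center, area_px, dim) {
  r_max <- ceiling(sqrt(area_px / pi)) + 3
  rows <- (center[1] - r_max):(center[1] + r_max)
  cols <- (center[2] - r_max):(center[2] + r_max)
  gr <- expand.grid(row = rows, col = cols)
  gr <- gr[gr$row >= 1 & gr$row <= dim[1] & gr$col >= 1 & gr$col <= dim[2], ]
  d2 <- (gr$row - center[1])^2 + (gr$col - center[2])^2
  ang <- atan2(gr$row - center[1], gr$col - center[2])
  gr <- gr[order(d2, ang), ]
  if (nrow(gr) < area_px) stop("blob does not fit in the image",
                               call. = FALSE)
  gr[seq_len(area_px), ]
}

#' Plant exact-area clusters in a section image
#'
#' Dark blobs of exactly the requested pixel areas on a light background,
#' with a minimum pairwise gap between blob bounding circles (resampled
#' with bounded retries, then an error).
#'
#' @param areas_px integer vector of exact blob areas.
#' @param dim image dims (rows, cols).
#' @param seed RNG seed.
#' @param gap_px minimum separation between blob edges.
#' @param bg_gray,blob_gray background and blob intensities.
#' @param max_tries placement retries before giving up.
#' @return list: `img` (a [section_image()]) and `truth` (tibble of
#'   centers and areas).
#' @export
synth_blob_image <- function(areas_px, dim = c(200, 200), seed = 1,
                             gap_px = 3, bg_gray = 200, blob_gray = 20,
                             max_tries = 200) {
  set.seed(seed + 3L)
  img <- matrix(bg_gray, dim[1], dim[2])
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  truth <- list()
  for (a in areas_px) {
    r <- sqrt(a / pi) + 1
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      c_new <- c(sample(seq(ceiling(r + 1), floor(dim[1] - r - 1)), 1),
                 sample(seq(ceiling(r + 1), floor(dim[2] - r - 1)), 1))
      if (nrow(centers)) {
        d <- sqrt(rowSums((centers - matrix(c_new, nrow(centers), 2,
                                            byrow = TRUE))^2))
        if (any(d < radii + r + gap_px)) next
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place blob of ", a,
                      " px with the required separation", call. = FALSE)
    px <- blob_pixels(c_new, a, dim)
    img[cbind(px$row, px$col)] <- blob_gray
    centers <- rbind(centers, c_new)
    radii <- c(radii, r)
    truth[[length(truth) + 1L]] <-
      tibble(row = c_new[1], col = c_new[2], area_px = a)
  }
  list(img = section_image(img), truth = dplyr::bind_rows(truth))
}

#' Synthesize a section-image study
#'
#' One image per animal: Gaussian background texture around a light gray
#' level, with a planted intensity effect (darker, i.e. more stain signal)
#' inside a known pixel block for every group at or past `effect_from` in
#' the timepoint order. The effect magnitude is `effect_d` background SDs.
#'
#' @param cfg a [sim_config()].
#' @param n_per_group animals per group.
#' @param groups group labels; the first is the control.
#' @param effect_from index into `groups` from which the effect is present
#'   (NULL for a null study).
#' @param seed RNG seed.
#' @return list: `images` (named list of [section_image()]), `design`
#'   (tibble with animal_id, group, sex), `control`, `truth` (effect mask
#'   at ROI resolution and affected groups).
#' @export
synth_sections <- function(cfg = sim_config(), n_per_group = 8,
                           groups = c("monomeric", "pff_2w", "pff_1m",
                                      "pff_3m", "pff_6m", "pff_7m"),
                           effect_from = 4, seed = 1) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  set.seed(seed + 4L)
  dm <- cfg$section_dim
  affected <- if (is.null(effect_from)) character(0) else {
    groups[seq_along(groups) >= effect_from]
  }
  images <- list()
  design <- list()
  for (gi in seq_along(groups)) {
    for (ai in seq_len(n_per_group)) {
      id <- paste0(groups[gi], "_", ai)
      img <- matrix(rnorm(prod(dm), cfg$bg_gray, cfg$bg_sd), dm[1], dm[2])
      if (groups[gi] %in% affected) {
        img[cfg$effect_rows, cfg$effect_cols] <-
          img[cfg$effect_rows, cfg$effect_cols] - cfg$effect_d * cfg$bg_sd
      }
      images[[id]] <- section_image(pmin(pmax(img, 0), 255),
                                    microns_per_px = cfg$microns_per_px,
                                    animal_id = id)
      design[[id]] <- tibble(animal_id = id, group = groups[gi],
                             sex = if (ai %% 2 == 0) "F" else "M")
    }
  }
  mask <- matrix(FALSE, dm[1] %/% 5, dm[2] %/% 5)
  if (length(affected)) {
    roi_r <- unique((cfg$effect_rows - 1) %/% 5 + 1)
    roi_c <- unique((cfg$effect_cols - 1) %/% 5 + 1)
    # only ROI blocks fully inside the effect region count as ground truth
    full_r <- roi_r[vapply(roi_r, function(r) {
      all(((r - 1) * 5 + 1):(r * 5) %in% cfg$effect_rows)
    }, TRUE)]
    full_c <- roi_c[vapply(roi_c, function(cc) {
      all(((cc - 1) * 5 + 1):(cc * 5) %in% cfg$effect_cols)
    }, TRUE)]
    mask[full_r[full_r <= nrow(mask)], full_c[full_c <= ncol(mask)]] <- TRUE
  }
  list(images = images, design = dplyr::bind_rows(design),
       control = groups[1],
       truth = list(effect_mask = mask, affected_groups = affected))
}
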