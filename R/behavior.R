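# Deterministic behavioral indices. All are plain arithmetic on raw assay
# measurements; validation is the point.

#' Olfactory discrimination index
#'
#' Time in the chocolate-flavor corner over time in the TMT (predator-odor)
#' corner; 1 means no preference.
#'
#' @param time_choc_s,time_tmt_s seconds, non-negative.
#' @return ratio; `Inf` with a warning when the TMT time is zero.
#' @export
olfactory_discrimination <- function(time_choc_s, time_tmt_s) {
  stopifnot(time_choc_s >= 0, time_tmt_s >= 0)
  if (time_tmt_s == 0) {
    warning("zero time at the TMT corner: index is infinite", call. = FALSE)
    return(Inf)
  }
  time_choc_s / time_tmt_s
}

#' Sucrose preference index
#'
#' Default convention: sucrose consumed over total fluid consumed, in
#' `[0, 1]` (0.5 = indifference). The literal water-to-sucrose ratio is
#' available behind `literal = TRUE`.
#'
#' @param sucrose_g,water_g grams consumed, non-negative, not both zero.
#' @param literal return water/sucrose instead of the preference fraction.
#' @export
sucrose_preference <- function(sucrose_g, water_g, literal = FALSE) {
  stopifnot(sucrose_g >= 0, water_g >= 0)
  if (sucrose_g == 0 && water_g == 0) {
    stop("no fluid consumed: preference undefined", call. = FALSE)
  }
  if (literal) return(water_g / sucrose_g)
  sucrose_g / (sucrose_g + water_g)
}

#' Fecal output metrics
#'
#' @param n_pellets pellet count over the session.
#' @param wet_g,dry_g total wet and dry weight, grams; `dry_g <= wet_g`.
#' @return tibble: count, total wet, mean pellet weight, dry weight, water
#'   content (fraction of wet weight).
#' @export
fecal_metrics <- function(n_pellets, wet_g, dry_g) {
  if (dry_g > wet_g) stop("dry weight exceeds wet weight", call. = FALSE)
  if (n_pellets == 0 && wet_g > 0) {
    stop("positive weight with zero pellets", call. = FALSE)
  }
  tibble(
    n_pellets = n_pellets,
    wet_g = wet_g,
    mean_pellet_g = if (n_pellets > 0) wet_g / n_pellets else NA_real_,
    dry_g = dry_g,
    water_content = if (wet_g > 0) (wet_g - dry_g) / wet_g else NA_real_
  )
}

#' Hindlimb distance from grid-frame counts
#'
#' Mean over the sampled frames (nominally 5) converted to centimetres at
#' 1 cm per grid frame; fewer than 5 samples compute on what is available
#' with a warning.
#'
#' @param grid_frames numeric vector of frame counts.
#' @param grid_cm centimetres per frame.
#' @export
hindlimb_distance <- function(grid_frames, grid_cm = 1) {
  if (length(grid_frames) == 0) stop("no frame samples", call. = FALSE)
  if (length(grid_frames) < 5) {
    warning("fewer than 5 frame samples; computing on ",
            length(grid_frames), call. = FALSE)
  }
  mean(grid_frames) * grid_cm
}

#' Operant-session metrics
#'
#' Walks a time-sorted event log of nose pokes and pellet events. A
#' retrieval is matched to the most recent unretrieved delivery and counts
#' when its latency is at most 10 s. The ratio is correct pokes over total
#' pokes.
#'
#' @param log tibble with `time_s` and `event` in `poke_correct`,
#'   `poke_incorrect`, `pellet_delivery`, `pellet_retrieval`.
#' @param retrieval_window_s latency window, seconds.
#' @return one-row tibble: `n_correct`, `n_incorrect`, `ratio`,
#'   `pellets_retrieved_within_window`, `session_failure` (no correct poke).
#' @export
operant_metrics <- function(log, retrieval_window_s = 10) {
  stopifnot(all(c("time_s", "event") %in% names(log)))
  log <- log[order(log$time_s), ]
  n_c <- sum(log$event == "poke_correct")
  n_i <- sum(log$event == "poke_incorrect")
  pending <- numeric(0)
  within <- 0L
  for (i in seq_len(nrow(log))) {
    ev <- log$event[i]
    if (ev == "pellet_delivery") {
      pending <- c(pending, log$time_s[i])
    } else if (ev == "pellet_retrieval") {
      if (!length(pending)) {
        stop("retrieval before any delivery at t = ", log$time_s[i],
             call. = FALSE)
      }
      lat <- log$time_s[i] - pending[length(pending)]
      pending <- pending[-length(pending)]
      if (lat <= retrieval_window_s) within <- within + 1L
    }
  }
  tibble(
    n_correct = n_c, n_incorrect = n_i,
    ratio = if (n_c + n_i > 0) n_c / (n_c + n_i) else NA_real_,
    pellets_retrieved_within_window = within,
    session_failure = n_c == 0
  )
}

#' Cross-session operant exclusion rule
#'
#' An animal is excluded when it fails to execute a single correct poke in
#' two consecutive sessions.
#'
#' @param n_correct_by_session integer vector, one entry per session in
#'   order.
#' @return logical.
#' @export
operant_exclusion <- function(n_correct_by_session) {
  z <- n_correct_by_session == 0
  any(z[-1] & z[-length(z)]) && length(z) >= 2
}

#' Validate a bedding-quality score
#'
#' Manual 0-5 rubric; integers only.
#' @param score integer.
#' @export
bedding_score <- function(score) {
  if (length(score) != 1 || is.na(score) || score != as.integer(score) ||
      score < 0 || score > 5) {
    stop("bedding score must be an integer from 0 to 5", call. = FALSE)
  }
  as.integer(score)
}
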