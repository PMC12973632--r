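#' Three-channel fiber-photometry trace
#'
#' Isosbestic control, green acetylcholine sensor and red dopamine sensor
#' sampled at a common rate (nominally 1017 Hz), with a TTL sync sample
#' index mapping photometry time onto the sleep-scoring clock.
#'
#' @param iso,ach,da numeric channels, arbitrary fluorescence units.
#' @param rate Hz.
#' @param ttl sample index (1-based) corresponding to epoch-grid time zero.
#' @export
photometry_trace <- function(iso, ach, da, rate = 1017, ttl = 1L) {
  stopifnot(is.numeric(iso), is.numeric(ach), is.numeric(da))
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (length(iso) != length(ach) || length(iso) != length(da)) {
    stop("all three channels must have the same length", call. = FALSE)
  }
  structure(list(iso = iso, ach = ach, da = da, rate = rate,
                 ttl = as.integer(ttl)),
            class = "phenomap_photometry")
}

#' @export
print.phenomap_photometry <- function(x, ...) {
  cat("<phenomap_photometry> ", length(x$iso), " samples @ ", x$rate,
      " Hz (", round(length(x$iso) / x$rate / 60, 1), " min), ttl at ",
      x$ttl, "\n", sep = "")
  invisible(x)
}

#' Read a photometry trace from CSV
#'
#' Columns `iso`, `ach`, `da`; rate and TTL from `# key=value` header
#' comments (defaults 1017 Hz, ttl 1).
#' @param path CSV path.
#' @export
read_photometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_meta_comments(path)
  df <- read.csv(path, comment.char = "#")
  for (ch in c("iso", "ach", "da")) {
    if (!ch %in% names(df)) {
      stop("missing channel '", ch, "' in ", path, call. = FALSE)
    }
  }
  photometry_trace(df$iso, df$ach, df$da,
                   rate = as.numeric(meta[["rate"]] %||% 1017),
                   ttl = as.integer(meta[["ttl"]] %||% 1))
}

#' @rdname read_photometry
#' @param trace a [photometry_trace()].
#' @export
write_photometry <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rate=", trace$rate), paste0("# ttl=", trace$ttl)),
             con)
  write.csv(data.frame(iso = trace$iso, ach = trace$ach, da = trace$da),
            con, row.names = FALSE)
  invisible(path)
}

#' Downsample a channel by window averaging
#'
#' Non-overlapping window means mapped onto the target grid. For
#' non-integer rate ratios the windows are fractional (area-weighted via
#' cumulative sums), so the mean of the output equals the mean of the
#' consumed input exactly; a trailing partial window is dropped.
#'
#' @param x numeric channel.
#' @param source_rate,target_rate Hz; `target_rate` must not exceed
#'   `source_rate`.
#' @return numeric vector at the target rate.
#' @export
downsample_mean <- function(x, source_rate, target_rate = 500) {
  if (target_rate > source_rate) {
    stop("target rate exceeds source rate", call. = FALSE)
  }
  r <- source_rate / target_rate
  n_out <- floor(length(x) / r)
  if (n_out < 1) stop("signal shorter than one output sample", call. = FALSE)
  # piecewise-constant integral of the samples, linearly interpolated at
  # fractional window edges
  cs <- c(0, cumsum(x))
  edge <- (0:n_out) * r
  lo <- floor(edge)
  frac <- edge - lo
  vals <- cs[lo + 1] + frac * x[pmin(lo + 1, length(x))]
  diff(vals) / r
}

# O(n) centered moving mean with truncated windows at the edges
moving_mean <- function(x, halfwidth) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - halfwidth)
  hi <- pmin(n, seq_len(n) + halfwidth)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Moving-baseline normalization (F/F0)
#'
#' Normalizes each sample F by the average F0 over a moving window (5 s by
#' default) centered on the same point; edge windows are truncated. The
#' literal ratio F/F0 is the default; `mode = "delta"` returns
#' (F - F0)/F0. Samples where F0 is zero become NaN with a warning.
#'
#' @param x numeric channel.
#' @param rate Hz.
#' @param window_s baseline window length, seconds.
#' @param mode "ratio" (F/F0) or "delta" ((F-F0)/F0).
#' @export
dff_moving <- function(x, rate, window_s = 5, mode = c("ratio", "delta")) {
  mode <- match.arg(mode)
  if (window_s * rate >= length(x)) {
    stop("baseline window must be shorter than the trace", call. = FALSE)
  }
  hw <- floor(window_s * rate / 2)
  f0 <- moving_mean(x, hw)
  bad <- f0 == 0
  if (any(bad)) {
    warning("zero baseline (F0) at ", sum(bad), " sample(s); NaN emitted",
            call. = FALSE)
    f0[bad] <- NA_real_
  }
  out <- if (mode == "ratio") x / f0 else (x - f0) / f0
  out[bad] <- NaN
  out
}

#' Per-minute z-score
#'
#' z-scores each non-overlapping 1-minute window independently (windows
#' anchored to the start of the trace; a trailing partial window is
#' z-scored on its own samples). Zero-variance windows become zeros with a
#' warning.
#'
#' @param x numeric channel.
#' @param rate Hz.
#' @export
minute_zscore <- function(x, rate) {
  n_win <- round(60 * rate)
  if (length(x) < n_win) stop("trace shorter than one minute", call. = FALSE)
  out <- numeric(length(x))
  starts <- seq(1L, length(x), by = n_win)
  warned <- FALSE
  for (s in starts) {
    idx <- s:min(s + n_win - 1L, length(x))
    xs <- x[idx]
    mu <- mean(xs, na.rm = TRUE)
    sdev <- sd(xs, na.rm = TRUE)
    if (!is.finite(sdev) || sdev == 0) {
      out[idx] <- 0
      warned <- TRUE
    } else {
      out[idx] <- (xs - mu) / sdev
    }
  }
  if (warned) {
    warning("zero-variance minute window(s); zeros emitted", call. = FALSE)
  }
  out
}

#' Average a channel over the 20-s scoring epochs
#'
#' The TTL sample marks epoch-grid time zero. One mean per epoch fully
#' covered by the trace; partial edge epochs are dropped. Epoch indices in
#' the output refer to the grid.
#'
#' @param x numeric channel (already processed).
#' @param rate Hz.
#' @param ttl sample index of grid time zero.
#' @param n_grid_epochs number of epochs in the grid.
#' @param epoch_s epoch length, seconds.
#' @return tibble with `epoch` and `mean`.
#' @export
epoch_align <- function(x, rate, ttl = 1L, n_grid_epochs = Inf,
                        epoch_s = 20) {
  spe <- round(rate * epoch_s)
  first <- if (ttl >= 1) 0L else ceiling((1 - ttl) / spe)
  means <- list()
  epochs <- integer(0)
  e <- first
  repeat {
    a <- ttl + e * spe
    b <- a + spe - 1L
    if (b > length(x) || e + 1 > n_grid_epochs) break
    if (a >= 1) {
      epochs <- c(epochs, e + 1L)
      means[[length(means) + 1L]] <- mean(x[a:b])
    }
    e <- e + 1L
  }
  if (!length(epochs)) {
    stop("no whole epoch overlaps the trace", call. = FALSE)
  }
  tibble(epoch = epochs, mean = unlist(means))
}

#' Run the full photometry normalization chain
#'
#' Fixed, literature-stated order: downsample to 500 Hz by window
#' averaging, F/F0 against a 5-s centered moving baseline, per-minute
#' z-score, then averaging over the 20-s scoring epochs. No isosbestic
#' regression or subtraction is applied anywhere: the isosbestic channel is
#' processed identically and used as a statistical comparator only.
#'
#' @param trace a [photometry_trace()].
#' @param grid a scored `phenomap_grid` (for stage labels and epoch count).
#' @param target_rate Hz after downsampling.
#' @param window_s F0 window, seconds.
#' @param dff_mode see [dff_moving()].
#' @param z_threshold RBD class cut applied to the grid.
#' @return tibble with `epoch`, `stage_class`, and per-epoch means `iso`,
#'   `ach`, `da`.
#' @export
photometry_epoch_means <- function(trace, grid, target_rate = 500,
                                   window_s = 5,
                                   dff_mode = c("ratio", "delta"),
                                   z_threshold = 2) {
  dff_mode <- match.arg(dff_mode)
  ttl_ds <- as.integer(floor((trace$ttl - 1) *
                               target_rate / trace$rate)) + 1L
  chain <- function(x) {
    x <- downsample_mean(x, trace$rate, target_rate)
    x <- dff_moving(x, target_rate, window_s, mode = dff_mode)
    x <- minute_zscore(x, target_rate)
    epoch_align(x, target_rate, ttl = ttl_ds, n_grid_epochs = nrow(grid))
  }
  per <- lapply(list(iso = trace$iso, ach = trace$ach, da = trace$da), chain)
  out <- per$iso
  names(out)[2] <- "iso"
  out$ach <- per$ach$mean
  out$da <- per$da$mean
  cls <- stage_classes(grid, z_threshold)
  out$stage_class <- cls[out$epoch]
  out[, c("epoch", "stage_class", "iso", "ach", "da")]
}

#' Stage-conditioned photometry summary
#'
#' Per stage class (wake, NREM, atonic REM, RBD-like): mean and SD of the
#' per-epoch channel means, the paired channel-minus-isosbestic contrast
#' per class, and the RBD-minus-atonic-REM contrast per channel. Classes
#' with no epochs yield NaN with an exclusion note; an animal without REM
#' epochs is excluded from the REM contrasts.
#'
#' @param epoch_means output of [photometry_epoch_means()].
#' @return list of class `phenomap_photometry_summary` with `class_means`,
#'   `iso_contrasts`, `rbd_contrasts`, `notes`.
#' @export
stage_conditioned_signal <- function(epoch_means) {
  all_classes <- c("W", "S", "P_atonic", "P_rbd")
  em <- epoch_means[!is.na(epoch_means$stage_class), ]
  long <- tidyr::pivot_longer(em, cols = c("iso", "ach", "da"),
                              names_to = "channel", values_to = "z")
  class_means <- tidyr::complete(
    dplyr::summarise(
      dplyr::group_by(long, .data$stage_class, .data$channel),
      mean = mean(.data$z), sd = sd(.data$z), n_epochs = dplyr::n(),
      .groups = "drop"
    ),
    stage_class = all_classes, channel = c("iso", "ach", "da"),
    fill = list(mean = NaN, sd = NaN, n_epochs = 0L)
  )
  wide <- tidyr::pivot_wider(class_means[, c("stage_class", "channel", "mean")],
                             names_from = "channel", values_from = "mean")
  iso_contrasts <- tibble(
    stage_class = rep(wide$stage_class, 2),
    channel = rep(c("ach", "da"), each = nrow(wide)),
    contrast_vs_iso = c(wide$ach - wide$iso, wide$da - wide$iso)
  )
  rbd_row <- wide[wide$stage_class == "P_rbd", ]
  rem_row <- wide[wide$stage_class == "P_atonic", ]
  rbd_contrasts <- tibble(
    channel = c("iso", "ach", "da"),
    rbd_minus_rem = c(rbd_row$iso - rem_row$iso,
                      rbd_row$ach - rem_row$ach,
                      rbd_row$da - rem_row$da)
  )
  notes <- character(0)
  missing_cls <- setdiff(all_classes, unique(em$stage_class))
  if (length(missing_cls)) {
    notes <- paste0("no epochs in class(es): ",
                    paste(missing_cls, collapse = ", "))
  }
  if (!any(em$stage_class %in% c("P_atonic", "P_rbd"))) {
    notes <- c(notes, "no REM epochs: animal excluded from REM contrasts")
  }
  structure(list(class_means = class_means, iso_contrasts = iso_contrasts,
                 rbd_contrasts = rbd_contrasts, notes = notes),
            class = "phenomap_photometry_summary")
}

#' @export
print.phenomap_photometry_summary <- function(x, ...) {
  cat("<phenomap_photometry_summary>\n")
  print(x$class_means)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
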