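# Minimal EDF (European Data Format) support for raw telemetry signals:
# 256-byte fixed header, 256 bytes per signal, int16 little-endian records.
# Signals are quantized to the 16-bit digital range on write, so EDF
# round-trips are exact only to the quantization step; CSV is the lossless
# canonical format.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

# shortest numeric representation that fits an 8-char EDF header field
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(s)
  }
  substr(formatC(x, format = "g"), 1, 8)
}

#' Write a recording as EDF
#'
#' @param rec a [recording()].
#' @param path output path (.edf).
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "phenomap_recording"))
  n_rec <- floor(length(rec$eeg) / rec$eeg_rate)  # 1-s data records
  chans <- list(
    list(label = "EEG", dim = "mV", x = rec$eeg[seq_len(n_rec * rec$eeg_rate)],
         spr = rec$eeg_rate),
    list(label = "EMG", dim = "mV", x = rec$emg[seq_len(n_rec * rec$emg_rate)],
         spr = rec$emg_rate),
    list(label = "Activity", dim = "counts",
         x = rec$activity[seq_len(min(length(rec$activity),
                                      n_rec * rec$activity_rate))],
         spr = rec$activity_rate)
  )
  ns <- length(chans)
  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$animal_id, 80),
    edf_pad("phenomap telemetry", 80),
    edf_pad(format(rec$start_time, "%d.%m.%y", tz = "UTC"), 8),
    edf_pad(format(rec$start_time, "%H.%M.%S", tz = "UTC"), 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad(paste0("lights=", rec$lights_on, "-", rec$lights_off), 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)

  phys <- lapply(chans, function(ch) {
    rng <- range(ch$x, finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    # quantize against the values exactly as printed in the header, so
    # reader and writer share the same physical range
    as.numeric(vapply(rng, edf_num, ""))
  })
  field <- function(f) paste0(vapply(seq_len(ns), f, ""), collapse = "")
  sig_hdr <- paste0(
    field(function(i) edf_pad(chans[[i]]$label, 16)),
    field(function(i) edf_pad("", 80)),
    field(function(i) edf_pad(chans[[i]]$dim, 8)),
    field(function(i) edf_pad(edf_num(phys[[i]][1]), 8)),
    field(function(i) edf_pad(edf_num(phys[[i]][2]), 8)),
    field(function(i) edf_pad(-32768, 8)),
    field(function(i) edf_pad(32767, 8)),
    field(function(i) edf_pad("", 80)),
    field(function(i) edf_pad(chans[[i]]$spr, 8)),
    field(function(i) edf_pad("", 32))
  )
  writeChar(sig_hdr, con, eos = NULL)

  dig <- lapply(seq_len(ns), function(i) {
    p <- phys[[i]]
    d <- round((chans[[i]]$x - p[1]) / (p[2] - p[1]) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      spr <- chans[[i]]$spr
      idx <- ((r - 1) * spr + 1):(r * spr)
      seg <- dig[[i]][idx]
      seg[is.na(seg)] <- -32768L
      writeBin(seg, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                       # version
  animal_id <- rd(80)
  rd(80)                      # recording id
  d <- rd(8); tm <- rd(8)
  rd(8)                       # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  f <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- f(16); f(80); f(8)
  pmin_ <- as.numeric(f(8)); pmax_ <- as.numeric(f(8))
  dmin_ <- as.numeric(f(8)); dmax_ <- as.numeric(f(8))
  f(80)
  spr <- as.integer(f(8))
  f(32)

  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (raw - dmin_[i]) / (dmax_[i] - dmin_[i]) *
          (pmax_[i] - pmin_[i])
    }
  }
  names(sig) <- toupper(labels)

  for (ch in c("EEG", "EMG")) {
    if (!ch %in% names(sig)) {
      stop("missing channel '", ch, "' in ", path, call. = FALSE)
    }
  }
  if (!"ACTIVITY" %in% names(sig)) {
    stop("missing channel 'Activity' in ", path, call. = FALSE)
  }
  i_eeg <- match("EEG", names(sig)); i_emg <- match("EMG", names(sig))
  lights <- c("07:00", "19:00")
  m <- regmatches(reserved,
                  regexec("lights=(\\d\\d:\\d\\d)-(\\d\\d:\\d\\d)", reserved))[[1]]
  if (length(m) == 3) lights <- m[2:3]
  start <- as.POSIXct(paste(d, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  recording(
    eeg = sig[[i_eeg]], emg = sig[[i_emg]], activity = sig[["ACTIVITY"]],
    eeg_rate = spr[i_eeg] / rec_dur, emg_rate = spr[i_emg] / rec_dur,
    activity_rate = spr[match("ACTIVITY", names(sig))] / rec_dur,
    animal_id = animal_id, start_time = start,
    lights_on = lights[1], lights_off = lights[2]
  )
}
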