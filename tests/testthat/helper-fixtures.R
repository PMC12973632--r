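# shared fixtures and independent oracles, all built in code

make_grid <- function(stages, start = "2024-01-01 00:00:00",
                      z = rep(0, length(stages)),
                      bands = NULL, activity = 0) {
  n <- length(stages)
  df <- tibble::tibble(
    epoch = seq_len(n),
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 20,
    stage = stages,
    rms_emg = abs(z) + 1,
    z_rms_emg = z,
    artifact_flag = stages == "ARTIFACT",
    activity = rep_len(activity, n)
  )
  if (!is.null(bands)) {
    for (b in names(bands)) df[[b]] <- rep_len(bands[[b]], n)
  }
  epoch_grid(df)
}

# brute-force band fractions from a raw DFT (rectangular window); the
# independent route against the Welch implementation
dft_band_fractions <- function(x, rate, scheme = band_scheme()) {
  tr <- attr(scheme, "total_range")
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  keep <- f <= rate / 2
  P <- P[keep]
  f <- f[keep]
  tot <- sum(P[f >= tr[1] & f < tr[2]])
  stats::setNames(
    vapply(seq_len(nrow(scheme)), function(i) {
      100 * sum(P[f >= scheme$f_lo[i] & f < scheme$f_hi[i]]) / tot
    }, 0.0),
    scheme$band
  )
}

# random test signal with broadband noise and on-DFT-grid tones kept clear
# of band edges (so the rectangular-window oracle itself does not leak)
random_band_signal <- function(n = 10000, rate = 500,
                               scheme = band_scheme()) {
  edges <- sort(unique(c(scheme$f_lo, scheme$f_hi,
                         attr(scheme, "total_range"))))
  x <- rnorm(n, sd = 0.2)
  for (j in seq_len(sample(0:3, 1))) {
    repeat {
      f0 <- round(runif(1, 1, 78) * n / rate) * rate / n
      if (min(abs(f0 - edges)) > 0.7) break
    }
    x <- x + runif(1, 0.1, 1) * sin(2 * pi * f0 * seq_len(n) / rate +
                                      runif(1, 0, 2 * pi))
  }
  x
}

disc_mask <- function(dim, cx, cy, r) {
  m <- matrix(FALSE, dim, dim)
  for (i in seq_len(dim)) {
    for (j in seq_len(dim)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
    }
  }
  m
}

# brute-force 4-connected component labeling (flood fill); the independent
# oracle for counting non-touching blobs
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1) %% nrow(mask) + 1
      c <- (p - 1) %/% nrow(mask) + 1
      if (r > 1) stack <- c(stack, p - 1L)
      if (r < nrow(mask)) stack <- c(stack, p + 1L)
      if (c > 1) stack <- c(stack, p - nrow(mask))
      if (c < ncol(mask)) stack <- c(stack, p + nrow(mask))
    }
  }
  lab
}

# truth-based grid for photometry tests: stages from the generator plus a
# z column that reproduces the RBD labeling
truth_grid <- function(stages, is_rbd) {
  make_grid(stages, z = ifelse(is_rbd, 3, 0))
}

# slide a window over the truth classes until it holds enough REM and
# RBD-like epochs (sessions are timed to cover sleep cycles)
find_rem_window <- function(truth, len = 90, need = 2) {
  cls <- truth$stage
  cls[truth$is_rbd] <- "RBD"
  for (i in seq_len(max(0, length(cls) - len + 1))) {
    w <- cls[i:(i + len - 1)]
    if (sum(w == "RBD") >= need && sum(w == "P") >= need) return(i)
  }
  NA_integer_
}

short_cfg <- function(...) sim_config(...)
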