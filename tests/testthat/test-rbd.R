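test_that("per-epoch RMS matches the brute-force definition", {
  set.seed(21)
  emg <- rnorm(30000, sd = 0.05)
  rec <- recording(rnorm(30000, sd = 0.01), emg, rep(0, 60))
  g <- rms_emg_grid(rec, make_grid(rep("W", 3)))
  for (i in 1:3) {
    expect_equal(g$rms_emg[i],
                 sqrt(mean(emg[((i - 1) * 10000 + 1):(i * 10000)]^2)))
  }
  # closed forms
  rec0 <- recording(rnorm(30000, sd = 0.01), rep(0, 30000), rep(0, 60))
  expect_equal(rms_emg_grid(rec0, make_grid(rep("W", 3)))$rms_emg,
               rep(0, 3))
  recc <- recording(rnorm(30000, sd = 0.01), rep(-0.3, 30000), rep(0, 60))
  expect_equal(rms_emg_grid(recc, make_grid(rep("W", 3)))$rms_emg,
               rep(0.3, 3))
})

test_that("z-scoring uses the population SD over non-artifact epochs", {
  g <- make_grid(c("W", "S", "P"))
  g$rms_emg <- c(1, 2, 3)
  gz <- zscore_rms(g)
  expect_equal(gz$z_rms_emg, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(mean(gz$z_rms_emg), 0, tolerance = 1e-9)

  g$rms_emg <- rep(2, 3)
  expect_warning(gz0 <- zscore_rms(g), "zero RMS-EMG variance")
  expect_equal(gz0$z_rms_emg, rep(0, 3))

  # artifact epochs are excluded from the moments and get NaN
  ga <- make_grid(c("W", "ARTIFACT", "S", "P"))
  ga$rms_emg <- c(1, 100, 2, 3)
  gza <- zscore_rms(ga)
  expect_true(is.nan(gza$z_rms_emg[2]))
  expect_equal(mean(gza$z_rms_emg[-2]), 0, tolerance = 1e-9)
})

test_that("RBD detection counts REM epochs with z strictly above threshold", {
  stages <- c(rep("P", 10), rep("W", 60), rep("S", 30))
  z <- rep(0, 100)
  z[c(1, 2)] <- c(2.5, 3.0)
  z[3] <- 2.0                      # boundary: not strictly above
  g <- make_grid(stages, z = z)
  s <- detect_rbd(g, z_threshold = 2)
  expect_equal(s$n_rem_epochs, 10)
  expect_equal(s$n_rbd_epochs, 2)
  expect_equal(s$rbd_ratio, 0.2)
  expect_equal(s$n_rbd_light + s$n_rbd_dark, s$n_rbd_epochs)
  expect_equal(s$n_rem_light + s$n_rem_dark, s$n_rem_epochs)
  expect_false(s$excluded_no_rem)
})

test_that("animals without any REM epoch are flagged for exclusion", {
  g <- make_grid(rep(c("W", "S"), 10))
  s <- detect_rbd(g)
  expect_true(s$excluded_no_rem)
  expect_equal(s$n_rbd_epochs, 0)
  expect_true(is.na(s$rbd_ratio))
})

test_that("RBD detection is monotone in the z threshold", {
  set.seed(22)
  stages <- sample(c("W", "S", "P"), 300, replace = TRUE)
  g <- make_grid(stages, z = rnorm(300))
  counts <- vapply(seq(0, 3, by = 0.25),
                   function(th) detect_rbd(g, th)$n_rbd_epochs, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("architecture summary enumerates bouts and percent time", {
  g <- make_grid(c("W", "W", "S", "S", "S", "P"))
  a <- architecture_summary(g)
  expect_equal(a$percent_day, c(W = 100 * 2 / 6, S = 50, P = 100 / 6),
               ignore_attr = TRUE)
  expect_equal(a$mean_bout_s, c(40, 60, 20), ignore_attr = TRUE)
  expect_equal(a$longest_bout_s, c(40, 60, 20), ignore_attr = TRUE)
  expect_equal(a$n_bouts, c(1L, 1L, 1L), ignore_attr = TRUE)

  # constant grid: one bout, longest = mean = total
  ac <- architecture_summary(make_grid(rep("W", 30)))
  expect_equal(ac$n_bouts[ac$stage == "W"], 1L)
  expect_equal(ac$longest_bout_s[ac$stage == "W"], 600)
  expect_equal(ac$mean_bout_s[ac$stage == "W"], 600)

  # alternation: every wake bout one epoch long
  aa <- architecture_summary(make_grid(rep(c("W", "S"), 20)))
  expect_equal(aa$mean_bout_s[aa$stage == "W"], 20)
  expect_equal(aa$n_bouts[aa$stage == "W"], 20L)
})

test_that("stage band profile separates RBD-like from atonic REM", {
  stages <- c(rep("W", 4), rep("S", 4), rep("P", 6))
  z <- c(rep(0, 11), rep(3, 3))      # last 3 REM epochs lose atonia
  theta <- c(rep(10, 11), rep(30, 3))
  g <- make_grid(stages, z = z,
                 bands = list(delta = 30, theta = 1, alpha = 5, sigma = 5,
                              beta = 5, low_gamma = 5, high_gamma = 5))
  g$theta <- theta
  prof <- stage_band_profile(g)
  th <- function(cl) prof$mean_power[prof$class == cl & prof$band == "theta"]
  expect_equal(th("P_rbd"), 30)
  expect_equal(th("P_atonic"), 10)
  expect_gt(th("P_rbd"), th("P_atonic"))
  # single-epoch class mean equals that epoch; empty class warns
  g2 <- make_grid(c("W", "P"), z = c(0, 0),
                  bands = list(delta = 42, theta = 7, alpha = 5, sigma = 5,
                               beta = 5, low_gamma = 5, high_gamma = 5))
  expect_warning(p2 <- stage_band_profile(g2), "empty stage class")
  expect_equal(p2$mean_power[p2$class == "P_atonic" & p2$band == "delta"],
               42)
  expect_true(is.nan(p2$mean_power[p2$class == "S" & p2$band == "delta"]))
})

test_that("day counts decompose into light plus dark for random grids", {
  set.seed(23)
  for (k in 1:10) {
    n <- sample(50:400, 1)
    start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      sample(0:86399, 1)
    g <- make_grid(sample(c("W", "S", "P"), n, replace = TRUE),
                   start = start, z = rnorm(n, sd = 1.5))
    s <- detect_rbd(g)
    expect_equal(s$n_rbd_light + s$n_rbd_dark, s$n_rbd_epochs)
    expect_true(s$rbd_ratio >= 0 && s$rbd_ratio <= 1 || is.na(s$rbd_ratio))
  }
})
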