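test_that("downsampling preserves constants, means, and window structure", {
  expect_equal(downsample_mean(rep(3.7, 1017 * 2), 1017, 500),
               rep(3.7, 1000))
  # linear ramp: integer-ratio window means from a brute-force loop
  x <- seq_len(1000)
  got <- downsample_mean(x, 1000, 250)
  brute <- vapply(seq_len(250),
                  function(i) mean(x[((i - 1) * 4 + 1):(i * 4)]), 0.0)
  expect_equal(got, brute, tolerance = 1e-12)
  # fractional ratio: output mean equals consumed-input mean
  set.seed(31)
  y <- rnorm(1017 * 5)
  out <- downsample_mean(y, 1017, 500)
  expect_equal(mean(out), mean(y[seq_len(length(out) * 1017 / 500)]),
               tolerance = 1e-9)
  # Nyquist alternation cancels
  alt <- rep(c(1, -1), 500)
  expect_lt(max(abs(downsample_mean(alt, 1000, 500))), 1e-12)
  expect_error(downsample_mean(y, 500, 1017), "exceeds")
})

test_that("F/F0 normalization matches a brute-force moving mean", {
  expect_equal(dff_moving(rep(5, 100), 10, window_s = 2), rep(1, 100))
  x <- rep(1, 200)
  x[100] <- 3                       # isolated impulse on unit baseline
  got <- dff_moving(x, 10, window_s = 2)
  hw <- floor(2 * 10 / 2)
  brute <- vapply(seq_along(x), function(i) {
    x[i] / mean(x[max(1, i - hw):min(length(x), i + hw)])
  }, 0.0)
  expect_equal(got, brute, tolerance = 1e-12)
  expect_gt(got[100], 1)
  # zero baseline -> NaN guard
  z <- c(rep(0, 40), rep(1, 60))
  expect_warning(out <- dff_moving(z, 10, window_s = 2), "zero baseline")
  expect_true(any(is.nan(out)))
})

test_that("per-minute z-scoring standardizes each window and kills offsets", {
  set.seed(32)
  rate <- 100
  x <- rnorm(rate * 180)
  z <- minute_zscore(x, rate)
  for (w in 1:3) {
    idx <- ((w - 1) * rate * 60 + 1):(w * rate * 60)
    expect_equal(mean(z[idx]), 0, tolerance = 1e-6)
    expect_equal(sd(z[idx]), 1, tolerance = 1e-6)
  }
  # adding a constant leaves the output unchanged
  expect_equal(minute_zscore(x + 100, rate), z, tolerance = 1e-9)
  # per-minute scale invariance: doubling the amplitude each minute
  s <- sin(2 * pi * seq_len(rate * 120) / rate)
  s[(rate * 60 + 1):(rate * 120)] <- 2 * s[(rate * 60 + 1):(rate * 120)]
  zs <- minute_zscore(s, rate)
  expect_equal(zs[seq_len(rate * 60)], zs[(rate * 60 + 1):(rate * 120)],
               tolerance = 1e-9)
  expect_warning(z0 <- minute_zscore(rep(2, rate * 60), rate),
                 "zero-variance")
  expect_equal(z0, rep(0, rate * 60))
})

test_that("epoch alignment equals brute-force averaging and translates with TTL", {
  set.seed(33)
  rate <- 50
  x <- rnorm(rate * 200)
  al <- epoch_align(x, rate, ttl = 1L)
  spe <- rate * 20
  brute <- vapply(seq_len(10),
                  function(e) mean(x[((e - 1) * spe + 1):(e * spe)]), 0.0)
  expect_equal(al$mean, brute, tolerance = 1e-12)
  # constant zero signal -> zero means
  expect_equal(epoch_align(rep(0, rate * 100), rate)$mean, rep(0, 5))
  # a step exactly at an epoch boundary flips the means at that epoch
  stp <- c(rep(0, spe * 3), rep(1, spe * 3))
  ms <- epoch_align(stp, rate)$mean
  expect_equal(ms, c(0, 0, 0, 1, 1, 1))
  # shifting the TTL by one epoch shifts the means by one epoch
  al2 <- epoch_align(x, rate, ttl = 1L + spe)
  expect_equal(al2$mean, brute[-1], tolerance = 1e-12)
  expect_error(epoch_align(x[seq_len(10)], rate), "no whole epoch")
})

test_that("per-epoch chain means match brute-force on random traces", {
  set.seed(34)
  for (k in 1:20) {
    rate <- 100
    n_ep <- sample(4:8, 1)
    x <- rnorm(rate * 20 * n_ep + sample(0:50, 1))
    al <- epoch_align(x, rate)
    spe <- rate * 20
    brute <- vapply(seq_len(nrow(al)), function(e) {
      mean(x[((e - 1) * spe + 1):(e * spe)])
    }, 0.0)
    expect_lt(max(abs(al$mean - brute) / pmax(abs(brute), 1e-12)), 1e-9)
  }
})

test_that("the chain recovers injected stage-dependent contrasts", {
  cfg <- sim_config()
  hyp <- simulate_hypnogram(cfg, 21600, seed = 301)
  set.seed(301)
  is_rbd <- rep(FALSE, length(hyp))
  is_rbd[phenomap:::pick_rbd_epochs(hyp, cfg$rbd_fraction)] <- TRUE
  truth <- tibble::tibble(stage = hyp, is_rbd = is_rbd)
  i0 <- find_rem_window(truth)
  expect_false(is.na(i0))
  win <- i0:(i0 + 89)
  cls <- truth$stage
  cls[truth$is_rbd] <- "RBD"
  sp <- synth_photometry(cls[win], cfg, seed = 301)
  g <- truth_grid(truth$stage[win], truth$is_rbd[win])
  em <- photometry_epoch_means(sp$trace, g)
  ss <- stage_conditioned_signal(em)
  rc <- ss$rbd_contrasts
  expect_gt(rc$rbd_minus_rem[rc$channel == "da"], 0)
  expect_lt(rc$rbd_minus_rem[rc$channel == "ach"], 0)
  # isosbestic carries no stage effect: its contrast is the smallest
  expect_lt(abs(rc$rbd_minus_rem[rc$channel == "iso"]),
            abs(rc$rbd_minus_rem[rc$channel == "da"]))
})

test_that("identical channels produce zero contrasts and missing REM is noted", {
  em <- tibble::tibble(
    epoch = 1:8,
    stage_class = rep(c("W", "S", "P_atonic", "P_rbd"), 2),
    iso = rnorm(8), ach = 0, da = 0
  )
  em$ach <- em$iso
  em$da <- em$iso
  ss <- stage_conditioned_signal(em)
  expect_true(all(abs(ss$iso_contrasts$contrast_vs_iso) < 1e-12))
  # sensor channels inherit exactly the isosbestic RBD-vs-REM contrast
  rc <- ss$rbd_contrasts
  iso_c <- rc$rbd_minus_rem[rc$channel == "iso"]
  expect_true(all(abs(rc$rbd_minus_rem - iso_c) < 1e-12))

  em2 <- em[em$stage_class %in% c("W", "S"), ]
  ss2 <- stage_conditioned_signal(em2)
  expect_true(any(grepl("no REM", ss2$notes)))
  expect_true(all(is.nan(
    ss2$rbd_contrasts$rbd_minus_rem
  )))
})

test_that("photometry traces round-trip through CSV", {
  set.seed(35)
  tr <- photometry_trace(rnorm(500), rnorm(500), rnorm(500),
                         rate = 250, ttl = 42L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_photometry(tr, path)
  back <- read_photometry(path)
  expect_equal(back$iso, tr$iso)
  expect_equal(back$da, tr$da)
  expect_equal(back$rate, 250)
  expect_equal(back$ttl, 42L)
})
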