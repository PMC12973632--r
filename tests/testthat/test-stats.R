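# textbook one-way ANOVA from first principles
hand_anova <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  means <- vapply(groups, mean, 0.0)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0.0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

test_that("the equal-variance branch reproduces textbook ANOVA", {
  groups <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(3, 4, 5, 6))
  d <- data.frame(value = unlist(groups),
                  group = rep(names(groups), each = 4))
  res <- gated_anova(d, control = "a")
  ref <- hand_anova(groups)
  expect_equal(res$branch, "anova_tukey")
  expect_equal(res$omnibus$statistic, ref$f, tolerance = 1e-9)
  expect_equal(res$omnibus$p.value, ref$p, tolerance = 1e-9)
  expect_equal(nrow(res$posthoc), 3)          # Tukey all pairs
  expect_true(all(res$posthoc$p.adjusted >= res$omnibus$p.value * 0))
  g <- glance(res)
  expect_equal(g$statistic, ref$f)
})

test_that("the branch decision follows Bartlett's gate", {
  set.seed(61)
  # equal spread -> equal-variance path, non-significant omnibus
  d_eq <- data.frame(value = rnorm(30), group = rep(c("a", "b", "c"), 10))
  expect_equal(gated_anova(d_eq, control = "a")$branch, "anova_tukey")
  # variances 1 vs 100 -> Welch/Brown-Forsythe with Dunnett
  welch_taken <- vapply(1:40, function(s) {
    set.seed(s)
    d <- data.frame(
      value = c(rnorm(10, sd = 1), rnorm(10, sd = 10), rnorm(10, sd = 1)),
      group = rep(c("a", "b", "c"), each = 10)
    )
    gated_anova(d, control = "a")$branch == "welch_dunnett"
  }, TRUE)
  expect_gte(mean(welch_taken), 0.95)
  # report structure on the unequal branch
  set.seed(1)
  d <- data.frame(
    value = c(rnorm(10, sd = 1), rnorm(10, sd = 10), rnorm(10, sd = 1)),
    group = rep(c("a", "b", "c"), each = 10)
  )
  res <- gated_anova(d, control = "a")
  expect_setequal(res$omnibus$test,
                  c("Welch ANOVA", "Brown-Forsythe ANOVA"))
  expect_equal(res$omnibus$statistic[res$omnibus$test == "Welch ANOVA"],
               unname(oneway.test(value ~ group, d)$statistic),
               tolerance = 1e-9)
  expect_equal(nrow(res$posthoc), 2)          # Dunnett vs control
})

test_that("degenerate and two-group inputs are handled", {
  d0 <- data.frame(value = rep(1, 9), group = rep(c("a", "b", "c"), 3))
  expect_error(gated_anova(d0), "degenerate")
  d2 <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                   group = rep(c("a", "b"), each = 3))
  res <- gated_anova(d2)
  expect_equal(res$branch, "ttest")
})

test_that("Dunnett adjustment matches a Monte-Carlo max-|t| oracle", {
  set.seed(62)
  n <- 20
  d <- data.frame(
    value = c(rnorm(n), rnorm(n, 0.5), rnorm(n, 1)),
    group = rep(c("ctrl", "g1", "g2"), each = n)
  )
  res <- dunnett_vs_control(d, control = "ctrl")
  # oracle: simulate the joint null of the two contrast t's from normal
  # group means and a shared chi-squared variance
  B <- 200000
  df <- 3 * n - 3
  set.seed(63)
  z0 <- matrix(rnorm(3 * B), B, 3) / sqrt(n)
  s2 <- rchisq(B, df) / df
  t1 <- (z0[, 2] - z0[, 1]) / sqrt(s2 * 2 / n)
  t2 <- (z0[, 3] - z0[, 1]) / sqrt(s2 * 2 / n)
  maxt <- pmax(abs(t1), abs(t2))
  for (i in 1:2) {
    p_mc <- mean(maxt >= abs(res$statistic[i]))
    expect_lt(abs(res$p.adjusted[i] - p_mc), 0.01)
  }
  # adjusted never smaller than the unadjusted two-sided p
  p_un <- 2 * pt(-abs(res$statistic), df)
  expect_true(all(res$p.adjusted >= p_un - 1e-12))
})

test_that("Dunnett with one comparison reduces to the pooled t-test", {
  set.seed(64)
  d <- data.frame(value = c(rnorm(8), rnorm(8, 1)),
                  group = rep(c("ctrl", "tr"), each = 8))
  res <- dunnett_vs_control(d, control = "ctrl")
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(res$p.adjusted, tt$p.value, tolerance = 1e-3)
  # identical groups vs identical control -> p near 1
  d1 <- data.frame(value = rep(c(1, 2, 3), 3) + rnorm(9, sd = 1e-8),
                   group = rep(c("ctrl", "g1", "g2"), each = 3))
  r1 <- dunnett_vs_control(d1, control = "ctrl")
  expect_true(all(r1$p.adjusted > 0.99))
  expect_error(
    dunnett_vs_control(
      data.frame(value = c(1, 2, 3), group = c("ctrl", "a", "a")),
      control = "ctrl"
    ),
    "n >= 2"
  )
})

test_that("the two-way interaction detects a male-only effect and errors on df=0", {
  set.seed(65)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    d <- expand.grid(rep_i = 1:8, group = c("ctrl", "pff"),
                     sex = c("M", "F"))
    d$value <- rnorm(nrow(d)) +
      ifelse(d$group == "pff" & d$sex == "M", 2, 0)
    twoway_interaction(d)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  d1 <- expand.grid(group = c("a", "b"), sex = c("M", "F"))
  d1$value <- rnorm(4)
  expect_error(twoway_interaction(d1), "residual")
})

test_that("t-tests match the hand formula and reject degenerate input", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- phm_ttest(a, b)
  sp <- sqrt((sum((a - 2)^2) + sum((b - 5)^2)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-9)
  # identical groups with spread: t = 0, p = 1
  r0 <- phm_ttest(a, a)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_error(phm_ttest(rep(1, 3), rep(2, 3)), "zero pooled variance")
  expect_error(phm_ttest(c(1, 2, 3), c(2, 3, 4), paired = TRUE),
               "paired differences")
})

test_that("ROUT flags planted outliers and spares identical values", {
  flagged <- vapply(1:50, function(s) {
    set.seed(s)
    v <- c(rnorm(20), 10)
    ro <- rout_outliers(v)
    ro$outlier[21] && sum(ro$outlier[1:20]) <= 1
  }, TRUE)
  expect_gte(mean(flagged), 0.9)
  expect_false(any(rout_outliers(rep(2, 10))$outlier))
  expect_warning(r2 <- rout_outliers(c(1, 2)), "fewer than 3")
  expect_false(any(r2$outlier))
})

test_that("ROUT false-flag rate on clean data stays near Q", {
  rates <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    mean(rout_outliers(rnorm(20))$outlier)
  }, 0.0)
  expect_lte(mean(rates), 0.06)
})
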