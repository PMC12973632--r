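#' ROUT outlier detection (constant model)
#'
#' Robust outlier identification for column data: the robust fit is the
#' sample median, the robust scale (RSDR) is the 68.27th percentile of the
#' absolute residuals with the n/(n-1) small-sample correction, each point
#' gets a two-tailed t p-value from residual/RSDR with n-1 df, and a
#' false-discovery-rate step at rate `Q` flags the extreme points. With
#' fewer than 3 values no exclusion is performed (warning).
#'
#' @param values numeric vector.
#' @param Q FDR rate, default 0.05 (the "Q = 5%" setting).
#' @return tibble with `value` and `outlier`; robust center/scale in
#'   attributes.
#' @export
rout_outliers <- function(values, Q = 0.05) {
  n <- length(values)
  out <- tibble(value = values, outlier = FALSE)
  if (n < 3) {
    warning("fewer than 3 values: no outlier exclusion performed",
            call. = FALSE)
    return(out)
  }
  center <- median(values)
  res <- values - center
  rsdr <- quantile(abs(res), 0.6827, type = 7, names = FALSE) * n / (n - 1)
  if (rsdr == 0) {
    out$outlier <- res != 0
  } else {
    t_stat <- abs(res) / rsdr
    p <- 2 * pt(-t_stat, df = n - 1)
    ord <- order(p)
    thresh <- Q * seq_len(n) / n
    passed <- p[ord] <= thresh
    k <- if (any(passed)) max(which(passed)) else 0L
    if (k > 0) out$outlier[ord[seq_len(k)]] <- TRUE
  }
  attr(out, "center") <- center
  attr(out, "rsdr") <- rsdr
  out
}

# Brown-Forsythe ANOVA F* (group means weighted by 1 - n_i/N in the
# denominator) with Satterthwaite-style df
brown_forsythe_f <- function(values, g) {
  g <- factor(g)
  n_i <- as.numeric(table(g))
  N <- sum(n_i)
  m_i <- tapply(values, g, mean)
  v_i <- tapply(values, g, stats::var)
  grand <- mean(values)
  num <- sum(n_i * (m_i - grand)^2)
  ci <- (1 - n_i / N) * v_i
  den <- sum(ci)
  f <- num / den
  df1 <- length(n_i) - 1
  df2 <- den^2 / sum(ci^2 / (n_i - 1))
  tibble(statistic = f, df1 = df1, df2 = df2,
         p.value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Dunnett many-to-one comparisons
#'
#' Two-sided comparisons of every non-control group mean against the
#' control, with familywise adjustment through the multivariate-t
#' distribution of the max-|t| statistic (correlation
#' `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`, pooled error variance,
#' N - k df). The multivariate-t probability is evaluated numerically to
#' about 1e-4; with a single comparison the adjusted p reduces to the
#' ordinary two-sample t p-value on the pooled variance.
#'
#' @param data data frame.
#' @param value,group column names (strings).
#' @param control control group label.
#' @return tibble, one row per comparison: estimate, t, df, `p.adjusted`.
#' @export
dunnett_vs_control <- function(data, value = "value", group = "group",
                               control) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (!control %in% levels(g)) stop("control group not found", call. = FALSE)
  n_i <- table(g)
  if (n_i[[control]] < 2) stop("control group needs n >= 2", call. = FALSE)
  k <- nlevels(g)
  N <- length(y)
  m <- tapply(y, g, mean)
  msw <- sum(tapply(y, g, function(x) sum((x - mean(x))^2))) / (N - k)
  others <- setdiff(levels(g), control)
  n0 <- n_i[[control]]
  ni <- as.numeric(n_i[others])
  est <- m[others] - m[[control]]
  se <- sqrt(msw * (1 / ni + 1 / n0))
  t_stat <- est / se
  lam <- sqrt(ni / (ni + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_adj <- dunnett_adjusted_p(unname(t_stat), corr, N - k)
  tibble(comparison = paste(others, "-", control), estimate = unname(est),
         statistic = unname(t_stat), df = N - k, p.adjusted = p_adj)
}

# familywise-adjusted p for each |t| under the multivariate t; quasi-Monte
# Carlo integration with a locally fixed RNG stream so results are
# reproducible
dunnett_adjusted_p <- function(t_stat, corr, df) {
  vapply(t_stat, function(tt) {
    if (!is.finite(tt)) return(NA_real_)
    a <- abs(tt)
    pr <- with_local_seed(20240101L, mvtnorm::pmvt(
      lower = rep(-a, nrow(corr)), upper = rep(a, nrow(corr)),
      df = as.integer(df), corr = corr, type = "shifted",
      algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000L)
    ))
    max(0, min(1, 1 - as.numeric(pr)))
  }, 0.0)
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Bartlett-gated ANOVA decision tree
#'
#' The study's rule for three or more groups: run Bartlett's test on the
#' group variances; if it is not significant (p > 0.05) run a classical
#' one-way ANOVA with Tukey all-pairs post-hoc comparisons; if it is
#' significant, run Brown-Forsythe and Welch ANOVA with Dunnett
#' comparisons against the control. Two groups redirect to a t-test.
#'
#' @param data data frame.
#' @param value,group column names (strings).
#' @param control control label (needed on the Dunnett branch; defaults to
#'   the first group level with a message).
#' @param alpha gate level for Bartlett's test.
#' @return object of class `phenomap_anova`: `branch`, `bartlett`,
#'   `omnibus` (tibble; both Welch and Brown-Forsythe rows on the
#'   unequal-variance branch), `posthoc`.
#' @export
gated_anova <- function(data, value = "value", group = "group",
                        control = NULL, alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (any(!is.finite(y))) stop("values must be finite", call. = FALSE)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (k == 2) {
    lv <- levels(g)
    tt <- phm_ttest(y[g == lv[1]], y[g == lv[2]])
    return(structure(list(branch = "ttest", bartlett = NULL,
                          omnibus = tt, posthoc = NULL),
                     class = "phenomap_anova"))
  }
  v_i <- tapply(y, g, stats::var)
  if (all(v_i == 0)) {
    if (length(unique(y)) == 1) {
      stop("degenerate input: all groups constant and equal", call. = FALSE)
    }
    stop("all groups have zero variance", call. = FALSE)
  }
  bt <- bartlett.test(y, g)
  if (bt$p.value > alpha) {
    branch <- "anova_tukey"
    fit <- aov(y ~ g)
    s <- summary(fit)[[1]]
    omnibus <- tibble(test = "one-way ANOVA", statistic = s[["F value"]][1],
                      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                      p.value = s[["Pr(>F)"]][1])
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble(comparison = rownames(tk),
                      estimate = tk[, "diff"],
                      p.adjusted = tk[, "p adj"])
  } else {
    branch <- "welch_dunnett"
    if (is.null(control)) {
      control <- levels(g)[1]
      message("no control given; using first group '", control,
              "' for Dunnett comparisons")
    }
    wl <- oneway.test(y ~ g, var.equal = FALSE)
    bf <- brown_forsythe_f(y, g)
    omnibus <- dplyr::bind_rows(
      tibble(test = "Welch ANOVA", statistic = unname(wl$statistic),
             df1 = unname(wl$parameter[1]), df2 = unname(wl$parameter[2]),
             p.value = wl$p.value),
      dplyr::mutate(bf, test = "Brown-Forsythe ANOVA", .before = 1)
    )
    posthoc <- dunnett_vs_control(
      data.frame(value = y, group = g), control = control
    )
  }
  structure(list(branch = branch,
                 bartlett = tibble(statistic = unname(bt$statistic),
                                   df = unname(bt$parameter),
                                   p.value = bt$p.value),
                 omnibus = omnibus, posthoc = posthoc),
            class = "phenomap_anova")
}

#' @export
print.phenomap_anova <- function(x, ...) {
  cat("<phenomap_anova> branch: ", x$branch, "\n", sep = "")
  if (!is.null(x$bartlett)) {
    cat("  Bartlett p = ", format(x$bartlett$p.value, digits = 4), "\n",
        sep = "")
  }
  print(x$omnibus)
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Two-way sex-by-group interaction
#'
#' Interaction F and p from the two-factor linear model, tested as the
#' marginal (type-III-style, sum-contrast) improvement of the interaction
#' term over the additive model; unbalanced designs are allowed, empty
#' cells and designs without residual df are errors.
#'
#' @param data data frame.
#' @param value,group,sex column names (strings).
#' @return one-row tibble: term, df1, df2, statistic, p.value.
#' @export
twoway_interaction <- function(data, value = "value", group = "group",
                               sex = "sex") {
  y <- data[[value]]
  res <- vec_interaction(matrix(y, ncol = 1), data[[group]], data[[sex]])
  g <- factor(data[[group]]); s <- factor(data[[sex]])
  df1 <- (nlevels(g) - 1) * (nlevels(s) - 1)
  df2 <- length(y) - nlevels(g) * nlevels(s)
  tibble(term = paste0(group, ":", sex), df1 = df1, df2 = df2,
         statistic = res$f, p.value = res$p)
}

#' Two-group t-test
#'
#' Classical paired or unpaired two-sided t-test; identical inputs with no
#' variability (zero pooled variance, or zero variance of the paired
#' differences) are an error rather than a silent p of 1.
#'
#' @param a,b numeric vectors (equal length when paired).
#' @param paired logical.
#' @return one-row tibble: statistic, df, estimate, p.value, method.
#' @export
phm_ttest <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group",
                                           call. = FALSE)
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal n",
                                     call. = FALSE)
    if (stats::var(a - b) == 0) {
      stop("zero variance of paired differences", call. = FALSE)
    }
  } else if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  tt <- t.test(a, b, paired = paired, var.equal = !paired)
  tibble(test = if (paired) "paired t-test" else "unpaired t-test",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         estimate = if (paired) unname(tt$estimate) else {
           unname(tt$estimate[1] - tt$estimate[2])
         },
         p.value = tt$p.value)
}
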