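#' Grayscale section image
#'
#' An 8-bit grayscale section (values 0-255, dark = DAB deposit) with a
#' pixel size in micrometres.
#'
#' @param mat numeric matrix in `[0, 255]`.
#' @param microns_per_px pixel edge, micrometres.
#' @param animal_id,section_label metadata.
#' @export
section_image <- function(mat, microns_per_px = 2.5, animal_id = NULL,
                          section_label = NULL) {
  stopifnot(is.matrix(mat))
  if (length(mat) == 0) stop("empty image", call. = FALSE)
  if (min(mat) < 0 || max(mat) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (microns_per_px <= 0) stop("pixel size must be positive", call. = FALSE)
  structure(mat, microns_per_px = microns_per_px, animal_id = animal_id,
            section_label = section_label,
            class = c("phenomap_section", "matrix", "array"))
}

#' Read a section image (PNG or TIFF) as 8-bit grayscale
#'
#' Multi-channel images are averaged to gray; intensities are rescaled to
#' the 0-255 range.
#'
#' @param path image path.
#' @param microns_per_px pixel edge, micrometres.
#' @export
read_section <- function(path, microns_per_px = 2.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  section_image(round(img * 255), microns_per_px = microns_per_px)
}

#' Normalize a section to its whole-image mean signal
#'
#' DAB deposits are dark on a light background, so the stain signal is
#' `255 - gray`; each pixel is then divided by the whole-image mean signal,
#' making the output mean exactly 1 and removing section-to-section
#' exposure differences. The operation is idempotent: an already-normalized
#' density map is returned divided by its (unit) mean, unchanged. An
#' all-white image has zero signal and is an error.
#'
#' @param img a [section_image()] (gray) or an already-normalized density.
#' @return A density matrix of class `phenomap_density`, mean 1.
#' @export
normalize_section <- function(img) {
  if (inherits(img, "phenomap_density")) {
    sig <- unclass(img)
  } else {
    sig <- 255 - unclass(img)
  }
  m <- mean(sig)
  if (m == 0) stop("zero signal: all-white image cannot be normalized",
                   call. = FALSE)
  structure(sig / m, microns_per_px = attr(img, "microns_per_px"),
            animal_id = attr(img, "animal_id"),
            class = c("phenomap_density", "matrix", "array"))
}

#' Downsample an image into ROI blocks
#'
#' Non-overlapping `factor` x `factor` block means; ragged edges are
#' truncated. With the default factor of 5 each ROI aggregates 25 source
#' pixels.
#'
#' @param img matrix (density or gray).
#' @param factor block edge in source pixels.
#' @return matrix of block means, dims `floor(dim(img)/factor)`.
#' @export
downsample_rois <- function(img, factor = 5) {
  x <- unclass(img)
  nr <- nrow(x) %/% factor
  nc <- ncol(x) %/% factor
  if (nr < 1 || nc < 1) stop("image smaller than one ROI block",
                             call. = FALSE)
  x <- x[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # average rows within blocks, then columns
  xr <- rowsum(x, rep(seq_len(nr), each = factor)) / factor
  out <- t(rowsum(t(xr), rep(seq_len(nc), each = factor)) / factor)
  dimnames(out) <- NULL
  out
}

#' Assemble an ROI stack
#'
#' One aligned ROI grid per animal (cross-animal registration is the
#' caller's responsibility; only shape equality is checked here) linked to
#' a study design table.
#'
#' @param grids named list of equal-shape matrices, names = animal ids.
#' @param design tibble with `animal_id`, `group`, optional `sex`.
#' @param control control group label.
#' @return list of class `phenomap_roi_stack`.
#' @export
roi_stack <- function(grids, design, control) {
  design <- as_tibble(design)
  stopifnot(all(c("animal_id", "group") %in% names(design)))
  if (anyDuplicated(design$animal_id)) {
    stop("every animal must appear exactly once in the design",
         call. = FALSE)
  }
  if (!control %in% design$group) {
    stop("control group '", control, "' not present in design",
         call. = FALSE)
  }
  miss <- setdiff(design$animal_id, names(grids))
  if (length(miss)) {
    stop("missing grids for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  grids <- grids[design$animal_id]
  dims <- vapply(grids, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all ROI grids must share the same shape", call. = FALSE)
  }
  structure(list(grids = grids, design = design, control = control,
                 dim = dims[, 1]),
            class = "phenomap_roi_stack")
}

# animals x ROI value matrix (ROIs in column-major order)
stack_matrix <- function(stack) {
  t(vapply(stack$grids, as.numeric, numeric(prod(stack$dim))))
}

# vectorized one-way ANOVA across the columns of V
vec_oneway <- function(V, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- nrow(V)
  n_g <- as.numeric(table(g))
  gm <- rowsum(V, g) / n_g                    # group means, k x ROI
  grand <- colMeans(V)
  ssb <- colSums(n_g * (gm - rep(grand, each = k))^2)
  ssw <- colSums((V - gm[as.integer(g), , drop = FALSE])^2)
  df1 <- k - 1
  df2 <- N - k
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero <- ssw <= 0                            # no within-group variance
  f[zero] <- NaN
  p[zero] <- NaN
  list(f = f, p = p, msw = msw, df2 = df2, group_means = gm, n_g = n_g,
       levels = levels(g))
}

#' ROI-by-ROI group statistics
#'
#' For every ROI of a registered stack: a one-way ANOVA p-value across
#' groups; Dunnett-style many-to-one comparisons of each group against the
#' control; and, when the non-control groups form an ordered time course,
#' an onset map giving the earliest timepoint whose control contrast is
#' significant at that timepoint and at every later one ("increases and
#' remains significantly different"). `mode = "sex_by_group"` instead
#' reports the sex-by-group interaction F and p per ROI. ANOVA p-values are
#' reported raw (no across-ROI correction) to match the source procedure; a
#' Benjamini-Hochberg option exists but is off by default.
#'
#' @param stack a [roi_stack()].
#' @param mode "oneway" or "sex_by_group".
#' @param posthoc run Dunnett comparisons (oneway mode).
#' @param timepoint_order character vector ordering the non-control groups
#'   for the onset map; defaults to their design order.
#' @param alpha significance level for the onset map.
#' @param p_adjust "none" (default) or "BH" across ROIs.
#' @return list of class `phenomap_roi_test` with matrices `p`, `statistic`,
#'   `onset`, and array `posthoc_p` (ROI x group).
#' @export
roi_group_test <- function(stack, mode = c("oneway", "sex_by_group"),
                           posthoc = TRUE, timepoint_order = NULL,
                           alpha = 0.05, p_adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  V <- stack_matrix(stack)
  g <- stack$design$group
  if (min(table(g)) < 2) {
    stop("need at least 2 animals per group per ROI", call. = FALSE)
  }
  dm <- stack$dim
  shape <- function(v) matrix(v, dm[1], dm[2])

  if (mode == "sex_by_group") {
    if (!"sex" %in% names(stack$design)) {
      stop("sex_by_group mode needs a 'sex' column in the design",
           call. = FALSE)
    }
    res <- vec_interaction(V, g, stack$design$sex)
    p <- res$p
    if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    return(structure(list(p = shape(p), statistic = shape(res$f),
                          posthoc_p = NULL, onset = NULL, mode = mode,
                          dim = dm),
                     class = "phenomap_roi_test"))
  }

  av <- vec_oneway(V, g)
  p <- av$p
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")

  posthoc_p <- NULL
  onset <- NULL
  if (posthoc) {
    ctrl <- stack$control
    others <- setdiff(av$levels, ctrl)
    i0 <- match(ctrl, av$levels)
    idx <- match(others, av$levels)
    n0 <- av$n_g[i0]
    ni <- av$n_g[idx]
    lam <- sqrt(ni / (ni + n0))
    corr <- outer(lam, lam)
    diag(corr) <- 1
    se <- sqrt(av$msw)                       # per-ROI sqrt(MSW)
    posthoc_p <- matrix(NA_real_, ncol(V), length(others),
                        dimnames = list(NULL, others))
    tmat <- (t(av$group_means[idx, , drop = FALSE]) -
               av$group_means[i0, ]) /
      outer(se, sqrt(1 / ni + 1 / n0))
    for (r in seq_len(ncol(V))) {
      if (!is.finite(av$p[r])) next
      posthoc_p[r, ] <- dunnett_adjusted_p(tmat[r, ], corr, av$df2)
    }
    if (is.null(timepoint_order)) {
      timepoint_order <- unique(g[g != ctrl])
    }
    sig <- posthoc_p[, timepoint_order, drop = FALSE] < alpha
    k <- length(timepoint_order)
    onset_v <- apply(sig, 1, function(row) {
      if (any(is.na(row))) return(NA_integer_)
      ok <- rev(cumprod(rev(row))) == 1     # significant from t onward
      if (any(ok)) which(ok)[1] else NA_integer_
    })
    onset <- shape(onset_v)
  }

  structure(list(p = shape(p), statistic = shape(av$f),
                 posthoc_p = posthoc_p, onset = onset, mode = mode,
                 timepoint_order = timepoint_order, dim = dm),
            class = "phenomap_roi_test")
}

# vectorized two-way interaction (type-III-style marginal test with sum
# contrasts: full model vs model without the interaction term)
vec_interaction <- function(V, g, sex) {
  g <- factor(g)
  sex <- factor(sex)
  if (nlevels(g) < 2 || nlevels(sex) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  if (any(table(g, sex) == 0)) {
    stop("empty factor cell(s): ",
         paste(which(table(g, sex) == 0), collapse = ", "), call. = FALSE)
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X1 <- stats::model.matrix(~ g * sex)
  X0 <- stats::model.matrix(~ g + sex)
  df_int <- ncol(X1) - ncol(X0)
  df_res <- nrow(X1) - ncol(X1)
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  rss <- function(X) {
    r <- stats::lm.fit(X, V)$residuals
    if (is.null(dim(r))) r <- matrix(r, ncol = 1)
    colSums(r^2)
  }
  rss1 <- rss(X1)
  rss0 <- rss(X0)
  f <- ((rss0 - rss1) / df_int) / (rss1 / df_res)
  p <- pf(f, df_int, df_res, lower.tail = FALSE)
  zero <- rss1 <= 0 & rss0 <= 0
  f[zero] <- NaN
  p[zero] <- NaN
  list(f = f, p = p)
}

#' @export
print.phenomap_roi_test <- function(x, ...) {
  cat("<phenomap_roi_test> ", x$dim[1], "x", x$dim[2], " ROIs, mode ",
      x$mode, "\n", sep = "")
  cat("  ROIs with p < 0.05: ", sum(x$p < 0.05, na.rm = TRUE), " / ",
      sum(is.finite(x$p)), "\n", sep = "")
  if (!is.null(x$onset)) {
    cat("  ROIs with a detected onset: ", sum(!is.na(x$onset)), "\n",
        sep = "")
  }
  invisible(x)
}
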