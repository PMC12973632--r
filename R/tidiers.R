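#' Tidy a gated ANOVA report
#'
#' Returns the post-hoc comparison table (Tukey or Dunnett depending on the
#' branch taken), or the omnibus table when no post-hoc exists.
#'
#' @param x a `phenomap_anova`.
#' @param ... unused.
#' @method tidy phenomap_anova
#' @export
tidy.phenomap_anova <- function(x, ...) {
  if (!is.null(x$posthoc)) x$posthoc else x$omnibus
}

#' One-row summary of a gated ANOVA report
#'
#' The branch taken, Bartlett gate p, and the primary omnibus statistic
#' (the Welch row on the unequal-variance branch).
#'
#' @param x a `phenomap_anova`.
#' @param ... unused.
#' @method glance phenomap_anova
#' @export
glance.phenomap_anova <- function(x, ...) {
  om <- x$omnibus[1, ]
  tibble(
    branch = x$branch,
    bartlett.p.value = if (is.null(x$bartlett)) NA_real_ else {
      x$bartlett$p.value
    },
    statistic = om$statistic,
    p.value = om$p.value
  )
}

#' Tidy an ROI test map
#'
#' One row per ROI: row/col, F statistic, p, onset timepoint (when
#' computed) and the per-group Dunnett-adjusted p-values.
#'
#' @param x a `phenomap_roi_test`.
#' @param ... unused.
#' @method tidy phenomap_roi_test
#' @export
tidy.phenomap_roi_test <- function(x, ...) {
  out <- tibble(
    row = rep(seq_len(x$dim[1]), x$dim[2]),
    col = rep(seq_len(x$dim[2]), each = x$dim[1]),
    statistic = as.numeric(x$statistic),
    p.value = as.numeric(x$p)
  )
  if (!is.null(x$onset)) out$onset <- as.numeric(x$onset)
  if (!is.null(x$posthoc_p)) {
    ph <- as_tibble(as.data.frame(x$posthoc_p))
    names(ph) <- paste0("p.adj.", names(ph))
    out <- dplyr::bind_cols(out, ph)
  }
  out
}

#' One-row summary of an ROI test map
#'
#' @param x a `phenomap_roi_test`.
#' @param ... unused.
#' @method glance phenomap_roi_test
#' @export
glance.phenomap_roi_test <- function(x, ...) {
  tibble(
    n_rois = prod(x$dim),
    n_tested = sum(is.finite(x$p)),
    n_significant = sum(x$p < 0.05, na.rm = TRUE),
    n_with_onset = if (is.null(x$onset)) NA_integer_ else {
      sum(!is.na(x$onset))
    }
  )
}
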