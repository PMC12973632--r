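#' Cluster size-class scheme
#'
#' Pixel area 6.25 square micrometres. Clusters of at most 1 pixel are
#' excluded as too small; clusters above 15,000 square micrometres are
#' excluded as artifacts (the bound is evaluated in micrometres, the small
#' bound in pixels, exactly as the printed procedure mixes units). The
#' remaining range partitions into small (1, 50], medium (50, 200] and
#' large (> 200) pixels, half-open on the left so 50 and 200 are never
#' double-counted.
#'
#' @param pixel_area_um2 area of one pixel.
#' @param exclude_px clusters with at most this many pixels are dropped.
#' @param artifact_um2 clusters strictly above this area are artifacts.
#' @param small_max_px,medium_max_px upper class bounds (closed), pixels.
#' @export
size_class_scheme <- function(pixel_area_um2 = 6.25, exclude_px = 1,
                              artifact_um2 = 15000, small_max_px = 50,
                              medium_max_px = 200) {
  structure(list(pixel_area_um2 = pixel_area_um2, exclude_px = exclude_px,
                 artifact_um2 = artifact_um2, small_max_px = small_max_px,
                 medium_max_px = medium_max_px),
            class = "phenomap_size_scheme")
}

#' Threshold an image at the 95th signal percentile
#'
#' The stain signal is the inverted intensity (dark = signal, as in
#' [normalize_section()]); the mask keeps pixels whose signal strictly
#' exceeds the image's 95th percentile. The percentile is an order
#' statistic (quantile type 1), which makes the mask exactly invariant
#' under any strictly monotone intensity transform. The alternative
#' reading, 95% of the maximum intensity, sits behind
#' `mode = "fraction_of_max"`. A constant image yields an empty mask with
#' a warning.
#'
#' @param img gray matrix 0-255 (or a density map with `invert = FALSE`).
#' @param percentile percent, default 95.
#' @param invert treat dark pixels as signal.
#' @param mode "percentile" (rank-based) or "fraction_of_max".
#' @return logical matrix.
#' @export
binarize_percentile <- function(img, percentile = 95, invert = TRUE,
                                mode = c("percentile", "fraction_of_max")) {
  mode <- match.arg(mode)
  sig <- unclass(img)
  if (length(sig) == 0) stop("empty image", call. = FALSE)
  if (invert) sig <- 255 - sig
  thr <- if (mode == "percentile") {
    quantile(sig, percentile / 100, type = 1, names = FALSE)
  } else {
    max(sig) * percentile / 100
  }
  mask <- sig > thr
  if (!any(mask)) warning("empty mask (constant or flat image)",
                          call. = FALSE)
  mask
}

#' Split touching clusters with a distance-transform watershed
#'
#' Connected foreground is split along watershed lines between local maxima
#' of the Euclidean distance transform, so overlapping near-convex blobs
#' separate while single convex blobs stay whole. The neighborhood radius
#' for merging nearby distance maxima is 3 px, damping over-segmentation
#' from pixel noise.
#'
#' @param mask logical matrix.
#' @param tolerance,ext passed to the watershed (minimum object-height
#'   separation and neighborhood radius).
#' @return integer label matrix (0 = background).
#' @export
watershed_split <- function(mask, tolerance = 1, ext = 3) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

#' Cluster table, size-class counts and densities
#'
#' Per-cluster pixel area, area in square micrometres and centroid
#' (0-based row/col), classified by the size scheme. The reported total is
#' small + medium + large after the 1-pixel and artifact exclusions;
#' densities are counts divided by the tissue area.
#'
#' @param labels integer label matrix from [watershed_split()].
#' @param scheme a [size_class_scheme()].
#' @param tissue_area_um2 positive tissue area.
#' @return list of class `phenomap_clusters`: `table` (per-cluster tibble),
#'   `counts` (per-class), `total`, `density` (per-class counts / area).
#' @export
count_clusters <- function(labels, scheme = size_class_scheme(),
                           tissue_area_um2) {
  if (tissue_area_um2 <= 0) stop("tissue area must be positive",
                                 call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    tab <- tibble(cluster = integer(0), row = numeric(0), col = numeric(0),
                  area_px = integer(0), area_um2 = numeric(0),
                  size_class = character(0))
  } else {
    idx <- which(labels > 0)
    lab <- labels[idx]
    rows <- (idx - 1) %% nrow(labels)        # 0-based
    cols <- (idx - 1) %/% nrow(labels)
    area <- as.integer(table(factor(lab, levels = ids)))
    tab <- tibble(
      cluster = ids,
      row = as.numeric(rowsum(rows, lab)) / area,
      col = as.numeric(rowsum(cols, lab)) / area,
      area_px = area,
      area_um2 = area * scheme$pixel_area_um2
    )
    tab$size_class <- with(scheme, dplyr::case_when(
      tab$area_px <= exclude_px ~ "excluded_small",
      tab$area_um2 > artifact_um2 ~ "excluded_artifact",
      tab$area_px <= small_max_px ~ "small",
      tab$area_px <= medium_max_px ~ "medium",
      TRUE ~ "large"
    ))
  }
  classes <- c("excluded_small", "small", "medium", "large",
               "excluded_artifact")
  counts <- setNames(
    vapply(classes, function(cl) sum(tab$size_class == cl), 0L), classes
  )
  total <- sum(counts[c("small", "medium", "large")])
  structure(
    list(table = tab,
         counts = tibble(size_class = classes, n = as.integer(counts)),
         total = total,
         density = tibble(
           size_class = c(classes[2:4], "total"),
           per_um2 = c(counts[c("small", "medium", "large")], total) /
             tissue_area_um2
         ),
         tissue_area_um2 = tissue_area_um2),
    class = "phenomap_clusters"
  )
}

#' @export
print.phenomap_clusters <- function(x, ...) {
  cat("<phenomap_clusters> total (after exclusions): ", x$total, "\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Cell density
#'
#' Manual counts normalized by the counting surface area.
#'
#' @param count number of cells, non-negative.
#' @param area surface area, positive (any consistent unit).
#' @return cells per unit area.
#' @export
cell_density <- function(count, area) {
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  count / area
}

#' Fraction of TH-positive neurons with an ApoE punctum
#'
#' @param n_th number of TH-positive neurons.
#' @param n_th_with_punctum TH-positive neurons with at least one punctum.
#' @return fraction in `[0, 1]`; NaN with a note when `n_th` is 0.
#' @export
apoe_colocalization <- function(n_th, n_th_with_punctum) {
  if (n_th_with_punctum > n_th) {
    stop("colocalized count exceeds TH count", call. = FALSE)
  }
  if (n_th == 0) {
    warning("no TH-positive neurons counted; fraction undefined",
            call. = FALSE)
    return(NaN)
  }
  n_th_with_punctum / n_th
}
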