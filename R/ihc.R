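#' Excess-red enhancement of a brightfield RGB image
#'
#' DAB (3,3'-diaminobenzidine) deposits are brown, i.e. red-rich relative to
#' the blue hematoxylin counterstain and the achromatic white background.
#' The enhancement computes, per pixel, `2*R - B - G` clamped to \[0, 255\],
#' which vanishes on any achromatic pixel and is large on DAB-stained ones.
#'
#' @param img RGB image array (`height x width x 3`, 8-bit scale).
#' @return Integer matrix on \[0, 255\] with the spatial shape of `img`.
#' @seealso [segment_cells()] which thresholds this channel.
#' @export
excess_red <- function(img) {
  img <- as_rgb_image(img)
  e <- 2L * img[, , 1] - img[, , 3] - img[, , 2]
  matrix(as.integer(clamp(e, 0L, 255L)), nrow(e), ncol(e))
}

# 256-bin histogram of an 8-bit grayscale matrix.
hist256 <- function(gray) {
  g <- as.integer(round(gray))
  if (min(g) < 0L || max(g) > 255L)
    stop_data("grayscale intensities must lie in [0, 255]")
  tabulate(g + 1L, nbins = 256L)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Selects the intensity level `t` that maximizes the sum of Shannon
#' entropies of the two normalized sub-histograms split at `t` (foreground
#' strictly above `t`), computed on the full 256-bin 8-bit histogram.
#' Empty bins contribute zero entropy; among tied maximizers the lowest
#' level is returned, so the result is deterministic.
#'
#' @param gray Grayscale matrix on \[0, 255\] with at least two distinct
#'   intensity values.
#' @return The threshold as a single integer level in 0--254; pixels with
#'   intensity `> t` are foreground.
#' @export
entropy_threshold <- function(gray) {
  h <- hist256(gray)
  if (sum(h > 0L) < 2L)
    stop_data("degenerate histogram: image has fewer than 2 distinct intensities")
  p <- h / sum(h)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)                 # P[t+1] = mass at levels <= t
  S <- cumsum(plogp)             # running sum of p*log(p)
  Stot <- S[256L]
  t_all <- 0:254
  P0 <- P[t_all + 1L]
  valid <- P0 > 0 & P0 < 1
  H_lo <- -S[t_all + 1L] / P0 + log(P0)
  H_hi <- -(Stot - S[t_all + 1L]) / (1 - P0) + log(1 - P0)
  psi <- ifelse(valid, H_lo + H_hi, -Inf)
  t_all[which.max(psi)]          # which.max returns the first (lowest) tie
}

#' Segment DAB-positive cells in an RGB section image
#'
#' Thresholds the excess-red channel at the maximum-entropy level, then
#' cleans the binary image with a morphological opening (disc structuring
#' element) followed by removal of 8-connected components smaller than
#' `min_object_area`, which eliminates staining specks and debris.
#'
#' A section with no DAB signal at all (constant-zero excess-red) is a valid
#' observation when tissue is present: such images yield an empty mask with
#' a warning rather than an error.
#'
#' @param img RGB image array.
#' @param min_object_area Minimum surviving component area in pixels
#'   (default 20).
#' @param opening_radius Radius of the disc structuring element in pixels
#'   (default 1; 0 skips the opening).
#' @return Logical cell mask with attribute `threshold` (the entropy
#'   threshold used, or `NA` for a blank section).
#' @export
segment_cells <- function(img, min_object_area = 20, opening_radius = 1) {
  img <- as_rgb_image(img)
  if (!is_count(min_object_area)) stop_config("min_object_area must be a count >= 0")
  if (!is_count(opening_radius)) stop_config("opening_radius must be a count >= 0")
  e <- excess_red(img)
  if (length(unique(as.vector(e))) < 2L) {
    if (all(e == 0L)) {
      tissue_mask(img)  # errors if there is no tissue either
      warning("no DAB signal detected; returning an empty cell mask")
      m <- matrix(FALSE, nrow(e), ncol(e))
      attr(m, "threshold") <- NA_integer_
      return(m)
    }
    stop_data("degenerate histogram: image has fewer than 2 distinct intensities")
  }
  t_star <- entropy_threshold(e)
  mask <- e > t_star
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  if (min_object_area > 0 && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    fg <- lab > 0L
    mask <- fg
    mask[fg] <- sizes[lab[fg]] >= min_object_area
  }
  attr(mask, "threshold") <- as.integer(t_star)
  mask
}

# Two-threshold (three-class) Otsu on a 256-bin histogram: maximizes the
# between-class variance over all (t1 < t2) pairs. Returns the thresholds
# and the mean intensity of each class.
otsu3 <- function(h) {
  p <- h / sum(h)
  i <- 0:255
  W <- cumsum(p); M <- cumsum(p * i)
  best <- -Inf; best_t <- c(NA, NA)
  for (t1 in 0:253) {
    w1 <- W[t1 + 1L]; m1 <- M[t1 + 1L]
    t2 <- (t1 + 1L):254L
    w2 <- W[t2 + 1L] - w1; m2 <- M[t2 + 1L] - m1
    w3 <- 1 - W[t2 + 1L]; m3 <- M[256L] - M[t2 + 1L]
    v <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; best_t <- c(t1, t2[k]) }
  }
  w1 <- W[best_t[1] + 1L]
  w2 <- W[best_t[2] + 1L] - w1
  w3 <- 1 - W[best_t[2] + 1L]
  m <- c(if (w1 > 0) M[best_t[1] + 1L] / w1 else NA,
         if (w2 > 0) (M[best_t[2] + 1L] - M[best_t[1] + 1L]) / w2 else NA,
         if (w3 > 0) (M[256L] - M[best_t[2] + 1L]) / w3 else NA)
  list(thresholds = best_t, class_means = m, class_weights = c(w1, w2, w3))
}

#' Segment the tissue section from the white slide background
#'
#' The hematoxylin-stained section is separated from the near-white
#' background by automatic thresholding of the blue channel: a three-class
#' Otsu partition is computed and every class whose mean blue intensity
#' reaches `white_cutoff` is taken as background (near-white pixels are
#' bright in all channels, including blue, while both hematoxylin- and
#' DAB-stained pixels are darker in blue). The remaining pixels form the
#' tissue mask, which is hole-filled so that pale interior structures
#' still count as section area. A frame fully covered by tissue has no
#' near-white class and maps to an all-true mask.
#'
#' @param img RGB image array.
#' @param white_cutoff Minimum mean blue intensity (0--255) for a class to
#'   be treated as background; default 225.
#' @return Logical tissue mask.
#' @export
tissue_mask <- function(img, white_cutoff = 225) {
  img <- as_rgb_image(img)
  blue <- img[, , 3]
  h <- hist256(blue)
  if (sum(h > 0L) < 2L)
    stop_data("degenerate histogram: constant blue channel")
  o <- otsu3(h)
  is_bg_class <- !is.na(o$class_means) & o$class_means >= white_cutoff
  present <- o$class_weights > 0
  if (all(is_bg_class[present]))
    stop_data("no tissue detected: all intensity classes are near-white")
  if (!any(is_bg_class)) {
    return(matrix(TRUE, nrow(blue), ncol(blue)))
  }
  # background = union of near-white classes; they occupy the top of the
  # blue range, so the lowest background class boundary separates tissue.
  cls <- findInterval(blue, c(o$thresholds[1] + 1L, o$thresholds[2] + 1L)) + 1L
  tissue <- matrix(!is_bg_class[cls], nrow(blue), ncol(blue))
  tissue <- EBImage::fillHull(tissue * 1) > 0.5
  tissue
}

#' Cell density of a section
#'
#' Cell density is the area occupied by segmented cells divided by the
#' total tissue area of the section, a dimensionless fraction. Only cell
#' pixels lying inside the tissue mask are counted.
#'
#' @param cells Logical cell mask.
#' @param tissue Logical tissue mask of identical shape with at least one
#'   foreground pixel.
#' @param threshold_used Optional intensity threshold to record alongside.
#' @return A `density_result`: list with `cell_area`, `tissue_area`,
#'   `density` and `threshold_used`.
#' @export
cell_density <- function(cells, tissue, threshold_used = NA_integer_) {
  assert_mask(cells, "cell mask"); assert_mask(tissue, "tissue mask")
  if (!identical(dim(cells), dim(tissue)))
    stop_data("cell and tissue masks must have identical shapes")
  tissue_area <- sum(tissue)
  if (tissue_area == 0L) stop_data("no tissue detected: empty tissue mask")
  cell_area <- sum(cells & tissue)
  structure(list(cell_area = cell_area, tissue_area = tissue_area,
                 density = cell_area / tissue_area,
                 threshold_used = threshold_used),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("cell density: %.4f (%d cell px / %d tissue px; threshold %s)\n",
              x$density, x$cell_area, x$tissue_area,
              ifelse(is.na(x$threshold_used), "-", x$threshold_used)))
  invisible(x)
}

#' Quantify DAB-positive cell density of one section image
#'
#' Runs the full per-image pipeline: tissue segmentation, cell segmentation
#' and density computation, with a physical-area conversion from the pixel
#' calibration.
#'
#' @inheritParams segment_cells
#' @param um_per_px Microns per pixel (square pixels assumed); default 0.46,
#'   a conventional 20x-scan calibration used when none is supplied.
#' @return A list with the `density_result`, both masks, and
#'   `tissue_area_mm2`.
#' @export
quantify_image <- function(img, min_object_area = 20, opening_radius = 1,
                           um_per_px = 0.46) {
  img <- as_rgb_image(img)
  if (!is_number(um_per_px) || um_per_px <= 0)
    stop_config("um_per_px must be a positive number")
  tissue <- tissue_mask(img)
  cells <- segment_cells(img, min_object_area, opening_radius)
  res <- cell_density(cells, tissue, attr(cells, "threshold"))
  list(density = res, cell_mask = cells, tissue_mask = tissue,
       tissue_area_mm2 = res$tissue_area * (um_per_px / 1000)^2)
}
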