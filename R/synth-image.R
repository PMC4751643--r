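#' Configuration for the synthetic IHC image generator
#'
#' Defines a simulated brightfield Ki-67 immunostain: DAB-brown positive
#' cells drawn as filled discs on a hematoxylin-blue tissue region, a
#' near-white slide background, and small staining-speck artifacts. All
#' colors are 8-bit per channel.
#'
#' @param width,height Frame size in pixels.
#' @param n_cells Number of DAB-positive cells to place.
#' @param cell_radius_range Two-element range of cell radii in pixels.
#' @param dab_color_mean,dab_color_std Mean and standard deviation of the
#'   per-channel DAB (brown) color; the mean must have red > blue.
#' @param tissue_color_mean,tissue_color_std Mean and standard deviation of
#'   the hematoxylin (blue) tissue color; the mean must have blue > red.
#' @param background_color Constant RGB of the unstained slide background.
#' @param n_artifacts Number of small specks to paint (not part of the
#'   ground-truth cell mask).
#' @param artifact_max_area Maximum speck area in pixels squared.
#' @param tissue_fraction Fraction of the frame covered by tissue, in (0, 1].
#' @param seed Integer seed; identical configurations with the same seed
#'   yield pixel-identical images.
#' @return An `image_gen_config` list.
#' @export
image_gen_config <- function(width = 256, height = 256, n_cells = 50,
                             cell_radius_range = c(4, 6),
                             dab_color_mean = c(150, 90, 60),
                             dab_color_std = c(12, 12, 12),
                             tissue_color_mean = c(140, 100, 170),
                             tissue_color_std = c(10, 10, 10),
                             background_color = c(245, 245, 245),
                             n_artifacts = 8, artifact_max_area = 12,
                             tissue_fraction = 0.85, seed = NULL) {
  cfg <- list(width = width, height = height, n_cells = n_cells,
              cell_radius_range = sort(cell_radius_range),
              dab_color_mean = dab_color_mean,
              dab_color_std = rep_len(dab_color_std, 3L),
              tissue_color_mean = tissue_color_mean,
              tissue_color_std = rep_len(tissue_color_std, 3L),
              background_color = background_color,
              n_artifacts = n_artifacts,
              artifact_max_area = artifact_max_area,
              tissue_fraction = tissue_fraction, seed = seed)
  validate_image_gen_config(cfg)
  structure(cfg, class = "image_gen_config")
}

validate_image_gen_config <- function(cfg) {
  ok_col <- function(x) is.numeric(x) && length(x) == 3L &&
    all(x >= 0 & x <= 255)
  if (!is_count(cfg$width, 8) || !is_count(cfg$height, 8))
    stop_config("width and height must be counts >= 8")
  if (!is_count(cfg$n_cells)) stop_config("n_cells must be a count >= 0")
  if (length(cfg$cell_radius_range) != 2L || any(cfg$cell_radius_range <= 0))
    stop_config("cell_radius_range must be two positive radii")
  if (!ok_col(cfg$dab_color_mean) || !ok_col(cfg$tissue_color_mean) ||
      !ok_col(cfg$background_color))
    stop_config("all color means must be 3-channel values in [0, 255]")
  if (cfg$dab_color_mean[1] <= cfg$dab_color_mean[3])
    stop_config("DAB color must have red > blue (brown chromogen)")
  if (cfg$tissue_color_mean[3] <= cfg$tissue_color_mean[1])
    stop_config("tissue color must have blue > red (hematoxylin)")
  if (any(cfg$dab_color_std < 0) || any(cfg$tissue_color_std < 0))
    stop_config("color standard deviations must be >= 0")
  if (!is_count(cfg$n_artifacts) || !is_count(cfg$artifact_max_area, 1))
    stop_config("n_artifacts must be a count and artifact_max_area >= 1")
  if (!is_number(cfg$tissue_fraction) ||
      cfg$tissue_fraction <= 0 || cfg$tissue_fraction > 1)
    stop_config("tissue_fraction must lie in (0, 1]")
  invisible(cfg)
}

# Elliptical tissue region centered in the frame, scaled (by bisection when
# the ellipse clips the frame) so its pixel area is close to
# tissue_fraction * width * height.
make_tissue_region <- function(height, width, fraction) {
  if (fraction >= 1) return(matrix(TRUE, height, width))
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  ellipse_area <- function(s) {
    a <- s * height / 2; b <- s * width / 2
    sum(((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1)
  }
  target <- fraction * height * width
  lo <- 0.05; hi <- 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ellipse_area(mid) < target) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  a <- s * height / 2; b <- s * width / 2
  ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
}

# Pixel indices of a filled disc clipped to the frame.
disc_pixels <- function(center_r, center_c, radius, height, width) {
  r0 <- max(1L, floor(center_r - radius)); r1 <- min(height, ceiling(center_r + radius))
  c0 <- max(1L, floor(center_c - radius)); c1 <- min(width, ceiling(center_c + radius))
  rs <- r0:r1; cs <- c0:c1
  rr <- rep(rs, times = length(cs)); cc <- rep(cs, each = length(rs))
  keep <- (rr - center_r)^2 + (cc - center_c)^2 <= radius^2
  cbind(rr[keep], cc[keep])
}

#' Generate a synthetic IHC section image with ground truth
#'
#' Paints the tissue region, places `n_cells` DAB-colored discs by rejection
#' sampling of centers inside the tissue (overlap between cells is allowed,
#' as in real sections; disc pixels falling outside the tissue are clipped),
#' then adds small DAB-colored specks that are excluded from the truth cell
#' mask. Per-pixel Gaussian color noise is added around the stain means and
#' clipped to \[0, 255\]; the background is a constant color.
#'
#' @param cfg An [image_gen_config()].
#' @return A list with `image` (RGB array) and `truth`, which carries
#'   `cell_mask`, `tissue_mask`, `cell_centers` (matrix of row/col) and
#'   `true_density` = cell pixels / tissue pixels.
#' @export
generate_ihc_image <- function(cfg) {
  if (!inherits(cfg, "image_gen_config")) cfg <- do.call(image_gen_config, cfg)
  validate_image_gen_config(cfg)
  h <- cfg$height; w <- cfg$width
  r_max <- cfg$cell_radius_range[2]
  tissue <- make_tissue_region(h, w, cfg$tissue_fraction)
  tissue_area <- sum(tissue)
  # deterministic pre-check: discs at the minimum radius must plausibly fit
  min_cell_area <- pi * cfg$cell_radius_range[1]^2
  if (cfg$n_cells * min_cell_area > 0.9 * tissue_area)
    stop_config("overcrowded configuration: %d cells of radius >= %.1f cannot fit in %d tissue pixels",
                cfg$n_cells, cfg$cell_radius_range[1], tissue_area)

  with_seed_if(cfg$seed, {
    img <- array(rep(cfg$background_color, each = h * w), dim = c(h, w, 3L))
    n_tis <- tissue_area
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissue] <- cfg$tissue_color_mean[ch] +
        stats::rnorm(n_tis, 0, cfg$tissue_color_std[ch])
      img[, , ch] <- plane
    }

    cell_mask <- matrix(FALSE, h, w)
    centers <- matrix(numeric(0), 0, 2)
    if (cfg$n_cells > 0) {
      tissue_idx <- which(tissue)
      radii <- stats::runif(cfg$n_cells, cfg$cell_radius_range[1], r_max)
      picks <- sample(tissue_idx, cfg$n_cells, replace = TRUE)
      centers <- cbind((picks - 1L) %% h + 1L, (picks - 1L) %/% h + 1L)
      for (k in seq_len(cfg$n_cells)) {
        px <- disc_pixels(centers[k, 1], centers[k, 2], radii[k], h, w)
        px <- px[tissue[px], , drop = FALSE]
        cell_mask[px] <- TRUE
      }
      n_cell_px <- sum(cell_mask)
      idx <- which(cell_mask)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- cfg$dab_color_mean[ch] +
          stats::rnorm(n_cell_px, 0, cfg$dab_color_std[ch])
        img[, , ch] <- plane
      }
    }

    if (cfg$n_artifacts > 0) {
      art_r <- sqrt(stats::runif(cfg$n_artifacts, 1, cfg$artifact_max_area) / pi)
      art_rc <- cbind(stats::runif(cfg$n_artifacts, 1, h),
                      stats::runif(cfg$n_artifacts, 1, w))
      for (k in seq_len(cfg$n_artifacts)) {
        px <- disc_pixels(art_rc[k, 1], art_rc[k, 2], art_r[k], h, w)
        if (nrow(px) == 0) next
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[px] <- cfg$dab_color_mean[ch] +
            stats::rnorm(nrow(px), 0, cfg$dab_color_std[ch])
          img[, , ch] <- plane
        }
      }
    }

    img <- array(as.integer(round(clamp(img, 0, 255))), dim = c(h, w, 3L))
    list(image = as_rgb_image(img),
         truth = list(cell_mask = cell_mask, tissue_mask = tissue,
                      cell_centers = centers,
                      true_density = sum(cell_mask) / tissue_area))
  })
}
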