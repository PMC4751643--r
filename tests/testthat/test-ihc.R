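test_that("excess red is 2R - B - G clamped to [0, 255]", {
  img <- flat_rgb(2, 2, c(100, 100, 100))
  img[1, 1, ] <- c(255, 0, 0)    # clamps at 255 (raw 510)
  img[1, 2, ] <- c(150, 60, 40)  # 300 - 40 - 60 = 200
  img[2, 1, ] <- c(10, 200, 200) # negative, clamps at 0
  e <- excess_red(img)
  expect_equal(e[1, 1], 255L)
  expect_equal(e[1, 2], 200L)
  expect_equal(e[2, 1], 0L)
  expect_equal(e[2, 2], 0L)      # achromatic pixel
})

test_that("excess red vanishes on any achromatic image and stays in range", {
  for (v in c(0L, 17L, 128L, 255L)) {
    expect_true(all(excess_red(flat_rgb(4, 4, c(v, v, v))) == 0L))
  }
  set.seed(11)
  img <- array(sample(0:255, 3 * 20 * 20, TRUE), dim = c(20, 20, 3))
  e <- excess_red(img)
  expect_true(all(e >= 0 & e <= 255))
  expect_error(excess_red(array(0L, c(4, 4, 2))), "RGB")
})

test_that("entropy threshold matches the exhaustive Kapur criterion scan", {
  two_level <- matrix(c(rep(40, 50), rep(200, 50)), 10, 10)
  expect_equal(entropy_threshold(two_level), oracle_entropy_threshold(two_level))
  set.seed(21)
  for (i in 1:25) {
    g <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_equal(entropy_threshold(g), oracle_entropy_threshold(g))
    # bimodal image closer to real stain histograms
    b <- matrix(round(pmin(pmax(c(rnorm(128, 60, 15), rnorm(128, 190, 20)), 0), 255)),
                16, 16)
    expect_equal(entropy_threshold(b), oracle_entropy_threshold(b))
  }
})

test_that("entropy threshold separates a two-valued image and rejects a constant one", {
  two_level <- matrix(c(rep(40, 50), rep(200, 50)), 10, 10)
  t_star <- entropy_threshold(two_level)
  expect_true(t_star >= 40 && t_star < 200)
  expect_error(entropy_threshold(matrix(7, 5, 5)), "degenerate histogram")
})

test_that("8-connected labeling agrees with a flood-fill oracle", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    lab <- label_components(m)
    oracle <- oracle_component_count(m)
    expect_equal(max(lab), oracle$n)
    # identical partition: labels must be a relabeling of the oracle's
    expect_equal(lab > 0, m)
    key <- paste(lab[m], oracle$labels[m])
    expect_equal(length(unique(key)), oracle$n)
  }
  # diagonal touch is one component under 8-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(max(label_components(d)), 1L)
})

test_that("segmentation keeps the cell and drops sub-threshold specks", {
  tissue_col <- c(110, 110, 180); dab <- c(140, 80, 50)
  img <- flat_rgb(64, 64, tissue_col)
  img <- paint_disc(img, 32, 32, 5.5, dab)            # ~100 px cell
  speck_at <- cbind(c(8, 8, 55, 55, 30), c(8, 55, 8, 55, 5))
  for (k in 1:5) img <- paint_disc(img, speck_at[k, 1], speck_at[k, 2], 0.9, dab) # ~3 px
  mask <- segment_cells(img, min_object_area = 10, opening_radius = 0)
  expect_equal(oracle_component_count(mask)$n, 1L)
  expect_true(mask[32, 32])
  # no surviving component smaller than min_object_area
  lab <- label_components(mask)
  expect_true(all(tabulate(lab[lab > 0]) >= 10))
})

test_that("cleanup leaves no component below min_object_area on noisy images", {
  set.seed(41)
  for (i in 1:5) {
    g <- generate_ihc_image(image_gen_config(width = 96, height = 96,
                                             n_cells = 8, seed = 100 + i))
    m <- segment_cells(g$image, min_object_area = 20, opening_radius = 1)
    lab <- label_components(m)
    if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 20))
  }
})

test_that("a section without DAB signal yields an empty mask with a warning", {
  img <- flat_rgb(32, 32, c(110, 110, 180))
  img[1:8, 1:32, ] <- rep(c(245, 245, 246), each = 8 * 32)  # background band
  expect_warning(m <- segment_cells(img), "empty cell mask")
  expect_false(any(m))
  expect_true(is.na(attr(m, "threshold")))
})

test_that("tissue mask recovers a blue disc on white and errors on blank input", {
  img <- flat_rgb(64, 64, c(246, 246, 246))
  img <- paint_disc(img, 32, 32, 20, c(110, 110, 180))
  truth <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 32)^2 <= 400)
  m <- tissue_mask(img)
  expect_gt(jaccard(m, truth), 0.98)
  expect_error(tissue_mask(flat_rgb(16, 16, c(255, 255, 255))),
               "degenerate histogram")
  noisy_white <- flat_rgb(32, 32, c(250, 250, 250))
  noisy_white[, , 3] <- 250L + matrix(sample(0:4, 32 * 32, TRUE), 32, 32)
  expect_error(tissue_mask(noisy_white), "no tissue")
})

test_that("tissue mask recovers truth area on generated frames, full coverage included", {
  for (frac in c(0.7, 1)) {
    g <- generate_ihc_image(image_gen_config(width = 128, height = 128,
                                             n_cells = 20, tissue_fraction = frac,
                                             seed = 55))
    m <- tissue_mask(g$image)
    expect_lt(abs(sum(m) - sum(g$truth$tissue_mask)) / sum(g$truth$tissue_mask),
              0.05)
  }
})

test_that("cell density is the in-tissue cell fraction with guarded edge cases", {
  tissue <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(cell_density(none, tissue)$density, 0)
  expect_equal(cell_density(tissue, tissue)$density, 1)
  cells <- none; cells[1:5, 1:4] <- TRUE
  expect_equal(cell_density(cells, tissue)$density, 0.2)
  # cell pixels outside tissue are not counted
  half <- matrix(rep(c(TRUE, FALSE), each = 50), 10, 10)
  expect_equal(cell_density(tissue, half)$density, 1)
  expect_error(cell_density(cells, none), "no tissue")
  expect_error(cell_density(cells, matrix(TRUE, 5, 5)), "identical shapes")
})

test_that("density is invariant under 2x nearest-neighbour upscaling", {
  set.seed(61)
  cells <- matrix(runif(64) < 0.2, 8, 8)
  tissue <- matrix(runif(64) < 0.8, 8, 8) | cells
  up <- function(m) m[rep(1:8, each = 2), rep(1:8, each = 2)]
  expect_equal(cell_density(up(cells), up(tissue))$density,
               cell_density(cells, tissue)$density)
})

test_that("adding DAB pixels inside tissue never decreases pipeline density", {
  base <- generate_ihc_image(image_gen_config(width = 96, height = 96,
                                              n_cells = 10, n_artifacts = 0,
                                              seed = 71))
  img <- base$image
  d0 <- quantify_image(img)$density$density
  # paint two extra cells whose discs lie fully inside the tissue region
  ctr <- which(base$truth$tissue_mask & !base$truth$cell_mask, arr.ind = TRUE)
  fully_inside <- function(p) {
    px <- expand.grid(i = (p[1] - 5):(p[1] + 5), j = (p[2] - 5):(p[2] + 5))
    px <- px[(px$i - p[1])^2 + (px$j - p[2])^2 <= 25, ]
    all(px$i >= 1 & px$i <= 96 & px$j >= 1 & px$j <= 96) &&
      all(base$truth$tissue_mask[as.matrix(px)])
  }
  ok <- ctr[apply(ctr, 1, fully_inside), , drop = FALSE]
  for (k in c(1, nrow(ok) %/% 2)) img <- paint_disc(img, ok[k, 1], ok[k, 2], 5, c(140, 80, 50))
  d1 <- quantify_image(img)$density$density
  expect_gte(d1, d0)
})
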