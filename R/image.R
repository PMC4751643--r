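#' Image containers and I/O
#'
#' Images are plain base-R arrays on the 8-bit scale: an RGB image is an
#' integer array of dimension `height x width x 3` with values in 0--255;
#' a grayscale image is an `height x width` matrix on the same scale; a
#' binary mask is a logical matrix. [as_rgb_image()] validates and coerces;
#' [read_rgb_image()] / [write_rgb_image()] go through 8-bit PNG, and
#' [write_mask()] / [read_mask()] store masks as 0/255 single-channel PNG.
#'
#' @param x An array, matrix or file path as appropriate.
#' @name image-io
NULL

#' @rdname image-io
#' @return `as_rgb_image()`: an integer `h x w x 3` array.
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_data("an RGB image must be a height x width x 3 array")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop_data("RGB intensities must lie in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

assert_mask <- function(x, name = "mask") {
  if (!is.matrix(x) || !is.logical(x) || anyNA(x))
    stop_data("%s must be a logical matrix without NAs", name)
  invisible(x)
}

#' @rdname image-io
#' @param path File path of an 8-bit PNG.
#' @export
read_rgb_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  as_rgb_image(round(px * 255))
}

#' @rdname image-io
#' @param img An RGB image array.
#' @export
write_rgb_image <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname image-io
#' @param mask A logical matrix.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname image-io
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' Label connected components (8-connectivity)
#'
#' Two-pass union-find labeling of a binary mask under 8-connectivity
#' (pixels touching by an edge or a corner belong to one component).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  assert_mask(mask)
  .label8_cpp(mask)
}
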