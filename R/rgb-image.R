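#' 8-bit RGB image arrays
#'
#' Throughout the package an RGB image is a plain `H x W x 3` array of
#' integers in `[0, 255]` (8 bits per channel, origin at the top-left,
#' row-major). These helpers validate, construct and read/write such
#' arrays. PNG is used for all lossless on-disk fixtures.
#'
#' @param x object to check or coerce.
#' @return `as_rgb_image()` returns an integer-valued `H x W x 3` array.
#' @name rgb_image
NULL

#' @rdname rgb_image
#' @export
is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    is.numeric(x) && !anyNA(x) &&
    min(x) >= 0 && max(x) <= 255 && all(x == floor(x))
}

#' @rdname rgb_image
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == 3L)
  x <- round_half_up(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# Deterministic half-away-from-zero rounding (base round() is half-to-even);
# fixed so pixel arithmetic is bit-reproducible across platforms.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

assert_rgb_image <- function(x, what = "image") {
  if (!is_rgb_image(x)) {
    stop(what, " must be an 8-bit RGB array (H x W x 3, integers in [0,255])",
         call. = FALSE)
  }
  invisible(x)
}

#' Read and write 8-bit RGB PNG images
#'
#' Thin wrappers around the \pkg{png} package converting between its
#' `[0, 1]` float convention and the package's 8-bit integer arrays.
#'
#' @param path file path.
#' @param image an 8-bit RGB array.
#' @return `read_image_png()` returns an RGB array; `write_image_png()`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  as_rgb_image(a * 255)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Convert an RGB image to 8-bit luminance grayscale
#'
#' Uses the ITU-R BT.601 weights `0.2989 R + 0.5870 G + 0.1140 B`,
#' rounded to the nearest 8-bit level.
#'
#' @param image an 8-bit RGB array.
#' @return integer matrix of gray levels in `[0, 255]`.
#' @export
rgb_to_gray <- function(image) {
  assert_rgb_image(image)
  g <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  g <- matrix(round_half_up(g), dim(image)[1], dim(image)[2])
  storage.mode(g) <- "integer"
  g
}
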