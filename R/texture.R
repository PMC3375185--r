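#' Rotation-invariant LBP + local variance texture features
#'
#' The texture descriptor behind the epithelium/stroma classifier: for
#' each pixel, `P` neighbors are sampled (bilinear interpolation) on a
#' circle of radius `R` and thresholded by the centre value to a binary
#' pattern. Uniform patterns (at most two 0/1 transitions around the
#' circle) are mapped to their bit count `0..P`, all non-uniform
#' patterns to one code `P + 1`, giving `P + 2` rotation-invariant
#' codes (the "riu2" mapping). The rotation-invariant local variance
#' (VAR) of the same `P` samples carries the contrast information LBP
#' discards; it is quantized into `Q` equal-occupancy bins learned from
#' training images, and the joint `(P + 2) x Q` histogram of the two
#' operators describes an element.
#'
#' @name texture_features
NULL

# Compute riu2 LBP codes and local variance in one pass over the sample
# stack. Neighbor 0 sits at (0, +R) and samples proceed counter-clockwise;
# the origin choice does not affect riu2/VAR outputs but is fixed for
# reproducibility. Returns full-size matrices with an NA border of width
# ceiling(R) where the circular neighborhood is incomplete.
lbp_var <- function(gray, P, R) {
  stopifnot(is.matrix(gray), P >= 4, R > 0)
  b <- ceiling(R)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 2 * b + 1 || w < 2 * b + 1) {
    stop("image smaller than the ", 2 * b + 1, "x", 2 * b + 1,
         " neighborhood", call. = FALSE)
  }
  g <- gray
  storage.mode(g) <- "double"
  ri <- (b + 1):(h - b)
  ci <- (b + 1):(w - b)
  centre <- g[ri, ci]
  shift <- function(sy, sx) g[ri + sy, ci + sx]
  eps <- 1e-9
  sum_bits <- matrix(0, length(ri), length(ci))
  trans <- matrix(0, length(ri), length(ci))
  s1 <- matrix(0, length(ri), length(ci))
  s2 <- matrix(0, length(ri), length(ci))
  first_bits <- NULL
  prev_bits <- NULL
  for (k in 0:(P - 1)) {
    a <- 2 * pi * k / P
    dx <- R * cos(a)
    dy <- -R * sin(a)         # row axis points down; CCW in image terms
    if (abs(dx - round(dx)) < eps) dx <- round(dx)
    if (abs(dy - round(dy)) < eps) dy <- round(dy)
    y0 <- floor(dy); fy <- dy - y0
    x0 <- floor(dx); fx <- dx - x0
    nb <- (1 - fy) * (1 - fx) * shift(y0, x0)
    if (fx > 0) nb <- nb + (1 - fy) * fx * shift(y0, x0 + 1)
    if (fy > 0) nb <- nb + fy * (1 - fx) * shift(y0 + 1, x0)
    if (fx > 0 && fy > 0) nb <- nb + fy * fx * shift(y0 + 1, x0 + 1)
    # ties count as >=; the 1e-6 guard keeps bilinear interpolation of equal
    # neighbours (weights summing to 1 up to fp error) on the tie side
    bits <- nb >= centre - 1e-6
    sum_bits <- sum_bits + bits
    if (is.null(first_bits)) first_bits <- bits else trans <- trans + (bits != prev_bits)
    prev_bits <- bits
    s1 <- s1 + nb
    s2 <- s2 + nb * nb
  }
  trans <- trans + (prev_bits != first_bits)    # close the circle
  code <- ifelse(trans <= 2, sum_bits, P + 1)
  v <- s2 / P - (s1 / P)^2
  v[v < 0] <- 0                                  # numerical guard
  code_full <- matrix(NA_integer_, h, w)
  var_full <- matrix(NA_real_, h, w)
  code_full[ri, ci] <- as.integer(code)
  var_full[ri, ci] <- v
  list(code = code_full, var = var_full)
}

#' @rdname texture_features
#' @param gray integer or numeric grayscale matrix.
#' @param P number of circular samples (8 or 16 in the default
#'   configuration).
#' @param R circle radius in pixels (1 or 2 by default).
#' @return `lbp_riu2()`: integer matrix of codes in `0..P+1` with an NA
#'   border of width `ceiling(R)`; `var_local()`: numeric matrix of
#'   population variances (`1/P` normalization) with the same border.
#' @export
lbp_riu2 <- function(gray, P = 8, R = 1) lbp_var(gray, P, R)$code

#' @rdname texture_features
#' @export
var_local <- function(gray, P = 8, R = 1) lbp_var(gray, P, R)$var

#' Learn an equal-occupancy variance quantizer
#'
#' Pools VAR values over (the tissue pixels of) a set of training
#' images and places the `Q - 1` cut points at the `k/Q` quantiles, so
#' each of the `Q` bins holds an equal share of training pixels. Bins
#' are right-open `[cut_(k-1), cut_k)`, the last unbounded.
#'
#' @param gray_images list of grayscale matrices.
#' @param P,R circular neighborhood used for VAR.
#' @param Q number of quantization levels (>= 2).
#' @param tissue_masks optional list of logical matrices restricting
#'   which pixels are pooled.
#' @return object of class `var_quantizer` with strictly ascending
#'   `cut_points`.
#' @export
train_var_quantizer <- function(gray_images, P = 8, R = 1, Q = 8,
                                tissue_masks = NULL) {
  stopifnot(length(gray_images) >= 1, Q >= 2)
  pool <- unlist(lapply(seq_along(gray_images), function(i) {
    v <- lbp_var(gray_images[[i]], P, R)$var
    keep <- !is.na(v)
    if (!is.null(tissue_masks)) keep <- keep & tissue_masks[[i]]
    v[keep]
  }))
  if (length(pool) == 0) stop("no pixels to train the quantizer on", call. = FALSE)
  cuts <- stats::quantile(pool, probs = seq_len(Q - 1) / Q, type = 7,
                          names = FALSE)
  if (any(diff(cuts) <= 0) || any(!is.finite(cuts))) {
    stop("degenerate variance distribution: duplicate quantiles ",
         "(all-constant training images?)", call. = FALSE)
  }
  structure(list(cut_points = cuts, Q = as.integer(Q),
                 P = as.integer(P), R = R),
            class = "var_quantizer")
}

#' Quantize variance values into equal-occupancy bins
#'
#' @param quantizer a [train_var_quantizer()] object.
#' @param v numeric vector/matrix of non-negative variances.
#' @return integer bin indices in `0 .. Q-1` (same shape as `v`).
#' @export
quantize_var <- function(quantizer, v) {
  stopifnot(inherits(quantizer, "var_quantizer"))
  out <- findInterval(v, quantizer$cut_points)
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

# The two feature scales: LBP/VAR at (P=8, R=1) and (P=16, R=2).
texture_scales <- function() list(list(P = 8L, R = 1),
                                  list(P = 16L, R = 2))

#' Train the VAR quantizers for both feature scales
#'
#' @inheritParams train_var_quantizer
#' @return object of class `texture_quantizers` (one `var_quantizer`
#'   per scale).
#' @export
train_texture_quantizers <- function(gray_images, Q = 8, tissue_masks = NULL) {
  qs <- lapply(texture_scales(), function(s) {
    train_var_quantizer(gray_images, P = s$P, R = s$R, Q = Q,
                        tissue_masks = tissue_masks)
  })
  names(qs) <- vapply(texture_scales(),
                      function(s) sprintf("P%dR%g", s$P, s$R), "")
  structure(qs, class = "texture_quantizers")
}

#' Compute the 224-bin LBP/VAR feature of one image element
#'
#' For each scale, the joint `(P + 2) x Q` histogram of (LBP code, VAR
#' bin) is accumulated over all pixels with a complete neighborhood and
#' flattened LBP-major; the two blocks (`(8+2)*8 + (16+2)*8 = 224`
#' bins) are concatenated and the Euclidean norm of the vector is
#' normalized to one.
#'
#' @param gray_element grayscale matrix, nominally the 80 x 80 sliding
#'   window.
#' @param quantizers a [train_texture_quantizers()] object.
#' @param normalize set FALSE to return raw joint-histogram counts
#'   (each scale's block then sums to its number of valid pixels).
#' @return numeric vector of length 224.
#' @export
extract_element_feature <- function(gray_element, quantizers, normalize = TRUE) {
  stopifnot(inherits(quantizers, "texture_quantizers"))
  blocks <- lapply(seq_along(texture_scales()), function(i) {
    s <- texture_scales()[[i]]
    q <- quantizers[[i]]
    lv <- lbp_var(gray_element, s$P, s$R)
    valid <- !is.na(lv$code)
    if (!any(valid)) stop("element has no valid pixels", call. = FALSE)
    codes <- lv$code[valid]
    bins <- quantize_var(q, lv$var[valid])
    idx <- codes * q$Q + bins + 1L               # LBP-major flattening
    tabulate(idx, nbins = (s$P + 2L) * q$Q)
  })
  v <- as.numeric(unlist(blocks))
  if (normalize) {
    n2 <- sqrt(sum(v^2))
    if (n2 == 0) stop("all-zero feature vector", call. = FALSE)
    v <- v / n2
  }
  v
}

#' Preprocess an RGB image for texture classification
#'
#' The image is scaled by a constant 0.5 (box filter), converted to
#' grayscale with the `0.2989 R + 0.5870 G + 0.1140 B` weights, and a
#' tissue mask is built by thresholding away the bright background and
#' smoothing the mask morphologically (closing, then erosion, with a
#' disc structuring element).
#'
#' @param image 8-bit RGB array.
#' @param background_threshold gray level above which a pixel counts as
#'   empty glass (default 240).
#' @param morph_radius disc radius in pixels for closing/erosion
#'   (default 5).
#' @return list with `gray` (integer matrix, half scale) and
#'   `tissue_mask` (logical matrix, TRUE = tissue).
#' @export
preprocess_texture <- function(image, background_threshold = 240,
                               morph_radius = 5) {
  assert_rgb_image(image)
  half <- downscale(image, scaling_spec(2))
  gray <- rgb_to_gray(half)
  tissue <- (gray <= background_threshold) * 1
  if (any(tissue > 0) && morph_radius > 0) {
    brush <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
    tissue <- EBImage::closing(tissue, brush)
    tissue <- EBImage::erode(tissue, brush)
    tissue <- EBImage::imageData(tissue)
  }
  list(gray = gray, tissue_mask = tissue > 0)
}

#' Enumerate 80 x 80 sliding-window elements over a tissue mask
#'
#' Windows slide row by row from the upper-left corner in steps of 40
#' pixels (50% overlap); a window is kept only if at least half of its
#' area is tissue. Trailing pixels that do not fill a whole window are
#' not covered.
#'
#' @param gray grayscale matrix (half-scale image).
#' @param tissue_mask logical matrix from [preprocess_texture()].
#' @param window,step window side and stride in pixels.
#' @param min_tissue minimum tissue fraction for a window to be kept.
#' @return data.frame with columns `row`, `col` (1-based top-left
#'   corners) in row-major order; zero rows (with attribute
#'   `too_small = TRUE` when the image cannot hold one window).
#' @export
enumerate_elements <- function(gray, tissue_mask, window = 80L, step = 40L,
                               min_tissue = 0.5) {
  stopifnot(identical(dim(gray), dim(tissue_mask)))
  h <- nrow(gray); w <- ncol(gray)
  empty <- data.frame(row = integer(0), col = integer(0))
  if (h < window || w < window) {
    attr(empty, "too_small") <- TRUE
    return(empty)
  }
  r0 <- seq(1L, h - window + 1L, by = step)
  c0 <- seq(1L, w - window + 1L, by = step)
  rows <- integer(0); cols <- integer(0)
  for (r in r0) {
    for (cc in c0) {
      cov <- mean(tissue_mask[r:(r + window - 1L), cc:(cc + window - 1L)])
      if (cov >= min_tissue) {
        rows <- c(rows, r); cols <- c(cols, cc)
      }
    }
  }
  data.frame(row = rows, col = cols)
}

#' LBP/VAR features of all elements of one image
#'
#' @param image 8-bit RGB array.
#' @param quantizers a [train_texture_quantizers()] object.
#' @param background_threshold,morph_radius passed to
#'   [preprocess_texture()].
#' @return numeric matrix (elements x 224); zero rows when no element
#'   qualifies.
#' @export
image_texture_features <- function(image, quantizers,
                                   background_threshold = 240,
                                   morph_radius = 5) {
  pp <- preprocess_texture(image, background_threshold, morph_radius)
  els <- enumerate_elements(pp$gray, pp$tissue_mask)
  if (nrow(els) == 0) return(matrix(numeric(0), 0, 224))
  feats <- t(vapply(seq_len(nrow(els)), function(i) {
    el <- pp$gray[els$row[i]:(els$row[i] + 79L),
                  els$col[i]:(els$col[i] + 79L)]
    extract_element_feature(el, quantizers)
  }, numeric(224)))
  feats
}
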