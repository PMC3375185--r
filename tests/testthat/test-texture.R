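test_that("grayscale conversion uses the standard luminance weights", {
  red <- as_rgb_image(array(rep(c(255L, 0L, 0L), each = 4), dim = c(2, 2, 3)))
  expect_equal(rgb_to_gray(red)[1, 1], 76L)   # round(0.2989 * 255)
  g <- as_rgb_image(array(rep(c(0L, 255L, 0L), each = 4), dim = c(2, 2, 3)))
  expect_equal(rgb_to_gray(g)[1, 1], as.integer(round(0.5870 * 255)))
})

test_that("preprocessing halves the image and removes bright background", {
  img <- small_texture("epithelium")$image
  big <- as_rgb_image(array(200L, dim = c(400, 400, 3)))
  expect_identical(dim(preprocess_texture(big)$gray), c(200L, 200L))
  white <- as_rgb_image(array(255L, dim = c(200, 200, 3)))
  expect_false(any(preprocess_texture(white)$tissue_mask))
  pp <- preprocess_texture(img)
  expect_gt(mean(pp$tissue_mask), 0.9)        # synthetic scenes are all tissue
})

test_that("riu2 codes follow the uniform-pattern contract", {
  const <- matrix(100L, 7, 7)
  expect_equal(lbp_riu2(const, 8, 1)[4, 4], 8)   # ties count as >=, all ones
  expect_equal(lbp_riu2(const, 16, 2)[4, 4], 16)

  spot <- matrix(10L, 5, 5); spot[3, 3] <- 200L
  expect_equal(lbp_riu2(spot, 8, 1)[3, 3], 0)    # all neighbors below centre

  set.seed(201)
  g <- matrix(sample(0:255, 50 * 50, TRUE), 50, 50)
  codes8 <- lbp_riu2(g, 8, 1)
  expect_lte(length(unique(stats::na.omit(as.vector(codes8)))), 10)
  expect_true(all(stats::na.omit(as.vector(codes8)) %in% 0:9))
  codes16 <- lbp_riu2(g, 16, 2)
  expect_lte(length(unique(stats::na.omit(as.vector(codes16)))), 18)
  # NA border of width ceiling(R)
  expect_true(all(is.na(codes16[1:2, ])))
  expect_error(lbp_riu2(matrix(0, 2, 2), 8, 1), "smaller")
})

test_that("local variance matches the population formula and is rotation-blind", {
  const <- matrix(55L, 7, 7)
  expect_true(all(stats::na.omit(as.vector(var_local(const, 8, 1))) == 0))

  # P = 4 samples sit on integer offsets: neighbors {255, 0, 255, 0}
  g <- matrix(0, 3, 3); g[2, 1] <- 255; g[2, 3] <- 255
  expect_equal(var_local(g, 4, 1)[2, 2], 127.5^2)  # 16256.25

  # rotating the image by 90 degrees rotates the VAR map (P = 8 circle is
  # 90-degree symmetric, so values are preserved exactly)
  set.seed(202)
  m <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
  rot90 <- function(x) t(x)[, nrow(x):1]
  v1 <- var_local(m, 8, 1)
  v2 <- var_local(rot90(m), 8, 1)
  expect_lt(max(abs(v2 - rot90(v1)), na.rm = TRUE), 1e-9)
})

test_that("starting angle of the circular sampling does not change VAR", {
  # independent brute-force sampler with an arbitrary first-sample angle
  bilinear <- function(g, y, x) {
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    v <- (1 - fy) * (1 - fx) * g[y0, x0]
    if (fx > 0) v <- v + (1 - fy) * fx * g[y0, x0 + 1]
    if (fy > 0) v <- v + fy * (1 - fx) * g[y0 + 1, x0]
    if (fx > 0 && fy > 0) v <- v + fy * fx * g[y0 + 1, x0 + 1]
    v
  }
  var_at <- function(g, cy, cx, P, R, k0) {
    s <- vapply(0:(P - 1), function(k) {
      a <- 2 * pi * (k + k0) / P
      bilinear(g, cy - R * sin(a), cx + R * cos(a))
    }, 0)
    mean(s^2) - mean(s)^2
  }
  set.seed(203)
  g <- matrix(sample(0:255, 9 * 9, TRUE), 9, 9)
  for (k0 in c(1, 3, 5)) {
    expect_equal(var_at(g, 5, 5, 8, 1, k0), var_at(g, 5, 5, 8, 1, 0),
                 tolerance = 1e-12)
  }
  # and the package value matches the independent sampler at origin 0
  expect_equal(var_local(g, 8, 1)[5, 5], var_at(g, 5, 5, 8, 1, 0),
               tolerance = 1e-12)
})

test_that("LBP and VAR are invariant to constant gray shifts", {
  set.seed(204)
  g <- matrix(sample(0:180, 40 * 40, TRUE), 40, 40)
  for (P in c(8, 16)) {
    R <- if (P == 8) 1 else 2
    expect_identical(lbp_riu2(g, P, R), lbp_riu2(g + 60L, P, R))
    expect_lt(max(abs(var_local(g, P, R) - var_local(g + 60L, P, R)),
                  na.rm = TRUE), 1e-9)
  }
})

test_that("the variance quantizer equalizes bin occupancy on its training pool", {
  set.seed(205)
  g <- matrix(sample(0:255, 120 * 120, TRUE), 120, 120)
  q <- train_var_quantizer(list(g), P = 8, R = 1, Q = 8)
  expect_length(q$cut_points, 7)
  expect_true(all(diff(q$cut_points) > 0))
  pool <- stats::na.omit(as.vector(var_local(g, 8, 1)))
  occ <- tabulate(quantize_var(q, pool) + 1L, nbins = 8)
  expect_lt(max(abs(occ - length(pool) / 8)) / (length(pool) / 8), 0.05)

  q2 <- train_var_quantizer(list(g), P = 8, R = 1, Q = 2)
  expect_equal(q2$cut_points, stats::quantile(pool, 0.5, names = FALSE),
               tolerance = 1e-9)

  expect_error(train_var_quantizer(list(matrix(7L, 50, 50)), 8, 1, 8),
               "degenerate")
})

test_that("element features have the documented geometry", {
  qs <- small_quantizers()
  set.seed(206)
  el <- matrix(sample(0:255, 80 * 80, TRUE), 80, 80)
  f <- extract_element_feature(el, qs)
  expect_length(f, 224)
  expect_equal(sqrt(sum(f^2)), 1, tolerance = 1e-9)

  raw <- extract_element_feature(el, qs, normalize = FALSE)
  expect_equal(sum(raw[1:80]), 78 * 78)    # scale 1: valid pixels (border 1)
  expect_equal(sum(raw[81:224]), 76 * 76)  # scale 2: valid pixels (border 2)

  # constant element: all mass at (code P, var bin 0) in each block; the
  # blocks hold 78^2 and 76^2 valid pixels (borders 1 and 2)
  fc <- extract_element_feature(matrix(50L, 80, 80), qs)
  nrm <- sqrt((78^2)^2 + (76^2)^2)
  expect_equal(fc[8 * 8 + 1], 78^2 / nrm, tolerance = 1e-12)
  expect_equal(fc[80 + 16 * 8 + 1], 76^2 / nrm, tolerance = 1e-12)
  expect_equal(sum(fc != 0), 2)
})

test_that("element enumeration follows the 80/40 sliding-window geometry", {
  g <- matrix(100L, 168, 168)
  full <- matrix(TRUE, 168, 168)
  els <- enumerate_elements(g, full)
  expect_equal(nrow(els), 9)              # 3 positions per axis
  expect_equal(els$row[1:3], c(1L, 1L, 1L))  # row-major from top-left
  expect_equal(els$col[1:3], c(1L, 41L, 81L))

  none <- enumerate_elements(g, !full)
  expect_equal(nrow(none), 0)

  # a window at exactly 50% tissue is kept; just below is dropped
  half <- matrix(FALSE, 80, 80); half[1:40, ] <- TRUE
  expect_equal(nrow(enumerate_elements(matrix(0L, 80, 80), half)), 1)
  half[40, 80] <- FALSE
  expect_equal(nrow(enumerate_elements(matrix(0L, 80, 80), half)), 0)

  small <- enumerate_elements(matrix(0L, 60, 60), matrix(TRUE, 60, 60))
  expect_equal(nrow(small), 0)
  expect_true(isTRUE(attr(small, "too_small")))
})
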