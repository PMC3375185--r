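test_that("stain matrix is unit-norm and invertible", {
  V <- hdab_stain_vectors()
  expect_equal(unname(sqrt(rowSums(V^2))), c(1, 1, 1))
  expect_gt(abs(det(V)), 0.1)
})

test_that("deconvolution inverts the Beer-Lambert forward model", {
  V <- hdab_stain_vectors()
  # pure white: zero optical density in every stain
  white <- as_rgb_image(array(255L, dim = c(4, 4, 3)))
  ch <- color_deconvolve(white, V)
  expect_true(all(ch$h_channel == 255L))
  expect_true(all(ch$dab_channel == 255L))

  # exact forward pixel at H concentration 0.5 (float image, no rounding)
  img <- array(0, dim = c(2, 2, 3))
  for (k in 1:3) img[, , k] <- 255 * 10^(-0.5 * V["haematoxylin", k])
  conc <- histodegrade:::deconvolve_concentrations(img, V)
  expect_lt(max(abs(conc$haematoxylin - 0.5)), 1e-6)
  expect_lt(max(abs(conc$dab)), 1e-6)

  expect_error(color_deconvolve(white, matrix(1, 3, 3)), "singular")
})

test_that("thresholding counts pixels below the level", {
  ch <- list(h_channel = matrix(250L, 40, 40), dab_channel = matrix(250L, 40, 40))
  ch$dab_channel[1:100] <- 10L
  m <- threshold_masks(ch, threshold_config(128, 128))
  expect_equal(sum(m$dab_mask), 100)
  expect_equal(sum(m$h_mask), 0)
  m0 <- threshold_masks(ch, threshold_config(0, 0))
  expect_false(any(m0$h_mask) || any(m0$dab_mask))
  dark <- list(h_channel = matrix(0L, 4, 4), dab_channel = matrix(0L, 4, 4))
  m1 <- threshold_masks(dark, threshold_config(255, 255))
  expect_true(all(m1$h_mask) && all(m1$dab_mask))
})

test_that("pseudocolour merge paints red over green over white", {
  h <- matrix(FALSE, 3, 3); d <- matrix(FALSE, 3, 3)
  img <- merge_result_image(h, d)
  expect_true(all(img == 255L))           # blank -> all white
  h[1, 1] <- TRUE; d[1, 1] <- TRUE        # both -> red wins
  h[2, 2] <- TRUE                         # H only -> green
  img <- merge_result_image(h, d)
  expect_equal(as.integer(img[1, 1, ]), c(255L, 0L, 0L))
  expect_equal(as.integer(img[2, 2, ]), c(0L, 255L, 0L))
  expect_equal(as.integer(img[3, 3, ]), c(255L, 255L, 255L))
  expect_error(merge_result_image(h, matrix(FALSE, 2, 2)), "dimensions")
})

test_that("extent is DAB over the union, brute-force checked", {
  h <- matrix(FALSE, 30, 30); d <- matrix(FALSE, 30, 30)
  h[1:300] <- TRUE                  # 300 H pixels
  d[251:350] <- TRUE                # 100 DAB pixels, 50 overlapping
  union_brute <- sum(mapply(function(a, b) a || b, h, d))
  expect_equal(union_brute, 350)
  expect_equal(staining_extent(h, d), 100 / 350)
  expect_equal(staining_extent(h, matrix(FALSE, 30, 30)), 0)
  same <- h & FALSE; same[1:50] <- TRUE
  expect_equal(staining_extent(same, same), 1)
  expect_equal(staining_extent(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
})

test_that("intensity maps the threshold to 0% and full stain to 100%", {
  ch <- matrix(0L, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(staining_intensity(mask, ch, 140), 100)
  ch[] <- 140L
  expect_equal(staining_intensity(mask, ch, 140), 0)
  ch[1:50] <- 0L
  expect_equal(staining_intensity(mask, ch, 140), 50)
  expect_equal(staining_intensity(matrix(FALSE, 2, 2), matrix(0L, 2, 2), 140), 0)
})

test_that("quantification is exact on blanks and accurate on synthetic cores", {
  blank <- as_rgb_image(array(255L, dim = c(32, 32, 3)))
  q <- quantify_ihc(blank)
  expect_equal(q$extent, 0)
  expect_equal(q$n_background_pixels, 32 * 32)
  expect_equal(q$n_dab_pixels + q$n_h_only_pixels, 0)

  # planted truth recovery across a positivity sweep at default noise
  errs <- vapply(1:8, function(i) {
    pf <- 0.1 + 0.8 * (i - 1) / 7
    core <- generate_ihc_core(ihc_scene_params(width = 256, height = 256,
                                               n_nuclei = 110,
                                               positive_fraction = pf,
                                               seed = 600 + i))
    abs(quantify_ihc(core$image)$extent - core$truth$true_extent)
  }, 0)
  expect_lte(mean(errs), 0.05)
})

test_that("extent grows monotonically with the DAB threshold", {
  core <- small_core()
  ch <- color_deconvolve(core$image)
  ext <- vapply(seq(40, 240, by = 25), function(t) {
    m <- threshold_masks(ch, threshold_config(167, t))
    staining_extent(m$h_mask, m$dab_mask)
  }, 0)
  expect_true(all(diff(ext) >= 0))
  expect_true(all(ext >= 0 & ext <= 1))
})

test_that("a lossless round trip leaves the quantification unchanged", {
  core <- small_core()
  enc <- compress_jp2(core$image, compression_spec("lossless"))
  q1 <- quantify_ihc(core$image)
  q2 <- quantify_ihc(decompress_jp2(enc$stream))
  expect_identical(q1, q2)
})

test_that("threshold calibration lands on the frozen defaults", {
  cores <- Map(function(s, pf) generate_ihc_core(
    ihc_scene_params(seed = s, positive_fraction = pf)),
    101:105, c(0.2, 0.35, 0.5, 0.65, 0.8))
  cfg <- calibrate_thresholds(cores)
  expect_equal(cfg$h_threshold, default_thresholds()$h_threshold)
  expect_equal(cfg$dab_threshold, default_thresholds()$dab_threshold)
})
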