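test_that("core generation is deterministic and honours the positivity fraction", {
  p0 <- ihc_scene_params(width = 128, height = 128, n_nuclei = 30,
                         positive_fraction = 0, seed = 5)
  core0 <- generate_ihc_core(p0)
  expect_equal(core0$truth$true_extent, 0)
  expect_false(any(core0$truth$positive_mask))

  p1 <- ihc_scene_params(width = 128, height = 128, n_nuclei = 30,
                         positive_fraction = 1, seed = 5)
  expect_equal(generate_ihc_core(p1)$truth$true_extent, 1)

  p <- ihc_scene_params(seed = 7, n_nuclei = 200, positive_fraction = 0.30)
  a <- generate_ihc_core(p)
  b <- generate_ihc_core(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # per-nucleus assignment is binomial, so pixel extent is near 0.30
  expect_gte(a$truth$true_extent, 0.25)
  expect_lte(a$truth$true_extent, 0.35)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(3)
  set.seed(99)
  invisible(generate_ihc_core(ihc_scene_params(width = 96, height = 96,
                                               n_nuclei = 5, seed = 1)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("tiny frames that cannot hold one nucleus are rejected", {
  expect_error(generate_ihc_core(
    ihc_scene_params(width = 64, height = 64, nucleus_radius_range = c(30, 40))),
    "too small")
})

test_that("deconvolution recovers planted masks from a noise-free core", {
  core <- small_core_clean()
  ch <- color_deconvolve(core$image)
  masks <- threshold_masks(ch, default_thresholds())
  expect_gte(jaccard(masks$h_mask, core$truth$nucleus_mask), 0.95)
  expect_gte(jaccard(masks$dab_mask, core$truth$positive_mask), 0.95)
})

test_that("texture scenes are deterministic and class-distinct", {
  p <- texture_scene_params(width = 200, height = 200, seed = 3)
  expect_identical(generate_texture_image(p)$image,
                   generate_texture_image(p)$image)
  pe <- texture_scene_params(width = 200, height = 200,
                             class_label = "epithelium", seed = 3)
  ps <- texture_scene_params(width = 200, height = 200,
                             class_label = "stroma", seed = 3)
  expect_false(identical(generate_texture_image(pe)$image,
                         generate_texture_image(ps)$image))
})

test_that("texture classes are separable in feature space (positive silhouette)", {
  qs <- small_quantizers()
  feats <- list(); labs <- character(0)
  for (cl in c("epithelium", "stroma")) {
    for (s in 41:44) {
      img <- generate_texture_image(texture_scene_params(
        width = 256, height = 256, class_label = cl, seed = s))$image
      f <- image_texture_features(img, qs)
      feats[[length(feats) + 1L]] <- f
      labs <- c(labs, rep(cl, nrow(f)))
    }
  }
  X <- do.call(rbind, feats)
  D <- as.matrix(dist(X))
  sil <- vapply(seq_along(labs), function(i) {
    own <- labs == labs[i]; own[i] <- FALSE
    a <- mean(D[i, own]); b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})

test_that("dataset generation writes reproducible PNGs and a faithful manifest", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(5, base_seed = 9, kind = "ihc", out_dir = d1,
                         width = 128, height = 128, n_nuclei = 25,
                         overwrite = TRUE)
  expect_equal(nrow(m1), 5)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_error(generate_dataset(5, base_seed = 9, kind = "ihc", out_dir = d1,
                                width = 128, height = 128, n_nuclei = 25),
               "overwrite")
  m2 <- generate_dataset(5, base_seed = 9, kind = "ihc", out_dir = d2,
                         width = 128, height = 128, n_nuclei = 25,
                         overwrite = TRUE)
  h1 <- unname(tools::md5sum(file.path(d1, m1$file)))
  h2 <- unname(tools::md5sum(file.path(d2, m2$file)))
  expect_identical(h1, h2)
  # sweeping the positivity fraction spans the extent scale
  expect_lt(min(m1$true_extent), 0.2)
  expect_gt(max(m1$true_extent), 0.8)
  expect_equal(utils::read.csv(file.path(d1, "manifest.csv"))$true_extent,
               m1$true_extent, tolerance = 1e-6)
})
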