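# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small noise-free core whose planted masks are exactly recoverable.
small_core_clean <- function() memo("core_clean", {
  generate_ihc_core(ihc_scene_params(width = 192, height = 192, n_nuclei = 40,
                                     positive_fraction = 0.4, noise_sd = 0,
                                     seed = 11))
})

# A small noisy core at default optics.
small_core <- function() memo("core_noisy", {
  generate_ihc_core(ihc_scene_params(width = 192, height = 192, n_nuclei = 40,
                                     positive_fraction = 0.4, seed = 12))
})

# Small texture images of both classes (256x256 keeps LBP runs quick).
small_texture <- function(class_label, seed = 21) {
  memo(sprintf("tex_%s_%d", class_label, seed), {
    generate_texture_image(texture_scene_params(width = 256, height = 256,
                                                class_label = class_label,
                                                seed = seed))
  })
}

# Quantizers trained on one small image pair.
small_quantizers <- function() memo("quant", {
  grays <- lapply(c("epithelium", "stroma"), function(cl) {
    preprocess_texture(small_texture(cl)$image)$gray
  })
  train_texture_quantizers(grays)
})

# A small fitted segmentation model (6 + 6 training images).
small_model <- function() memo("model", {
  dir <- file.path(tempdir(), "fixture_tex_train")
  man <- generate_dataset(6, base_seed = 31, kind = "texture", out_dir = dir,
                          size_range = c(256, 320),
                          impurity_range = c(0, 0.05), overwrite = TRUE)
  texseg_fit(file.path(dir, man$file), man$class_label)
})

jaccard <- function(a, b) sum(a & b) / sum(a | b)
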