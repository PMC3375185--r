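#' Synthetic histology scenes with known ground truth
#'
#' Real tissue-microarray scans are not redistributable, so every stage
#' of the package is exercised on synthetic scenes: (a) IHC-like cores
#' whose colours are produced by Beer-Lambert superposition of
#' haematoxylin and DAB optical densities, with the true DAB-positive
#' pixel fraction known exactly; (b) two-class texture images mimicking
#' compact epithelial blob texture versus oriented fibrous stroma.
#'
#' @name synthetic
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Parameters of a synthetic IHC core scene
#'
#' Defaults emulate a crop of a Ki-67 stained breast-cancer TMA core
#' scanned at roughly 0.25 um/pixel: nuclei of 10-20 pixel radius
#' (~5-10 um diameter at that resolution), dense tumor-sheet cellularity, haematoxylin counterstain on every
#' nucleus and DAB additionally deposited on the positive subset.
#'
#' @param width,height image size in pixels (>= 64).
#' @param n_nuclei number of nuclei to plant (>= 1).
#' @param positive_fraction per-nucleus probability of DAB positivity,
#'   in `[0, 1]`; realised positivity is binomial.
#' @param nucleus_radius_range `c(min, max)` semi-major axis in pixels.
#' @param dab_od peak DAB optical density of a positive nucleus (> 0).
#' @param hem_od peak haematoxylin optical density of any nucleus (> 0).
#' @param noise_sd additive Gaussian noise sigma in 8-bit units.
#' @param seed integer RNG seed; all output is a pure function of the
#'   parameters including the seed.
#' @return a list of class `ihc_scene_params`.
#' @export
ihc_scene_params <- function(width = 512, height = 512, n_nuclei = 450,
                             positive_fraction = 0.3,
                             nucleus_radius_range = c(10, 20),
                             dab_od = 0.8, hem_od = 0.6,
                             noise_sd = 2, seed = 1) {
  stopifnot(width >= 64, height >= 64, n_nuclei >= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            length(nucleus_radius_range) == 2,
            nucleus_radius_range[1] > 0,
            diff(nucleus_radius_range) >= 0,
            dab_od > 0, hem_od > 0, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_nuclei = as.integer(n_nuclei),
                 positive_fraction = positive_fraction,
                 nucleus_radius_range = nucleus_radius_range,
                 dab_od = dab_od, hem_od = hem_od,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ihc_scene_params")
}

# Paint value `val` inside an ellipse into matrix `m` using max-composition
# (overlapping stains keep the larger optical density).
paint_ellipse_max <- function(m, cx, cy, r1, r2, theta, val) {
  h <- nrow(m); w <- ncol(m)
  r <- max(r1, r2)
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / r1)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / r2)
  inside <- (u * u + v * v) <= 1
  sub <- m[rows, cols]
  sub[inside] <- pmax(sub[inside], val)
  m[rows, cols] <- sub
  m
}

#' Generate a synthetic IHC-stained core image
#'
#' Nuclei are random ellipses; every nucleus carries haematoxylin
#' optical density and a binomial subset additionally carries DAB.
#' Channels are composed with the Beer-Lambert law
#' `I_c = 255 * 10^(-OD_H * v_H[c] - OD_DAB * v_D[c])` using the same
#' H-DAB stain vectors the deconvolution module inverts, so colour
#' deconvolution can (up to noise) recover the planted masks.
#'
#' @param params an [ihc_scene_params()] object.
#' @return list with elements `image` (8-bit RGB array) and `truth`, a
#'   list holding `nucleus_mask`, `positive_mask` (logical matrices)
#'   and `true_extent = |positive| / |nucleus|` over pixels.
#' @export
generate_ihc_core <- function(params) {
  stopifnot(inherits(params, "ihc_scene_params"))
  p <- params
  rmax <- p$nucleus_radius_range[2]
  if (p$width < 2 * rmax + 2 || p$height < 2 * rmax + 2) {
    stop("image too small to hold one nucleus of radius ", rmax, call. = FALSE)
  }
  vecs <- hdab_stain_vectors()
  with_seed(p$seed, {
    h_od <- matrix(0, p$height, p$width)
    d_od <- matrix(0, p$height, p$width)
    cx <- runif(p$n_nuclei, rmax + 1, p$width - rmax)
    cy <- runif(p$n_nuclei, rmax + 1, p$height - rmax)
    r1 <- runif(p$n_nuclei, p$nucleus_radius_range[1], rmax)
    r2 <- r1 * runif(p$n_nuclei, 0.65, 1)
    th <- runif(p$n_nuclei, 0, pi)
    pos <- stats::rbinom(p$n_nuclei, 1L, p$positive_fraction) == 1L
    if (p$positive_fraction == 0) pos[] <- FALSE
    if (p$positive_fraction == 1) pos[] <- TRUE
    for (i in seq_len(p$n_nuclei)) {
      h_od <- paint_ellipse_max(h_od, cx[i], cy[i], r1[i], r2[i], th[i], p$hem_od)
      if (pos[i]) {
        d_od <- paint_ellipse_max(d_od, cx[i], cy[i], r1[i], r2[i], th[i], p$dab_od)
      }
    }
    img <- array(0, dim = c(p$height, p$width, 3L))
    for (ch in 1:3) {
      img[, , ch] <- 255 * 10^-(h_od * vecs["haematoxylin", ch] +
                                  d_od * vecs["dab", ch])
    }
    if (p$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = p$noise_sd)
    }
    nucleus_mask <- h_od > 0
    positive_mask <- d_od > 0
    list(image = as_rgb_image(img),
         truth = list(
           nucleus_mask = nucleus_mask,
           positive_mask = positive_mask,
           true_extent = if (sum(nucleus_mask) == 0) 0 else
             sum(positive_mask) / sum(nucleus_mask)))
  })
}

#' Parameters of a synthetic two-class texture scene
#'
#' The two classes are built to differ in texture, not brightness:
#' `"epithelium"` is rendered as densely packed rounded dark blobs
#' (compact chromatin-like texture), `"stroma"` as sparser, elongated,
#' randomly oriented low-contrast fibres. Image sides default to the
#' annotation-size regime of real region-of-interest exports
#' (168-1191 pixels).
#'
#' @param width,height image size in pixels, in `[168, 1191]` by default.
#' @param class_label `"epithelium"` or `"stroma"`.
#' @param background_level 8-bit gray of empty glass (bright field).
#' @param density texture element density multiplier (1 = default).
#' @param impurity fraction (in `[0, 0.45]`) of the frame covered by a
#'   strip of the *other* tissue texture. Real region-of-interest
#'   annotations are rarely pure — epithelial regions contain stromal
#'   septa and vice versa — and this admixture is what spreads
#'   image-level classifier scores towards the decision boundary.
#' @param noise_sd additive luminance noise sigma in 8-bit units.
#' @param seed integer RNG seed.
#' @return a list of class `texture_scene_params`.
#' @export
texture_scene_params <- function(width = 384, height = 384,
                                 class_label = c("epithelium", "stroma"),
                                 background_level = 245, density = 1,
                                 impurity = 0, noise_sd = 6, seed = 1) {
  class_label <- match.arg(class_label)
  stopifnot(width >= 168, height >= 168, width <= 1191, height <= 1191,
            background_level > 0, background_level <= 255,
            density > 0, impurity >= 0, impurity <= 0.45, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 class_label = class_label,
                 background_level = background_level,
                 density = density, impurity = impurity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "texture_scene_params")
}

# Paint a darker ellipse with min-composition (overlapping elements keep
# the darker value).
paint_ellipse_min <- function(m, cx, cy, r1, r2, theta, val) {
  h <- nrow(m); w <- ncol(m)
  r <- max(r1, r2)
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / r1)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / r2)
  inside <- (u * u + v * v) <= 1
  sub <- m[rows, cols]
  sub[inside] <- pmin(sub[inside], val)
  m[rows, cols] <- sub
  m
}

# Spatially correlated grain: white noise smoothed with a 3x3 box and
# rescaled to the requested sigma. Scanner noise is not white (optics and
# demosaicing correlate neighbouring pixels), and correlated grain also
# survives the half-scale preprocessing step instead of averaging away.
correlated_noise <- function(h, w, sd) {
  z <- matrix(stats::rnorm((h + 2) * (w + 2)), h + 2, w + 2)
  s <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) s <- s + z[(1:h) + dy, (1:w) + dx]
  s / 3 * sd                      # sum of 9 iid N(0,1) has sd 3
}

# Paint one tissue texture into the luminance canvas, restricted to the
# rectangle [y0,y1] x [x0,x1] (element centres are drawn there).
paint_texture <- function(lum, cls, density, y0, y1, x0, x1, full_w, full_h) {
  area <- (y1 - y0 + 1) * (x1 - x0 + 1)
  if (cls == "epithelium") {
    # densely packed fine chromatin-like blobs
    n <- round(density * area / 220)
    if (n < 1) return(lum)
    cx <- runif(n, x0, x1); cy <- runif(n, y0, y1)
    r1 <- runif(n, 2.5, 6); r2 <- r1 * runif(n, 0.75, 1)
    th <- runif(n, 0, pi)
    val <- runif(n, 95, 160)
  } else {
    # dense oriented fibre mat; structure everywhere, no flat glass
    n <- round(density * area / 320)
    if (n < 1) return(lum)
    cx <- runif(n, x0, x1); cy <- runif(n, y0, y1)
    r1 <- runif(n, 12, 35)           # fibre half-length
    r2 <- runif(n, 1.2, 2.8)         # fibre half-width
    # orientations drift smoothly across the field
    th <- (cx / full_w + cy / full_h) * pi + runif(n, -0.5, 0.5)
    val <- runif(n, 150, 190)
  }
  for (i in seq_len(n)) {
    lum <- paint_ellipse_min(lum, cx[i], cy[i], r1[i], r2[i], th[i], val[i])
  }
  lum
}

#' Generate a synthetic epithelium- or stroma-like texture image
#'
#' The primary texture fills the frame; when `impurity > 0` a strip
#' along one image edge (chosen by the RNG) is overpainted with the
#' other class's texture, emulating the mixed tissue content of real
#' annotated regions.
#'
#' @param params a [texture_scene_params()] object.
#' @return list with elements `image` (8-bit RGB array) and
#'   `class_label`.
#' @export
generate_texture_image <- function(params) {
  stopifnot(inherits(params, "texture_scene_params"))
  p <- params
  other <- setdiff(c("epithelium", "stroma"), p$class_label)
  with_seed(p$seed, {
    # luminance canvas; tissue fills the frame, slightly below glass level
    base <- if (p$class_label == "epithelium") 205 else 215
    lum <- matrix(base, p$height, p$width)
    lum <- paint_texture(lum, p$class_label, p$density,
                         1, p$height, 1, p$width, p$width, p$height)
    if (p$impurity > 0) {
      side <- sample.int(4L, 1L)
      if (side <= 2L) {                       # left/right strip
        sw <- max(1, round(p$impurity * p$width))
        x0 <- if (side == 1L) 1 else p$width - sw + 1
        lum[, x0:(x0 + sw - 1)] <- base
        lum <- paint_texture(lum, other, p$density,
                             1, p$height, x0, x0 + sw - 1, p$width, p$height)
      } else {                                # top/bottom strip
        sh <- max(1, round(p$impurity * p$height))
        y0 <- if (side == 3L) 1 else p$height - sh + 1
        lum[y0:(y0 + sh - 1), ] <- base
        lum <- paint_texture(lum, other, p$density,
                             y0, y0 + sh - 1, 1, p$width, p$width, p$height)
      }
    }
    if (p$noise_sd > 0) {
      lum <- lum + correlated_noise(nrow(lum), ncol(lum), p$noise_sd)
    }
    tint <- if (p$class_label == "epithelium") c(1.02, 0.94, 1.04)  # purple
            else c(1.05, 0.92, 0.98)                                # eosin pink
    img <- array(0, dim = c(p$height, p$width, 3L))
    for (ch in 1:3) img[, , ch] <- lum * tint[ch]
    list(image = as_rgb_image(img), class_label = p$class_label)
  })
}

#' Generate a reproducible synthetic image dataset on disk
#'
#' Writes losslessly compressed PNG images plus a CSV manifest with one
#' row per image (`file, seed, kind, width, height, true_extent,
#' class_label`). Everything is reproducible from `base_seed`.
#'
#' @param n_per_condition number of images (per class for textures).
#' @param base_seed integer; per-image seeds are derived from it.
#' @param kind `"ihc"` or `"texture"`.
#' @param out_dir output directory, created if needed.
#' @param positive_fractions for `kind = "ihc"`: vector of per-image
#'   nucleus positivity probabilities, recycled/swept over images.
#'   Default sweeps evenly over `[0.05, 0.95]`.
#' @param size_range for `kind = "texture"`: range image sides are
#'   drawn from (uniform), inside the 168-1191 pixel annotation regime.
#' @param impurity_range for `kind = "texture"`: per-image admixture of
#'   the other tissue texture is drawn uniformly from this range,
#'   emulating the variable purity of real annotations.
#' @param overwrite refuse to clobber an existing manifest unless TRUE.
#' @param ... further arguments passed to [ihc_scene_params()] or
#'   [texture_scene_params()] (e.g. `noise_sd`, `width`).
#' @return the manifest as a data.frame (invisibly written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n_per_condition, base_seed, kind = c("ihc", "texture"),
                             out_dir, positive_fractions = NULL,
                             size_range = c(256, 448),
                             impurity_range = c(0, 0.4),
                             overwrite = FALSE, ...) {
  kind <- match.arg(kind)
  stopifnot(n_per_condition >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  seed0 <- (as.integer(base_seed) %% 1000000L) * 1000L
  rows <- list()
  if (kind == "ihc") {
    n <- n_per_condition
    if (is.null(positive_fractions)) {
      positive_fractions <- seq(0.05, 0.95, length.out = n)
    }
    pf <- rep_len(positive_fractions, n)
    for (i in seq_len(n)) {
      sp <- ihc_scene_params(positive_fraction = pf[i], seed = seed0 + i, ...)
      core <- generate_ihc_core(sp)
      f <- sprintf("ihc_%04d.png", i)
      write_image_png(core$image, file.path(out_dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, seed = sp$seed, kind = "ihc",
        width = sp$width, height = sp$height,
        true_extent = core$truth$true_extent, class_label = NA_character_,
        stringsAsFactors = FALSE)
    }
  } else {
    classes <- c("epithelium", "stroma")
    # image sides drawn once for both classes so size is not a class cue
    i <- 0L
    for (cl in classes) {
      for (k in seq_len(n_per_condition)) {
        i <- i + 1L
        sd_i <- seed0 + i
        draws <- with_seed(sd_i + 500L, c(
          round(runif(2, size_range[1], size_range[2])),
          runif(1, impurity_range[1], impurity_range[2])))
        sp <- texture_scene_params(width = draws[1], height = draws[2],
                                   class_label = cl, impurity = draws[3],
                                   seed = sd_i, ...)
        tex <- generate_texture_image(sp)
        f <- sprintf("tex_%s_%04d.png", substr(cl, 1, 3), k)
        write_image_png(tex$image, file.path(out_dir, f))
        rows[[length(rows) + 1L]] <- data.frame(
          file = f, seed = sp$seed, kind = "texture",
          width = sp$width, height = sp$height,
          true_extent = NA_real_, class_label = cl,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  manifest
}
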