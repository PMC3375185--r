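#' Degradation experiments
#'
#' Drivers reproducing the structure of the compression/scaling study:
#' a compression-by-scaling grid for IHC quantification (extent scores
#' dichotomized at the seventh decile of the reference condition and
#' compared to the lossless, non-scaled reference by percent agreement
#' and kappa) and a compression-only series for texture segmentation
#' (no scaling, because LBP features are scale-variant). File-size
#' accounting over the same grid is provided separately.
#'
#' @name experiment
NULL

ratio_label <- function(r) ifelse(r <= 1, "lossless", sprintf("1:%g", r))

# Round-trip a set of PNGs through JPEG2000 at one lossy ratio in a single
# worker process; returns the decoded PNG paths.
jp2_roundtrip_batch <- function(src_paths, ratio, work_dir) {
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  dst <- file.path(work_dir, basename(src_paths))
  jp2 <- file.path(work_dir, paste0(basename(src_paths), ".jp2"))
  jobs <- lapply(seq_along(src_paths), function(i) {
    list(op = "roundtrip", src = src_paths[i], jp2 = jp2[i], dst = dst[i],
         ratio = ratio)
  })
  run_jp2_jobs(jobs)
  unlink(jp2)
  dst
}

#' Run the compression-by-scaling grid for IHC quantification
#'
#' Every image is degraded at every (ratio, scale) condition
#' (compression at original scale, then box-filter downscaling of the
#' decoded image) and scored with [quantify_ihc()]. Extents of all
#' conditions are dichotomized with the cut-off computed once from the
#' reference condition (lossless, scale 1), so the reference cell is
#' exactly 100% / kappa 1, and each condition is compared to the
#' reference by percent agreement and Cohen's kappa.
#'
#' @param manifest data.frame from [generate_dataset()] (`kind = "ihc"`),
#'   or any data.frame with a `file` column of PNG names.
#' @param image_dir directory holding the manifest's PNGs.
#' @param ratios lossy compression ratios; 0 denotes lossless. The
#'   reference condition (lossless, scale 1) is always evaluated.
#' @param scales power-of-two downscale factors.
#' @param cfg a [threshold_config()].
#' @param decile dichotomization decile (default 7).
#' @return object of class `ihc_experiment_report`: `grid` (data.frame
#'   with `ratio, scale, agreement, kappa`), `extents` (images x
#'   conditions), `cutoff`, `reference`.
#' @export
run_ihc_grid <- function(manifest, image_dir,
                         ratios = c(0, 12, 25, 50),
                         scales = c(1, 2, 4, 8, 16, 32, 64, 128),
                         cfg = default_thresholds(), decile = 7) {
  stopifnot(nrow(manifest) >= 1, length(ratios) >= 1, length(scales) >= 1)
  paths <- file.path(image_dir, manifest$file)
  if (!all(file.exists(paths))) stop("missing images in ", image_dir, call. = FALSE)
  ratios <- sort(unique(ifelse(ratios <= 1, 0, ratios)))
  scales <- sort(unique(scales))
  if (!0 %in% ratios) ratios <- c(0, ratios)
  if (!1 %in% scales) scales <- c(1, scales)
  n <- length(paths)
  cond_names <- as.vector(outer(scales, ratios,
                                function(s, r) sprintf("r%g_s%g", r, s)))
  extents <- matrix(NA_real_, n, length(cond_names),
                    dimnames = list(manifest$file, cond_names))
  for (r in ratios) {
    src <- if (r == 0) paths else {
      jp2_roundtrip_batch(paths, r, file.path(tempdir(), sprintf("ihc_r%g", r)))
    }
    for (i in seq_len(n)) {
      img <- read_image_png(src[i])
      for (s in scales) {
        ds <- if (s == 1) img else downscale(img, scaling_spec(s))
        extents[i, sprintf("r%g_s%g", r, s)] <-
          quantify_ihc(ds, cfg = cfg)$extent
      }
    }
    if (r != 0) unlink(src)
  }
  ref_col <- "r0_s1"
  dich <- dichotomize_decile(extents[, ref_col], decile = decile)
  ref_labels <- dich$labels
  grid <- expand.grid(scale = scales, ratio = ratios)[, c("ratio", "scale")]
  grid$agreement <- NA_real_
  grid$kappa <- NA_real_
  for (k in seq_len(nrow(grid))) {
    col <- sprintf("r%g_s%g", grid$ratio[k], grid$scale[k])
    labels <- extents[, col] > dich$cutoff
    tab <- contingency(ref_labels, labels)
    grid$agreement[k] <- percent_agreement(tab)
    grid$kappa[k] <- cohens_kappa(tab)
  }
  structure(list(grid = grid, extents = extents, cutoff = dich$cutoff,
                 reference = ref_col),
            class = "ihc_experiment_report")
}

#' @export
print.ihc_experiment_report <- function(x, ...) {
  cat("IHC degradation grid: percent agreement vs lossless/unscaled reference\n")
  ag <- stats::xtabs(agreement ~ ratio + scale, data = x$grid)
  print(round(unclass(ag), 2))
  invisible(x)
}

#' Run the compression-only series for texture segmentation
#'
#' Classifies every test image at the lossless reference and after a
#' JPEG2000 round trip at each lossy ratio; predicted classes of each
#' ratio are compared to the reference predictions by percent
#' agreement and kappa. No scaling series is applied (the LBP features
#' are scale-variant by design).
#'
#' @param image_paths PNG paths of the test images (disjoint from the
#'   model's training images).
#' @param model a fitted [texseg_fit()] model.
#' @param ratios lossy compression ratios (default `c(12, 25, 50)`).
#' @return object of class `seg_experiment_report`: `table`
#'   (`ratio, agreement, kappa`), `classes` and `scores` (images x
#'   conditions, first column the lossless reference).
#' @export
run_seg_series <- function(image_paths, model, ratios = c(12, 25, 50)) {
  stopifnot(inherits(model, "texseg_model"), length(image_paths) >= 1,
            all(ratios > 1))
  classify_set <- function(paths) {
    pr <- predict(model, as.list(paths))
    if (any(is.na(pr$class))) {
      stop("unclassifiable image in the series (no qualifying elements)",
           call. = FALSE)
    }
    pr
  }
  conds <- c("lossless", sprintf("r%g", ratios))
  n <- length(image_paths)
  classes <- matrix(NA_character_, n, length(conds),
                    dimnames = list(basename(image_paths), conds))
  scores <- matrix(NA_real_, n, length(conds),
                   dimnames = dimnames(classes))
  ref <- classify_set(image_paths)
  classes[, 1] <- ref$class; scores[, 1] <- ref$mean_score
  tab <- data.frame(ratio = ratios, agreement = NA_real_, kappa = NA_real_)
  for (j in seq_along(ratios)) {
    dec <- jp2_roundtrip_batch(image_paths, ratios[j],
                               file.path(tempdir(), sprintf("seg_r%g", ratios[j])))
    pr <- classify_set(dec)
    unlink(dec)
    classes[, j + 1] <- pr$class; scores[, j + 1] <- pr$mean_score
    ct <- contingency(classes[, 1] == "epithelium", pr$class == "epithelium")
    tab$agreement[j] <- percent_agreement(ct)
    tab$kappa[j] <- cohens_kappa(ct)
  }
  structure(list(table = tab, classes = classes, scores = scores),
            class = "seg_experiment_report")
}

#' @export
print.seg_experiment_report <- function(x, ...) {
  cat("Segmentation agreement vs lossless reference:\n")
  print(transform(x$table, agreement = round(agreement, 2),
                  kappa = round(kappa, 4)), row.names = FALSE)
  invisible(x)
}

#' Stored-size accounting over the degradation grid
#'
#' For one representative image, computes the archival byte cost of
#' every (ratio, scale) condition: the image compressed at full scale,
#' decoded, downscaled, and stored at the final scale in the row's
#' compression mode (lossless row stored losslessly, lossy rows
#' re-encoded at their target ratio) — the cost of keeping that
#' condition's pyramid level on disk.
#'
#' @param image 8-bit RGB array.
#' @param ratios lossy ratios, 0 = lossless.
#' @param scales downscale factors.
#' @return matrix of stored bytes (rows = ratios, columns = scales).
#' @export
file_size_table <- function(image, ratios = c(0, 12, 25, 50),
                            scales = c(1, 2, 4, 8, 16, 32, 64, 128)) {
  assert_rgb_image(image)
  work <- file.path(tempdir(), "fst")
  dir.create(work, showWarnings = FALSE, recursive = TRUE)
  src <- file.path(work, "src.png")
  write_image_png(image, src)
  jobs <- list()
  files <- character(0)
  for (r in ratios) {
    dec <- if (r <= 1) image else {
      p <- jp2_roundtrip_batch(src, r, file.path(work, sprintf("r%g", r)))
      read_image_png(p)
    }
    for (s in scales) {
      ds <- if (s == 1) dec else downscale(dec, scaling_spec(s))
      f <- file.path(work, sprintf("cell_r%g_s%g.png", r, s))
      write_image_png(ds, f)
      jobs[[length(jobs) + 1L]] <- list(op = "encode", src = f,
                                        dst = paste0(f, ".jp2"),
                                        ratio = if (r <= 1) 0 else r)
      files <- c(files, f)
    }
  }
  rep <- run_jp2_jobs(jobs)
  unlink(c(files, paste0(files, ".jp2"), src))
  matrix(rep$stored_bytes, nrow = length(ratios), byrow = TRUE,
         dimnames = list(ratio_label(ratios), sprintf("S%g", scales)))
}

#' Run the complete IHC degradation study on synthetic cores
#'
#' Generates `n_images` synthetic IHC cores with the per-nucleus
#' positivity probability swept over `[0.05, 0.95]`, runs the full
#' compression-by-scaling grid, and reports extent recovery against the
#' planted ground truth alongside the agreement grid.
#'
#' @param n_images number of synthetic cores (default 100).
#' @param base_seed master seed; the whole study is reproducible from it.
#' @param work_dir where images are generated (default: under tempdir).
#' @param ratios,scales degradation grid, see [run_ihc_grid()].
#' @param cfg thresholds ([default_thresholds()] unless overridden).
#' @param ... passed to [ihc_scene_params()] via [generate_dataset()].
#' @return list with `report` (an `ihc_experiment_report`), `manifest`,
#'   and `extent_mae` (mean absolute error of the reference-condition
#'   extent against the planted truth).
#' @export
ihc_degradation_study <- function(n_images = 100, base_seed = 1,
                                  work_dir = file.path(tempdir(), "ihc_study"),
                                  ratios = c(0, 12, 25, 50),
                                  scales = c(1, 2, 4, 8, 16, 32, 64, 128),
                                  cfg = default_thresholds(), ...) {
  manifest <- generate_dataset(n_images, base_seed, kind = "ihc",
                               out_dir = work_dir, overwrite = TRUE, ...)
  report <- run_ihc_grid(manifest, work_dir, ratios = ratios, scales = scales,
                         cfg = cfg)
  mae <- mean(abs(report$extents[, report$reference] - manifest$true_extent))
  list(report = report, manifest = manifest, extent_mae = mae)
}

#' Run the complete segmentation degradation study on synthetic textures
#'
#' Mirrors the study design: the classifier is trained once on a
#' curated training set of nearly pure annotations (lossless images
#' only), then applied to a disjoint evaluation series whose
#' annotations have realistic mixed tissue content; the evaluation
#' series is re-classified after JPEG2000 round trips at each lossy
#' ratio and compared to the lossless reference predictions. No
#' scaling series is applied.
#'
#' @param n_train_per_class curated training images per class.
#' @param n_test_per_class evaluation images per class.
#' @param base_seed master seed.
#' @param work_dir where images are generated.
#' @param ratios lossy ratios (default `c(12, 25, 50)`).
#' @param train_impurity,test_impurity admixture ranges for the two
#'   splits (training annotations are curated, hence nearly pure).
#' @param ... passed to [texture_scene_params()] via
#'   [generate_dataset()] (e.g. `noise_sd`).
#' @return list with `model`, `series` (a `seg_experiment_report`),
#'   `test_manifest`, `accuracy` (reference predictions vs planted
#'   class labels) and `truth_table` (the corresponding
#'   `contingency_2x2`).
#' @export
seg_degradation_study <- function(n_train_per_class = 30,
                                  n_test_per_class = 60,
                                  base_seed = 1,
                                  work_dir = file.path(tempdir(), "seg_study"),
                                  ratios = c(12, 25, 50),
                                  train_impurity = c(0, 0.05),
                                  test_impurity = c(0, 0.4), ...) {
  tr_dir <- file.path(work_dir, "train")
  te_dir <- file.path(work_dir, "test")
  m_tr <- generate_dataset(n_train_per_class, base_seed + 1L, kind = "texture",
                           out_dir = tr_dir, impurity_range = train_impurity,
                           overwrite = TRUE, ...)
  m_te <- generate_dataset(n_test_per_class, base_seed + 2L, kind = "texture",
                           out_dir = te_dir, impurity_range = test_impurity,
                           overwrite = TRUE, ...)
  model <- texseg_fit(file.path(tr_dir, m_tr$file), m_tr$class_label)
  series <- run_seg_series(file.path(te_dir, m_te$file), model, ratios = ratios)
  ref_class <- series$classes[, 1]
  truth_table <- contingency(m_te$class_label == "epithelium",
                             ref_class == "epithelium")
  list(model = model, series = series, test_manifest = m_te,
       accuracy = mean(ref_class == m_te$class_label),
       truth_table = truth_table)
}

#' Write an experiment report's tables to CSV files
#'
#' @param report an `ihc_experiment_report` or `seg_experiment_report`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = TRUE)
    written <<- c(written, p)
  }
  if (inherits(report, "ihc_experiment_report")) {
    utils::write.csv(report$grid, file.path(dir, "agreement_grid.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(dir, "agreement_grid.csv"))
    emit(report$extents, "extents.csv")
  } else if (inherits(report, "seg_experiment_report")) {
    utils::write.csv(report$table, file.path(dir, "agreement_series.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(dir, "agreement_series.csv"))
    emit(report$scores, "scores.csv")
  } else {
    stop("unknown report type", call. = FALSE)
  }
  invisible(written)
}
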