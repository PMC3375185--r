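#' Linear C-SVM over texture features
#'
#' A linear soft-margin support vector machine (capacity constant
#' `C = 300`, established by validation in the original development of
#' the segmentation method) separates epithelium from stroma elements
#' in the 224-dimensional LBP/VAR feature space. The fitted classifier
#' is reduced to an explicit weight vector and bias, with the sign
#' convention that epithelium scores positive.
#'
#' @name texseg
NULL

#' Train the linear element classifier
#'
#' @param features numeric matrix (elements x 224).
#' @param labels character/factor vector with values `"epithelium"` and
#'   `"stroma"`; both classes must be present.
#' @param C capacity constant (default 300).
#' @return object of class `svm_model`: `w` (length-224 weights), `b`
#'   (bias), `C`. Decision value is `w . x + b`, positive = epithelium.
#' @export
train_svm <- function(features, labels, C = 300) {
  labels <- as.character(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            all(labels %in% c("epithelium", "stroma")))
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training set", call. = FALSE)
  }
  fit <- e1071::svm(x = features,
                    y = factor(labels, levels = c("stroma", "epithelium")),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-6)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  b <- -fit$rho
  # enforce epithelium-positive orientation
  dv <- drop(features %*% w) + b
  if (mean(dv[labels == "epithelium"]) < mean(dv[labels == "stroma"])) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, C = C), class = "svm_model")
}

#' Decision values of the linear classifier
#'
#' @param model an `svm_model`.
#' @param features numeric matrix (n x 224).
#' @return numeric vector of signed distances to the hyperplane
#'   (positive = epithelium side).
#' @export
decision_values <- function(model, features) {
  stopifnot(inherits(model, "svm_model"))
  drop(features %*% model$w) + model$b
}

#' Classify a whole image from its element scores
#'
#' Every qualifying 80 x 80 element is scored by the linear classifier
#' and the image is assigned by the mean decision value: epithelium
#' when the mean is strictly positive, stroma otherwise (a mean of
#' exactly zero is stroma). Images with `|mean| > 1` are strong
#' candidates for their class; means in `[-1, 1]` are weak.
#'
#' @param image 8-bit RGB array.
#' @param model an `svm_model` (see [train_svm()]).
#' @param quantizers a [train_texture_quantizers()] object.
#' @param background_threshold,morph_radius preprocessing parameters.
#' @return object of class `segmentation_result`: `element_scores`,
#'   `mean_score`, `predicted_class` (`NA` with
#'   `status = "unclassifiable"` when no element qualifies), `band`
#'   (`"strong"`/`"weak"`), `n_elements`.
#' @export
classify_image <- function(image, model, quantizers,
                           background_threshold = 240, morph_radius = 5) {
  feats <- image_texture_features(image, quantizers,
                                  background_threshold, morph_radius)
  if (nrow(feats) == 0) {
    return(structure(list(element_scores = numeric(0), mean_score = NA_real_,
                          predicted_class = NA_character_, band = NA_character_,
                          n_elements = 0L, status = "unclassifiable"),
                     class = "segmentation_result"))
  }
  sc <- decision_values(model, feats)
  m <- mean(sc)
  structure(list(element_scores = sc, mean_score = m,
                 predicted_class = if (m > 0) "epithelium" else "stroma",
                 band = if (abs(m) <= 1) "weak" else "strong",
                 n_elements = length(sc), status = "ok"),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("segmentation: unclassifiable (no qualifying elements)\n")
  } else {
    cat(sprintf("segmentation: %s (%s candidate), mean score %.3f over %d elements\n",
                x$predicted_class, x$band, x$mean_score, x$n_elements))
  }
  invisible(x)
}

#' Fit the full epithelium/stroma segmentation model
#'
#' End-to-end training: preprocesses the training images, learns the
#' equal-occupancy VAR quantizers from their pooled tissue pixels,
#' extracts the 224-bin element features, and trains the linear C-SVM.
#' The returned object carries everything needed to classify new
#' images.
#'
#' @param images list of 8-bit RGB arrays (or PNG file paths).
#' @param labels per-image class labels (`"epithelium"`/`"stroma"`).
#' @param C capacity constant (default 300).
#' @param Q VAR quantization levels (default 8).
#' @param background_threshold,morph_radius preprocessing parameters.
#' @return object of class `texseg_model`.
#' @export
texseg_fit <- function(images, labels, C = 300, Q = 8,
                       background_threshold = 240, morph_radius = 5) {
  stopifnot(length(images) == length(labels))
  images <- lapply(images, function(x) if (is.character(x)) read_image_png(x) else x)
  pps <- lapply(images, preprocess_texture, background_threshold, morph_radius)
  quantizers <- train_texture_quantizers(
    lapply(pps, `[[`, "gray"), Q = Q,
    tissue_masks = lapply(pps, `[[`, "tissue_mask"))
  feats <- list(); labs <- character(0)
  for (i in seq_along(images)) {
    f <- image_texture_features(images[[i]], quantizers,
                                background_threshold, morph_radius)
    if (nrow(f) > 0) {
      feats[[length(feats) + 1L]] <- f
      labs <- c(labs, rep(as.character(labels[i]), nrow(f)))
    }
  }
  feats <- do.call(rbind, feats)
  svm <- train_svm(feats, labs, C = C)
  structure(list(svm = svm, quantizers = quantizers,
                 config = list(C = C, Q = Q,
                               background_threshold = background_threshold,
                               morph_radius = morph_radius),
                 n_train_elements = nrow(feats)),
            class = "texseg_model")
}

#' @export
print.texseg_model <- function(x, ...) {
  cat(sprintf("LBP/VAR + linear C-SVM tissue classifier (C = %g, Q = %d)\n",
              x$config$C, x$config$Q))
  cat(sprintf("  trained on %d elements; |w| = %.3f, b = %.3f\n",
              x$n_train_elements, sqrt(sum(x$svm$w^2)), x$svm$b))
  invisible(x)
}

#' @export
coef.texseg_model <- function(object, ...) {
  c(object$svm$w, bias = object$svm$b)
}

#' Classify images with a fitted segmentation model
#'
#' @param object a [texseg_fit()] model.
#' @param images list of 8-bit RGB arrays or PNG file paths.
#' @param ... unused.
#' @return data.frame with one row per image: `n_elements`,
#'   `mean_score`, `class`, `band`.
#' @export
predict.texseg_model <- function(object, images, ...) {
  if (is.character(images)) images <- as.list(images)
  if (!is.list(images)) images <- list(images)
  rows <- lapply(images, function(x) {
    img <- if (is.character(x)) read_image_png(x) else x
    r <- classify_image(img, object$svm, object$quantizers,
                        object$config$background_threshold,
                        object$config$morph_radius)
    data.frame(n_elements = r$n_elements, mean_score = r$mean_score,
               class = r$predicted_class, band = r$band,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Save / load a fitted segmentation model as flat JSON
#'
#' @param model a `texseg_model`.
#' @param path JSON file path.
#' @return `texseg_save()` returns `path` invisibly; `texseg_load()`
#'   the restored model.
#' @export
texseg_save <- function(model, path) {
  stopifnot(inherits(model, "texseg_model"))
  obj <- list(w = model$svm$w, b = model$svm$b, C = model$svm$C,
              config = model$config,
              n_train_elements = model$n_train_elements,
              quantizers = lapply(unclass(model$quantizers), unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname texseg_save
#' @export
texseg_load <- function(path) {
  obj <- jsonlite::fromJSON(path)
  qs <- lapply(obj$quantizers, function(q) {
    structure(list(cut_points = q$cut_points, Q = as.integer(q$Q),
                   P = as.integer(q$P), R = q$R), class = "var_quantizer")
  })
  structure(list(
    svm = structure(list(w = obj$w, b = obj$b, C = obj$C), class = "svm_model"),
    quantizers = structure(qs, class = "texture_quantizers"),
    config = obj$config,
    n_train_elements = obj$n_train_elements),
    class = "texseg_model")
}
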