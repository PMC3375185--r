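#' JPEG2000 compression and pyramid downscaling
#'
#' The degradation operators: ISO-standard JPEG2000 wavelet compression
#' (mathematically lossless, or rate-controlled lossy at target ratios
#' 1:12, 1:25, 1:50) and power-of-two box-filter downscaling
#' (1:1 ... 1:128). Encoding and decoding are delegated to the OpenJPEG
#' codec (through Pillow's JPEG2000 plugin, driven by a bundled worker
#' script); wavelet/codeblock settings are the codec defaults and are
#' recorded in the report.
#'
#' @name codec
NULL

#' @rdname codec
#' @param mode `"lossless"` or `"lossy"`.
#' @param target_ratio requested compression ratio relative to the raw
#'   RGB byte count (`width * height * 3`); must be > 1 for lossy mode.
#'   The study grid is `{12, 25, 50}`.
#' @export
compression_spec <- function(mode = c("lossless", "lossy"), target_ratio = NULL) {
  mode <- match.arg(mode)
  if (mode == "lossy") {
    stopifnot(is.numeric(target_ratio), length(target_ratio) == 1,
              target_ratio > 1)
  } else {
    target_ratio <- NULL
  }
  structure(list(mode = mode, target_ratio = target_ratio),
            class = "compression_spec")
}

#' @rdname codec
#' @param factor linear downscale denominator; one of
#'   `{1, 2, 4, 8, 16, 32, 64, 128}`.
#' @export
scaling_spec <- function(factor = 1) {
  if (!(length(factor) == 1 && factor %in% c(1, 2, 4, 8, 16, 32, 64, 128))) {
    stop("scaling factor must be one of 1, 2, 4, 8, 16, 32, 64, 128",
         call. = FALSE)
  }
  structure(list(factor = as.integer(factor)), class = "scaling_spec")
}

codec_report <- function(raw_bytes, stored_bytes, spec) {
  structure(list(raw_bytes = raw_bytes,
                 stored_bytes = stored_bytes,
                 achieved_ratio = raw_bytes / stored_bytes,
                 mode = spec$mode,
                 target_ratio = spec$target_ratio,
                 codec = "JPEG2000 (OpenJPEG via Pillow, default wavelet/codeblock settings)"),
            class = "codec_report")
}

#' @export
print.codec_report <- function(x, ...) {
  cat(sprintf("JPEG2000 %s: %d -> %d bytes (ratio %.2f%s)\n",
              x$mode, x$raw_bytes, x$stored_bytes, x$achieved_ratio,
              if (is.null(x$target_ratio)) ""
              else sprintf(", target %g", x$target_ratio)))
  invisible(x)
}

jp2_python <- function() {
  py <- Sys.getenv("HISTODEGRADE_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) {
    stop("no 'python' interpreter found on PATH; JPEG2000 support needs ",
         "Python with Pillow", call. = FALSE)
  }
  py
}

jp2_worker <- function() {
  p <- system.file("python", "jp2_codec.py", package = "histodegrade")
  if (!nzchar(p)) stop("bundled jp2_codec.py worker not found", call. = FALSE)
  p
}

#' Run a batch of JPEG2000 encode/decode jobs in one worker process
#'
#' Low-level batching entry point used by the experiment driver; one
#' Python process handles the whole job list. Each job is a list with
#' fields `op` (`"encode"`, `"decode"` or `"roundtrip"`), `src`, `dst`,
#' optionally `jp2` (roundtrip codestream path) and `ratio` (absent or
#' <= 1 means lossless).
#'
#' @param jobs list of job lists.
#' @return data.frame with one row per job: `op`, `width`, `height`,
#'   `stored_bytes`.
#' @export
run_jp2_jobs <- function(jobs) {
  stopifnot(is.list(jobs), length(jobs) > 0)
  jobs_file <- tempfile(fileext = ".json")
  report_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(jobs_file, report_file)))
  jsonlite::write_json(jobs, jobs_file, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(jp2_python(),
                                  c(shQuote(jp2_worker()), shQuote(jobs_file),
                                    shQuote(report_file)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("JPEG2000 worker failed: ", paste(utils::tail(out, 3), collapse = " "),
         call. = FALSE)
  }
  rep <- jsonlite::fromJSON(report_file)
  as.data.frame(rep)
}

#' Compress an 8-bit RGB image to a JPEG2000 codestream
#'
#' @param image 8-bit RGB array.
#' @param spec a [compression_spec()].
#' @return list with `stream` (raw vector, the JPEG2000 codestream) and
#'   `report` (a `codec_report`: raw bytes, stored bytes, achieved
#'   ratio). Lossless mode round-trips bit-exactly; lossy rate control
#'   is approximate (the achieved ratio is typically within ~20% of the
#'   target).
#' @export
compress_jp2 <- function(image, spec = compression_spec()) {
  assert_rgb_image(image)
  stopifnot(inherits(spec, "compression_spec"))
  src <- tempfile(fileext = ".png")
  dst <- tempfile(fileext = ".jp2")
  on.exit(unlink(c(src, dst)))
  write_image_png(image, src)
  ratio <- if (spec$mode == "lossy") spec$target_ratio else 0
  rep <- run_jp2_jobs(list(list(op = "encode", src = src, dst = dst,
                                ratio = ratio)))
  stream <- readBin(dst, "raw", n = file.size(dst))
  raw_bytes <- prod(dim(image)[1:2]) * 3
  list(stream = stream, report = codec_report(raw_bytes, length(stream), spec))
}

#' Decode a JPEG2000 codestream back to an 8-bit RGB image
#'
#' @param stream raw vector (as returned by [compress_jp2()]) or the
#'   path of a `.jp2` file.
#' @return 8-bit RGB array. A corrupt or truncated codestream raises an
#'   explicit decode error.
#' @export
decompress_jp2 <- function(stream) {
  if (is.raw(stream)) {
    src <- tempfile(fileext = ".jp2")
    on.exit(unlink(src), add = TRUE)
    writeBin(stream, src)
  } else {
    stopifnot(is.character(stream), file.exists(stream))
    src <- stream
  }
  dst <- tempfile(fileext = ".png")
  on.exit(unlink(dst), add = TRUE)
  rep <- tryCatch(
    run_jp2_jobs(list(list(op = "decode", src = src, dst = dst))),
    error = function(e) stop("JPEG2000 decode failed: ", conditionMessage(e),
                             call. = FALSE))
  read_image_png(dst)
}

#' Downscale an image by an integer factor with a box filter
#'
#' Area-average (box) resampling: the output pixel is the mean of the
#' corresponding `factor x factor` block (partial blocks at the
#' right/bottom edge average over the pixels present), rounded
#' half-away-from-zero to 8 bits. Output dimensions are
#' `ceiling(input / factor)`; `factor = 1` returns a pixel-identical
#' copy.
#'
#' @param image 8-bit RGB array (a plain matrix is downscaled the same
#'   way and returned as a matrix).
#' @param spec a [scaling_spec()].
#' @return downscaled image of the same kind as the input.
#' @export
downscale <- function(image, spec = scaling_spec(1)) {
  stopifnot(inherits(spec, "scaling_spec"))
  f <- spec$factor
  if (f == 1) return(image)
  is_mat <- is.matrix(image)
  if (!is_mat) assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (f > h || f > w) {
    stop("scaling factor ", f, " exceeds an image dimension (", h, "x", w, ")",
         call. = FALSE)
  }
  gi <- ceiling(seq_len(h) / f)
  gj <- ceiling(seq_len(w) / f)
  cnt <- outer(tabulate(gi), tabulate(gj))
  avg1 <- function(m) {
    s <- rowsum(m, gi, reorder = TRUE)          # sum rows within blocks
    s <- t(rowsum(t(s), gj, reorder = TRUE))    # then columns
    s / cnt
  }
  if (is_mat) {
    out <- round_half_up(avg1(image))
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- array(0L, dim = c(max(gi), max(gj), 3L))
  for (ch in 1:3) out[, , ch] <- avg1(image[, , ch])
  as_rgb_image(out)
}

#' Apply a combined compression-then-scaling degradation
#'
#' The image is JPEG2000-compressed, decoded, and the decoded image is
#' then downscaled — compression happens at the original scale, as in a
#' scan-archive workflow where the stored compressed image is the
#' source for all derived resolutions. The report's `stored_bytes` is
#' the size of the degraded image re-encoded losslessly at its final
#' scale, i.e. the archival cost of keeping that condition's pixels.
#'
#' @param image 8-bit RGB array.
#' @param cspec a [compression_spec()].
#' @param sspec a [scaling_spec()].
#' @param scale_first if TRUE, downscale before compressing (non-default
#'   alternative workflow).
#' @return list with `image` (degraded 8-bit RGB array) and `report`
#'   (a `codec_report` whose `raw_bytes` refer to the final scale).
#' @export
degrade <- function(image, cspec = compression_spec(),
                    sspec = scaling_spec(1), scale_first = FALSE) {
  assert_rgb_image(image)
  roundtrip <- function(img, spec) {
    if (spec$mode == "lossless") return(img)  # bit-exact by definition
    enc <- compress_jp2(img, spec)
    decompress_jp2(enc$stream)
  }
  if (scale_first) {
    out <- roundtrip(downscale(image, sspec), cspec)
  } else {
    out <- downscale(roundtrip(image, cspec), sspec)
  }
  enc <- compress_jp2(out, compression_spec("lossless"))
  rep <- enc$report
  rep$mode <- cspec$mode
  rep$target_ratio <- cspec$target_ratio
  rep$scaling_factor <- sspec$factor
  list(image = out, report = rep)
}
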