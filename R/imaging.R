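#' Render a beat segment as a square grayscale raster
#'
#' Deterministic rasterisation for classifier input: the time axis is
#' linearly resampled to `size` columns; voltage maps to rows through a fixed
#' global window (`v_range`, default -1.5..+2.0 mV) so that ST-level shifts
#' stay comparable across images (per-beat min-max normalisation would erase
#' them); values outside the window clip. The trace is a 1-pixel polyline
#' drawn as 0 (black) on a background of 1 (white); vertical gaps between
#' adjacent columns are filled so the line is connected.
#'
#' @param beat a `beat_segment` (see [segment_beats()]), length >= 2.
#' @param size image side in pixels (>= 32; classifier default 256).
#' @param v_range length-2 voltage window in mV mapped onto the rows.
#' @return An object of class `beat_image`: `size` x `size` numeric matrix
#'   in `[0, 1]` with attributes `label` and `v_range`.
#' @export
#' @examples
#' rec <- generate_recording("SINUS_RHYTHM", 10, 360, 60,
#'                           rr_jitter_frac = 0, seed = 1)
#' pk <- rpeak_list(rec$true_r_peaks, 360)
#' img <- render_beat(segment_beats(rec$signal, pk)[[1]], size = 64)
#' dim(img)
render_beat <- function(beat, size = 256L, v_range = c(-1.5, 2.0)) {
  stopifnot(inherits(beat, "beat_segment"))
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32 pixels", call. = FALSE)
  if (length(beat$samples) < 2L) {
    stop("beat must contain at least 2 samples", call. = FALSE)
  }
  if (length(v_range) != 2L || v_range[2] <= v_range[1]) {
    stop("v_range must be an increasing length-2 vector", call. = FALSE)
  }
  # resample to `size` columns by linear interpolation
  v <- stats::approx(seq_along(beat$samples), beat$samples,
                     xout = seq(1, length(beat$samples), length.out = size))$y
  rows <- voltage_to_row(v, size, v_range)
  img <- matrix(1, nrow = size, ncol = size)
  img[rows[1], 1] <- 0
  for (j in 2:size) {
    lo <- min(rows[j - 1], rows[j])
    hi <- max(rows[j - 1], rows[j])
    img[lo:hi, j] <- 0
  }
  structure(img, class = c("beat_image", "matrix"),
            label = beat$label, v_range = v_range)
}

#' @rdname render_beat
#' @param v numeric voltages (mV).
#' @export
voltage_to_row <- function(v, size, v_range = c(-1.5, 2.0)) {
  v <- pmin(pmax(v, v_range[1]), v_range[2])
  # top row = v_range maximum; higher voltage -> smaller row index
  as.integer(round((v_range[2] - v) / (v_range[2] - v_range[1]) * (size - 1))) + 1L
}

#' @export
print.beat_image <- function(x, ...) {
  cat(sprintf("<beat_image> %dx%d, %d trace pixels, label %s\n",
              nrow(x), ncol(x), sum(x == 0),
              attr(x, "label") %||% "NA"))
  invisible(x)
}

#' @export
plot.beat_image <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1],
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Write labeled beat images to disk and build a manifest
#'
#' One image file per beat under a per-class subdirectory of `out_dir`.
#' PNG is the default (lossless, so tests can compare pixels exactly); JPEG
#' is accepted when the jpeg package is installed but is lossy. Every beat
#' must carry a label.
#'
#' @param beats list of labeled `beat_segment`s.
#' @param out_dir output directory (created if needed).
#' @param format `"png"` or `"jpg"`.
#' @param size,v_range passed to [render_beat()].
#' @param source free-text provenance recorded in the manifest.
#' @return A manifest data.frame (`path`, `label`, `source`) with attribute
#'   `class_counts`; also written to `out_dir/manifest.json`.
#' @export
build_image_dataset <- function(beats, out_dir, format = c("png", "jpg"),
                                size = 256L, v_range = c(-1.5, 2.0),
                                source = "beats") {
  format <- match.arg(format)
  if (format == "jpg" && !requireNamespace("jpeg", quietly = TRUE)) {
    stop("jpg output requires the jpeg package; use format = \"png\"",
         call. = FALSE)
  }
  labels <- vapply(beats, function(b) as.character(b$label), character(1))
  if (anyNA(labels)) {
    stop("every beat must be labeled to build a dataset", call. = FALSE)
  }
  labels <- as_beat_class(labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(beats))
  for (i in seq_along(beats)) {
    cls_dir <- file.path(out_dir, labels[i])
    dir.create(cls_dir, showWarnings = FALSE)
    img <- render_beat(beats[[i]], size = size, v_range = v_range)
    paths[i] <- file.path(cls_dir, sprintf("beat_%05d.%s", i, format))
    if (format == "png") {
      png::writePNG(unclass(img), paths[i])
    } else {
      jpeg::writeJPEG(unclass(img), paths[i], quality = 0.95)
    }
  }
  manifest <- data.frame(path = paths, label = labels, source = source,
                         stringsAsFactors = FALSE)
  counts <- table(factor(labels, levels = beat_classes()))
  attr(manifest, "class_counts") <- as.integer(counts)
  names(attr(manifest, "class_counts")) <- beat_classes()
  jsonlite::write_json(
    list(items = manifest[c("path", "label", "source")],
         class_counts = stats::setNames(as.list(as.integer(counts)),
                                        beat_classes())),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  manifest
}

#' Read a beat image back from disk
#'
#' @param path image file (PNG or JPEG).
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_beat_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path)
       else if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path)
       else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Load a manifest written by [build_image_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return Manifest data.frame with `class_counts` attribute.
#' @export
read_image_manifest <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  manifest <- as.data.frame(j$items, stringsAsFactors = FALSE)
  attr(manifest, "class_counts") <- unlist(j$class_counts)
  manifest
}
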