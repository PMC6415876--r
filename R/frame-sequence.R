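#' Frame sequences
#'
#' A `frame_sequence` holds an ordered set of equally sized single-channel
#' 8-bit frames (integer matrices with values 0--255) together with the
#' acquisition frame rate. It is the input type for all motility analysis.
#'
#' @param frames list of numeric matrices, all of identical dimension,
#'   values in 0--255.
#' @param fps frames per second (> 0).
#' @param source_id free-text identifier of the recording.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 30, source_id = "") {
  if (!is.list(frames) || length(frames) < 2L)
    stop_spermfx("a frame sequence needs at least 2 frames", "empty_input_error")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop_spermfx("frames must be matrices", "shape_error")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_spermfx("all frames must share identical dimensions", "shape_error")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop_spermfx("fps must be a single positive number", "parameter_error")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop_spermfx("frame intensities must lie in [0, 255]", "parameter_error")
  structure(
    list(frames = frames, fps = fps, source_id = as.character(source_id)),
    class = "frame_sequence"
  )
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.4g fps%s\n",
              length(x$frames), d[1], d[2], x$fps,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

# Collapse an RGB(A) array to 8-bit luminance using ITU-R 601 weights.
# `x` is in [0,1] (as returned by png/tiff/jpeg readers) or already 0-255.
to_gray255 <- function(x) {
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc >= 3L) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  if (max(x) <= 1) x <- x * 255
  round(clamp(x, 0, 255))
}

frame_files <- function(path) {
  fs <- list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                   ignore.case = TRUE, full.names = TRUE)
  fs[order(basename(fs))]
}

#' Read a video into a frame sequence
#'
#' Reads a multi-frame (stacked) TIFF file, or a directory of numbered
#' PNG/TIFF/JPEG frames, into a [frame_sequence()]. Colour frames are
#' collapsed to luminance (ITU-R 601 weights). TIFF containers carry no
#' frame-rate metadata, so `fps` is taken from the argument.
#'
#' @param path a multi-frame TIFF file or a directory of image frames.
#' @param max_frames keep at most this many frames (default all).
#' @param fps frame rate to record on the sequence (default 30).
#' @return A [frame_sequence()].
#' @export
read_video <- function(path, max_frames = Inf, fps = 30) {
  if (!file.exists(path))
    stop_spermfx(paste0("no such file: ", path), "decode_error")
  if (dir.exists(path)) {
    fs <- frame_files(path)
    if (length(fs) == 0L)
      stop_spermfx("directory contains no image frames", "empty_input_error")
    fs <- head(fs, max_frames)
    frames <- lapply(fs, function(f) to_gray255(read_raster(f)))
  } else {
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_spermfx(
                      paste0("cannot decode video container: ", conditionMessage(e)),
                      "decode_error"))
    if (!is.list(raw)) raw <- list(raw)
    if (length(raw) == 0L)
      stop_spermfx("container holds zero frames", "empty_input_error")
    raw <- head(raw, max_frames)
    frames <- lapply(raw, to_gray255)
  }
  frame_sequence(frames, fps = fps, source_id = basename(path))
}

#' Write a frame sequence as a multi-frame TIFF
#'
#' @param video a [frame_sequence()].
#' @param path output file path (`.tif`); the parent directory must exist.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "frame_sequence"))
  if (!dir.exists(dirname(path)))
    stop_spermfx("parent directory does not exist", "io_error")
  tiff::writeTIFF(lapply(video$frames, function(f) f / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    png  = png::readPNG,
    tif  = ,
    tiff = tiff::readTIFF,
    jpg  = ,
    jpeg = jpeg::readJPEG,
    NULL)
  if (is.null(reader))
    stop_spermfx(paste0("unsupported image format: .", ext), "decode_error")
  tryCatch(reader(path),
           error = function(e) stop_spermfx(
             paste0("cannot decode image: ", conditionMessage(e)), "decode_error"))
}

#' Read a still image as an 8-bit intensity raster
#'
#' PNG, TIFF and JPEG are supported; colour images are collapsed to
#' luminance with ITU-R 601 weights. Returns an integer matrix with values
#' 0--255; the optional physical pixel size is attached as the
#' `pixel_scale` attribute (micrometres per pixel).
#'
#' @param path image file path.
#' @param pixel_scale optional micrometres per pixel (> 0), metadata only.
#' @return numeric matrix (rows x cols) of intensities 0--255.
#' @export
read_image <- function(path, pixel_scale = NULL) {
  if (!file.exists(path))
    stop_spermfx(paste0("no such file: ", path), "decode_error")
  img <- to_gray255(read_raster(path))
  if (!is.null(pixel_scale)) {
    if (!is.numeric(pixel_scale) || pixel_scale <= 0)
      stop_spermfx("pixel_scale must be positive", "parameter_error")
    attr(img, "pixel_scale") <- pixel_scale
  }
  img
}

#' Write an intensity raster as a PNG image
#'
#' @param image numeric matrix with values 0--255.
#' @param path output `.png` path; the parent directory must exist.
#' @export
write_image <- function(image, path) {
  if (!dir.exists(dirname(path)))
    stop_spermfx("parent directory does not exist", "io_error")
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}
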