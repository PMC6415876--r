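#' Adaptive thresholding parameters
#'
#' Local-mean adaptive thresholding: a pixel is foreground when it deviates
#' from the mean of its `window`-sized neighbourhood by more than `offset`
#' in the direction given by `polarity`. The local mean is computed with
#' edge replication at the borders, so sharp local gradients (object
#' boundaries) drive the segmentation while slow illumination drifts cancel.
#'
#' @param window odd side length of the square neighbourhood (px, >= 3).
#' @param offset intensity subtracted from the local mean (may be negative).
#' @param polarity `"dark"` (objects darker than their surround, the halo
#'   assay's stained heads) or `"bright"`.
#' @return object of class `adaptive_threshold_params`.
#' @export
adaptive_threshold_params <- function(window = 51L, offset = 5,
                                      polarity = c("dark", "bright")) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop_spermfx("window must be odd and >= 3", "parameter_error")
  structure(list(window = window, offset = offset,
                 polarity = match.arg(polarity)),
            class = "adaptive_threshold_params")
}

# Box local mean with edge replication, via integral image on a padded copy.
local_mean <- function(img, window) {
  p <- (window - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  padded <- img[c(rep(1L, p), seq_len(h), rep(h, p)),
                c(rep(1L, p), seq_len(w), rep(w, p))]
  S <- apply(apply(padded, 2L, cumsum), 1L, cumsum)  # transposed integral image
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  i1 <- seq_len(h); i2 <- i1 + window - 1L
  j1 <- seq_len(w); j2 <- j1 + window - 1L
  (S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
     S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / (window^2)
}

#' Adaptive local-mean thresholding
#'
#' @param image numeric matrix of intensities 0--255.
#' @param params [adaptive_threshold_params()].
#' @return binary (0/1) integer matrix, 1 = foreground.
#' @export
adaptive_threshold <- function(image, params = adaptive_threshold_params()) {
  stopifnot(is.matrix(image))
  if (params$window >= min(dim(image)))
    stop_spermfx("window must be smaller than the image", "parameter_error")
  mu <- local_mean(image, params$window)
  fg <- if (params$polarity == "dark") image < mu - params$offset
        else image > mu + params$offset
  matrix(as.integer(fg), nrow(image), ncol(image))
}

#' Sanity filter on segmented head areas
#'
#' Pixel-area bounds excluding debris (below) and fused clumps of touching
#' heads (above). Areas are raw pixels; transferring between optical setups
#' requires recalibration.
#'
#' @param sanity_min_px,sanity_max_px inclusive pixel-area bounds.
#' @return object of class `segment_filter`.
#' @export
segment_filter <- function(sanity_min_px = 15L, sanity_max_px = 2000L) {
  if (sanity_min_px <= 0L || sanity_max_px <= sanity_min_px)
    stop_spermfx("require 0 < sanity_min_px < sanity_max_px", "parameter_error")
  structure(list(sanity_min_px = as.integer(sanity_min_px),
                 sanity_max_px = as.integer(sanity_max_px)),
            class = "segment_filter")
}

#' Segment sperm heads from a binary mask
#'
#' Labels 8-connected components and discards those outside the sanity
#' bounds; the survivors are reported with area, centroid and bounding box.
#'
#' @param mask binary (0/1) matrix.
#' @param filter a [segment_filter()].
#' @return data frame of head segments (possibly 0 rows): `label`,
#'   `area_px`, `centroid_row`, `centroid_col`, `bbox_*`.
#' @export
segment_heads <- function(mask, filter = segment_filter()) {
  if (!all(mask %in% c(0, 1)))
    stop_spermfx("mask must be binary", "parameter_error")
  st <- component_stats(label8(mask))
  st[st$area_px >= filter$sanity_min_px & st$area_px <= filter$sanity_max_px, ,
     drop = FALSE]
}

#' Score DNA fragmentation from segmented head areas
#'
#' In the sperm chromatin dispersion (halo) assay, sperm with intact DNA
#' disperse a chromatin halo and present as large connected regions, while
#' fragmented-DNA sperm show little or no halo and a small apparent head
#' area. A head is classified fragmented when its area falls strictly below
#' the calibrated threshold `a_star`; an area exactly at `a_star` counts as
#' non-fragmented.
#'
#' @param segments data frame from [segment_heads()] (or a numeric vector
#'   of areas).
#' @param a_star area threshold in px separating fragmented (small) from
#'   haloed (large) heads.
#' @return object of class `fragmentation_result` with `n_total`,
#'   `n_fragmented`, `score` (percent).
#' @export
score_fragmentation <- function(segments, a_star) {
  areas <- if (is.data.frame(segments)) segments$area_px else as.numeric(segments)
  if (length(areas) == 0L)
    stop_spermfx("no sperm heads to score", "no_cells_error")
  n_frag <- sum(areas < a_star)
  structure(list(n_total = length(areas), n_fragmented = n_frag,
                 score = 100 * n_frag / length(areas), a_star = a_star),
            class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat(sprintf("<fragmentation_result> %.1f%% fragmented (%d/%d heads, a* = %g px)\n",
              x$score, x$n_fragmented, x$n_total, x$a_star))
  invisible(x)
}

#' Calibrate the head-area threshold from samples of known score
#'
#' Mirrors device calibration on prepared samples with known fragmentation
#' values: over a grid of candidate area thresholds, picks the one whose
#' resulting scores have the smallest mean absolute error against the known
#' scores, breaking ties toward the smaller threshold.
#'
#' @param samples list of calibration samples; each element is a list with
#'   either `images` (list of intensity matrices) or `areas` (numeric
#'   vector of head areas), plus `known_score` (percent).
#' @param grid candidate thresholds; default: integer areas spanning the
#'   5th--95th percentile of the pooled observed areas.
#' @param params [adaptive_threshold_params()] used when segmenting images.
#' @param filter [segment_filter()] used when segmenting images.
#' @return the selected area threshold (`a_star`, numeric, with attribute
#'   `mae` holding the achieved mean absolute error).
#' @export
calibrate_area_threshold <- function(samples, grid = NULL,
                                     params = adaptive_threshold_params(),
                                     filter = segment_filter()) {
  if (length(samples) < 2L)
    stop_spermfx("calibration needs at least 2 samples with known scores",
                 "insufficient_calibration_error")
  areas <- lapply(samples, function(s) {
    if (!is.null(s$areas)) return(as.numeric(s$areas))
    segs <- lapply(s$images, function(im)
      segment_heads(adaptive_threshold(im, params), filter))
    unlist(lapply(segs, `[[`, "area_px"))
  })
  known <- vapply(samples, `[[`, numeric(1), "known_score")
  if (any(vapply(areas, length, integer(1)) == 0L))
    stop_spermfx("a calibration sample yielded no heads", "no_cells_error")
  pooled <- unlist(areas)
  if (is.null(grid)) {
    q <- stats::quantile(pooled, c(0.05, 0.95), names = FALSE)
    grid <- seq(ceiling(q[1]), floor(q[2]))
  }
  grid <- sort(grid)
  mae <- vapply(grid, function(a) {
    mean(abs(vapply(areas, function(v) 100 * sum(v < a) / length(v),
                    numeric(1)) - known))
  }, numeric(1))
  a_star <- grid[which.min(mae)]   # which.min takes the first (smallest) tie
  attr(a_star, "mae") <- min(mae)
  a_star
}

#' Run the DNA-fragmentation assay on a set of images of one sample
#'
#' Segments every image, pools the head segments across images, and scores
#' the pooled set against `a_star`.
#'
#' @param images list of intensity matrices (one sample, several fields).
#' @param params [adaptive_threshold_params()].
#' @param filter [segment_filter()].
#' @param a_star calibrated area threshold (px).
#' @return a `fragmentation_result` (see [score_fragmentation()]) plus a
#'   `report` attribute with the full parameter echo.
#' @export
run_dnafrag_assay <- function(images, params = adaptive_threshold_params(),
                              filter = segment_filter(), a_star) {
  if (length(images) == 0L)
    stop_spermfx("no images supplied", "empty_input_error")
  segs <- lapply(images, function(im)
    segment_heads(adaptive_threshold(im, params), filter))
  areas <- unlist(lapply(segs, `[[`, "area_px"))
  if (length(areas) == 0L)
    stop_spermfx("no sperm heads found in any image", "no_cells_error")
  res <- score_fragmentation(areas, a_star)
  res$report <- analysis_report(
    "dna_frag",
    parameters = c(unclass(params), unclass(filter), list(a_star = a_star)),
    results = list(n_total = res$n_total, n_fragmented = res$n_fragmented,
                   score = res$score),
    inputs = sprintf("image%02d", seq_along(images)))
  res
}
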