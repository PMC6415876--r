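#' Size gate for foreground components
#'
#' Area filter (in whole pixels) on connected foreground components,
#' rejecting objects too small (noise) or too large (debris, drift
#' artefacts) to be sperm heads. The default 4--200 px spans a sperm head
#' at the reference optical magnification and must be recalibrated for
#' other optics.
#'
#' @param min_area_px minimum component area in pixels (>= 1).
#' @param max_area_px maximum component area in pixels (>= min).
#' @return object of class `size_gate`.
#' @export
size_gate <- function(min_area_px = 4L, max_area_px = 200L) {
  if (min_area_px < 1L || max_area_px < min_area_px)
    stop_spermfx("require 0 < min_area_px <= max_area_px", "parameter_error")
  structure(list(min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px)), class = "size_gate")
}

#' Count gated motile objects in one foreground mask
#'
#' Counts 8-connected foreground components whose pixel area falls inside
#' the size gate. An empty mask yields 0.
#'
#' @param mask binary (0/1) matrix.
#' @param gate a [size_gate()].
#' @return non-negative integer count.
#' @export
count_motile_frame <- function(mask, gate = size_gate()) {
  if (!all(mask %in% c(0, 1)))
    stop_spermfx("mask must be binary", "parameter_error")
  lab <- label8(mask)
  if (max(lab) == 0L) return(0L)
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= gate$min_area_px & areas <= gate$max_area_px)
}

# 3x3 morphological opening; suppresses single-pixel noise before labelling.
open3 <- function(mask) {
  op <- EBImage::opening(mask, EBImage::makeBrush(3L, "box"))
  matrix(as.integer(op > 0), nrow(mask), ncol(mask))
}

#' Count motile sperm across a video
#'
#' Runs the mixture-of-Gaussians background model frame by frame: each frame
#' is first classified against the model trained on the preceding frames,
#' then folded into the model. Frames after `burn_in` contribute a gated
#' component count (after a single 3x3 morphological opening of the mask);
#' the aggregate count `M` is the mean of the per-frame counts.
#'
#' @param video a [frame_sequence()].
#' @param params [bg_model_params()].
#' @param gate [size_gate()].
#' @return object of class `motile_count_result` with fields
#'   `per_frame_counts`, `M` (aggregate count), `frames_used`.
#' @export
count_motile <- function(video, params = bg_model_params(), gate = size_gate()) {
  stopifnot(inherits(video, "frame_sequence"))
  n <- length(video$frames)
  if (n <= params$burn_in)
    stop_spermfx(sprintf("video has %d frames but burn_in is %d; need more frames",
                         n, params$burn_in), "insufficient_frames_error")
  model <- mog_init(video$frames[[1]], params)
  counts <- integer(0)
  for (t in 2:n) {
    frame <- video$frames[[t]]
    if (t > params$burn_in) {
      mask <- mog_foreground(model, frame, params)
      counts <- c(counts, count_motile_frame(open3(mask), gate))
    }
    model <- mog_update(model, frame, params)
  }
  if (params$burn_in == 0L) {
    # frame 1 initializes the model and is fully explained by it: count 0
    counts <- c(0L, counts)
  }
  structure(list(per_frame_counts = counts, M = mean(counts),
                 frames_used = length(counts)),
            class = "motile_count_result")
}

#' @export
print.motile_count_result <- function(x, ...) {
  cat(sprintf("<motile_count_result> M = %.2f over %d frames (range %d-%d)\n",
              x$M, x$frames_used, min(x$per_frame_counts), max(x$per_frame_counts)))
  invisible(x)
}
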