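#' Eosin-nigrosin viability percentage
#'
#' Dead sperm with compromised membranes take up eosin (stained); live
#' sperm exclude the dye. Viability is the percentage of unstained (live)
#' sperm among all intact sperm counted. Clinical practice requires at
#' least `minimum` (default 200) sperm per sample; results below the
#' minimum are still computed but flagged non-reportable.
#'
#' @param n_live unstained (dye-excluding) sperm count (>= 0).
#' @param n_dead stained sperm count (>= 0).
#' @param minimum clinical minimum total count (default 200).
#' @return object of class `viability_result` with `percent_viable`,
#'   `total_counted`, `meets_minimum`.
#' @export
compute_viability <- function(n_live, n_dead, minimum = 200L) {
  if (n_live < 0 || n_dead < 0)
    stop_spermfx("counts must be non-negative", "parameter_error")
  total <- n_live + n_dead
  if (total == 0)
    stop_spermfx("no sperm counted", "no_cells_error")
  structure(list(percent_viable = 100 * n_live / total,
                 n_live = n_live, n_dead = n_dead,
                 total_counted = total,
                 meets_minimum = total >= minimum, minimum = minimum),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result> %.1f%% viable (%d/%d)%s\n",
              x$percent_viable, x$n_live, x$total_counted,
              if (x$meets_minimum) ""
              else sprintf(" [below clinical minimum of %d]", x$minimum)))
  invisible(x)
}

#' Classify live/dead sperm in a stained field by intensity
#'
#' Automates counting on an eosin-nigrosin field imaged in monochrome:
#' dye-excluding (live) heads appear bright, stained (dead) heads dark.
#' Heads are segmented as in the DNA-fragmentation module (both polarities
#' combined, since live and dead heads deviate from the background in
#' opposite directions); each head's mean interior intensity is normalized
#' to the local background (the median intensity of non-head pixels in its
#' expanded bounding box) and the head is classified dead when that ratio
#' falls below `stain_cutoff`.
#'
#' This classifier is a desk-scale automation of the stain logic; the
#' reference viability protocol it emulates is a manual count.
#'
#' @param image intensity matrix 0--255.
#' @param filter [segment_filter()].
#' @param stain_cutoff normalized-intensity cutoff in (0, 1), default 0.5.
#' @param params [adaptive_threshold_params()] (polarity is ignored; both
#'   are used). The default offset is 20, higher than the halo module's:
#'   both stains give strong contrast, and unioning the two polarity masks
#'   doubles the noise-speckle density a small offset would let through.
#' @return list with `n_live`, `n_dead`, and a per-head data frame `heads`
#'   (`area_px`, `mean_intensity`, `background`, `ratio`, `class`).
#' @export
classify_stained_field <- function(image, filter = segment_filter(),
                                   stain_cutoff = 0.5,
                                   params = adaptive_threshold_params(offset = 20)) {
  if (stain_cutoff <= 0 || stain_cutoff >= 1)
    stop_spermfx("stain_cutoff must be in (0, 1)", "parameter_error")
  dark <- adaptive_threshold(image, adaptive_threshold_params(
    params$window, params$offset, "dark"))
  bright <- adaptive_threshold(image, adaptive_threshold_params(
    params$window, params$offset, "bright"))
  mask <- open3(matrix(as.integer(dark | bright), nrow(image), ncol(image)))
  lab <- label8(mask)
  segs <- segment_heads(mask, filter)
  if (nrow(segs) == 0L)
    stop_spermfx("no sperm heads found", "no_cells_error")
  margin <- 10L
  h <- nrow(image); w <- ncol(image)
  res <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    rs <- max(1L, s$bbox_rmin - margin):min(h, s$bbox_rmax + margin)
    cs <- max(1L, s$bbox_cmin - margin):min(w, s$bbox_cmax + margin)
    sub <- image[rs, cs, drop = FALSE]
    sublab <- lab[rs, cs, drop = FALSE]
    interior <- mean(sub[sublab == s$label])
    bg <- median(sub[sublab == 0L])
    ratio <- interior / bg
    data.frame(area_px = s$area_px, mean_intensity = interior,
               background = bg, ratio = ratio,
               class = if (ratio < stain_cutoff) "dead" else "live",
               stringsAsFactors = FALSE)
  })
  heads <- do.call(rbind, res)
  list(n_live = sum(heads$class == "live"),
       n_dead = sum(heads$class == "dead"),
       heads = heads)
}

#' Run the viability assay on a stained field image
#'
#' @param image intensity matrix 0--255.
#' @param filter [segment_filter()].
#' @param stain_cutoff see [classify_stained_field()].
#' @param minimum clinical minimum count (default 200).
#' @return a `viability_result` with the per-head table attached as
#'   `heads` and an [analysis_report()] as `report`.
#' @export
run_viability_assay <- function(image, filter = segment_filter(),
                                stain_cutoff = 0.5, minimum = 200L) {
  cls <- classify_stained_field(image, filter, stain_cutoff)
  res <- compute_viability(cls$n_live, cls$n_dead, minimum)
  res$heads <- cls$heads
  res$report <- analysis_report(
    "viability",
    parameters = c(unclass(filter),
                   list(stain_cutoff = stain_cutoff, minimum = minimum)),
    results = list(percent_viable = res$percent_viable,
                   n_live = res$n_live, n_dead = res$n_dead,
                   meets_minimum = res$meets_minimum))
  res
}
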