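#' Motility scene specification
#'
#' Defines a synthetic microscopy video: bright elliptical cells on a noisy
#' background, a subset moving as persistent random walks (heading
#' perturbed each frame, reflective borders) and the rest static. Defaults
#' emulate the reference recording conditions: 1 second at 30 fps, a sperm
#' head spanning a few pixels, and moderate sensor noise.
#'
#' @param n_motile,n_immotile cell counts (>= 0).
#' @param cell_radius_px cell radius in px (>= 1).
#' @param speed_mean,speed_sd per-frame displacement of motile cells (px).
#' @param background_level background intensity (0--255).
#' @param cell_contrast intensity gap between cell and background (may be
#'   negative for dark cells).
#' @param noise_sd Gaussian pixel noise SD.
#' @param frames number of frames (>= 2).
#' @param fps frame rate.
#' @param width,height frame size in px.
#' @param seed integer RNG seed for the scene.
#' @return object of class `motility_scene_spec`.
#' @export
motility_scene <- function(n_motile = 10L, n_immotile = 10L,
                           cell_radius_px = 3, speed_mean = 6, speed_sd = 1.5,
                           background_level = 60, cell_contrast = 80,
                           noise_sd = 2, frames = 30L, fps = 30,
                           width = 480L, height = 360L, seed = 1L) {
  if (n_motile < 0L || n_immotile < 0L)
    stop_spermfx("cell counts must be >= 0", "parameter_error")
  if (cell_radius_px < 1) stop_spermfx("cell_radius_px must be >= 1", "parameter_error")
  if (frames < 2L) stop_spermfx("need at least 2 frames", "parameter_error")
  if (noise_sd < 0) stop_spermfx("noise_sd must be >= 0", "parameter_error")
  structure(list(n_motile = as.integer(n_motile),
                 n_immotile = as.integer(n_immotile),
                 cell_radius_px = cell_radius_px, speed_mean = speed_mean,
                 speed_sd = speed_sd, background_level = background_level,
                 cell_contrast = cell_contrast, noise_sd = noise_sd,
                 frames = as.integer(frames), fps = fps,
                 width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed)),
            class = "motility_scene_spec")
}

# Rejection-sample cell centres with pairwise minimum separation.
place_cells <- function(n, width, height, radius, min_sep, max_tries = 2000L) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- c(runif(1, radius + 1, height - radius), runif(1, radius + 1, width - radius))
      if (i == 1L ||
          all((pts[seq_len(i - 1), 1] - p[1])^2 + (pts[seq_len(i - 1), 2] - p[2])^2
              >= min_sep^2)) {
        pts[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_spermfx("could not place cells without overlap", "placement_error")
  }
  colnames(pts) <- c("row", "col")
  pts
}

# Draw an anti-aliased filled disc into `img` (adds `contrast` weighted by
# pixel coverage, approximated from the centre distance).
draw_disc <- function(img, r0, c0, radius, contrast) {
  h <- nrow(img); w <- ncol(img)
  rr <- max(1L, floor(r0 - radius - 1)):min(h, ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(w, ceiling(c0 + radius + 1))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  cov <- clamp(radius + 0.5 - d, 0, 1)
  img[rr, cc] <- img[rr, cc] + contrast * cov
  img
}

#' Generate a synthetic motility video with ground truth
#'
#' Motile cells follow persistent random walks at the specified speed with
#' reflective borders; immotile cells stay put; Gaussian pixel noise is
#' added per frame and intensities quantized to 8 bits. The same seed
#' yields bit-identical output.
#'
#' @param spec a [motility_scene()].
#' @return list with `video` (a [frame_sequence()]) and `truth` (class
#'   `scene_ground_truth`: true motile/immotile counts and initial
#'   positions).
#' @export
gen_motility_video <- function(spec) {
  stopifnot(inherits(spec, "motility_scene_spec"))
  with_seed(spec$seed, {
    n <- spec$n_motile + spec$n_immotile
    pos <- place_cells(n, spec$width, spec$height, spec$cell_radius_px,
                       min_sep = 4 * spec$cell_radius_px)
    init_pos <- pos
    motile <- seq_len(n) <= spec$n_motile
    heading <- runif(n, 0, 2 * pi)
    frames <- vector("list", spec$frames)
    for (t in seq_len(spec$frames)) {
      if (t > 1L && spec$n_motile > 0L) {
        idx <- which(motile)
        heading[idx] <- heading[idx] + rnorm(length(idx), 0, 0.35)
        step <- pmax(rnorm(length(idx), spec$speed_mean, spec$speed_sd), 0)
        pos[idx, 1] <- pos[idx, 1] + step * sin(heading[idx])
        pos[idx, 2] <- pos[idx, 2] + step * cos(heading[idx])
        # reflective borders (keep the whole cell inside the frame)
        for (k in idx) {
          lim_r <- c(spec$cell_radius_px + 1, spec$height - spec$cell_radius_px)
          lim_c <- c(spec$cell_radius_px + 1, spec$width - spec$cell_radius_px)
          if (pos[k, 1] < lim_r[1]) { pos[k, 1] <- 2 * lim_r[1] - pos[k, 1]; heading[k] <- -heading[k] }
          if (pos[k, 1] > lim_r[2]) { pos[k, 1] <- 2 * lim_r[2] - pos[k, 1]; heading[k] <- -heading[k] }
          if (pos[k, 2] < lim_c[1]) { pos[k, 2] <- 2 * lim_c[1] - pos[k, 2]; heading[k] <- pi - heading[k] }
          if (pos[k, 2] > lim_c[2]) { pos[k, 2] <- 2 * lim_c[2] - pos[k, 2]; heading[k] <- pi - heading[k] }
        }
      }
      img <- matrix(spec$background_level, spec$height, spec$width)
      for (k in seq_len(n))
        img <- draw_disc(img, pos[k, 1], pos[k, 2], spec$cell_radius_px,
                         spec$cell_contrast)
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                            nrow(img), ncol(img))
      frames[[t]] <- round(clamp(img, 0, 255))
    }
    truth <- structure(list(n_motile = spec$n_motile,
                            n_immotile = spec$n_immotile,
                            initial_positions = init_pos,
                            motile = motile, seed = spec$seed),
                       class = "scene_ground_truth")
    list(video = frame_sequence(frames, fps = spec$fps,
                                source_id = sprintf("synthetic-motility-seed%d", spec$seed)),
         truth = truth)
  })
}

#' Generate a paired HBA scene (uncoated + HA-coated region videos)
#'
#' The uncoated-region video carries `n_motile` motile cells; in the
#' HA-coated video a fraction `bound_fraction` of them is bound (rendered
#' immotile), leaving `round(n_motile * (1 - bound_fraction))` motile.
#'
#' @param spec a [motility_scene()] describing the uncoated region.
#' @param bound_fraction fraction of motile sperm bound on the coated
#'   region, in \[0, 1\].
#' @return list with `video_nc`, `video_ha` ([frame_sequence()]s) and
#'   `truth` (bound fraction and per-video motile counts).
#' @export
gen_hba_pair <- function(spec, bound_fraction) {
  stopifnot(inherits(spec, "motility_scene_spec"))
  if (bound_fraction < 0 || bound_fraction > 1)
    stop_spermfx("bound_fraction must lie in [0, 1]", "parameter_error")
  nc <- gen_motility_video(spec)
  n_free <- as.integer(round(spec$n_motile * (1 - bound_fraction)))
  spec_ha <- spec
  spec_ha$n_motile <- n_free
  spec_ha$n_immotile <- spec$n_immotile + (spec$n_motile - n_free)
  spec_ha$seed <- spec$seed + 1L
  class(spec_ha) <- class(spec)
  ha <- gen_motility_video(spec_ha)
  truth <- structure(list(bound_fraction = bound_fraction,
                          n_motile_nc = spec$n_motile, n_motile_ha = n_free,
                          expected_score = 100 * (1 - n_free / spec$n_motile),
                          seed = spec$seed),
                     class = "scene_ground_truth")
  list(video_nc = nc$video, video_ha = ha$video, truth = truth)
}

#' Halo-field scene specification
#'
#' A still image of sperm heads after the chromatin dispersion assay: a
#' two-population field of dark discs (head or head+halo) on a bright
#' background with a smooth illumination gradient and Gaussian noise.
#'
#' @param n_cells number of heads.
#' @param frag_fraction fraction of fragmented (small-area) heads.
#' @param area_small_mean,area_large_mean,area_sd head-area populations
#'   (px^2), small < large.
#' @param min_separation_px minimum gap between disc rims.
#' @param illumination_gradient peak-to-peak intensity of a linear
#'   illumination ramp across the field.
#' @param contrast object/background intensity gap (> 0; objects dark).
#' @param background_level background intensity.
#' @param noise_sd Gaussian noise SD.
#' @param width,height image size (px).
#' @param seed integer RNG seed.
#' @return object of class `halo_scene_spec`.
#' @export
halo_scene <- function(n_cells = 100L, frag_fraction = 0.3,
                       area_small_mean = 40, area_large_mean = 140,
                       area_sd = 8, min_separation_px = 6,
                       illumination_gradient = 20, contrast = 60,
                       background_level = 200, noise_sd = 3,
                       width = 512L, height = 512L, seed = 1L) {
  if (area_small_mean >= area_large_mean)
    stop_spermfx("area_small_mean must be < area_large_mean", "parameter_error")
  if (frag_fraction < 0 || frag_fraction > 1)
    stop_spermfx("frag_fraction must lie in [0, 1]", "parameter_error")
  structure(list(n_cells = as.integer(n_cells), frag_fraction = frag_fraction,
                 area_small_mean = area_small_mean,
                 area_large_mean = area_large_mean, area_sd = area_sd,
                 min_separation_px = min_separation_px,
                 illumination_gradient = illumination_gradient,
                 contrast = contrast, background_level = background_level,
                 noise_sd = noise_sd, width = as.integer(width),
                 height = as.integer(height), seed = as.integer(seed)),
            class = "halo_scene_spec")
}

#' Generate a synthetic halo-assay field with ground truth
#'
#' `round(n_cells * frag_fraction)` heads draw their areas from the small
#' population and the remainder from the large one (normal laws truncated
#' positive); discs are placed without overlap, then the illumination
#' gradient and noise are applied.
#'
#' @param spec a [halo_scene()].
#' @return list with `image` (intensity matrix) and `truth` (per-cell
#'   class, target area and position; `n_fragmented`, `frag_fraction`).
#' @export
gen_halo_field <- function(spec) {
  stopifnot(inherits(spec, "halo_scene_spec"))
  with_seed(spec$seed, {
    n_small <- as.integer(round(spec$n_cells * spec$frag_fraction))
    n_large <- spec$n_cells - n_small
    areas <- c(pmax(rnorm(n_small, spec$area_small_mean, spec$area_sd), 4),
               pmax(rnorm(n_large, spec$area_large_mean, spec$area_sd), 4))
    classes <- rep(c("fragmented", "intact"), c(n_small, n_large))
    radii <- sqrt(areas / pi)
    # place largest first: greedy packing fails less often
    ord <- order(radii, decreasing = TRUE)
    pts <- matrix(NA_real_, spec$n_cells, 2)
    for (i in ord) {
      placed <- FALSE
      for (t in seq_len(2000L)) {
        p <- c(runif(1, radii[i] + 2, spec$height - radii[i] - 1),
               runif(1, radii[i] + 2, spec$width - radii[i] - 1))
        others <- which(!is.na(pts[, 1]))
        if (length(others) == 0L ||
            all(sqrt((pts[others, 1] - p[1])^2 + (pts[others, 2] - p[2])^2)
                >= radii[others] + radii[i] + spec$min_separation_px)) {
          pts[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stop_spermfx("could not place halo-field cells without overlap",
                     "placement_error")
    }
    img <- matrix(spec$background_level, spec$height, spec$width)
    ramp <- seq(-spec$illumination_gradient / 2, spec$illumination_gradient / 2,
                length.out = spec$width)
    img <- img + matrix(ramp, spec$height, spec$width, byrow = TRUE)
    for (i in seq_len(spec$n_cells))
      img <- draw_disc(img, pts[i, 1], pts[i, 2], radii[i], -spec$contrast)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    img <- round(clamp(img, 0, 255))
    truth <- structure(list(n_cells = spec$n_cells, n_fragmented = n_small,
                            frag_fraction = spec$frag_fraction,
                            classes = classes, areas = areas,
                            positions = pts, seed = spec$seed),
                       class = "scene_ground_truth")
    list(image = img, truth = truth)
  })
}

#' Generate a synthetic stained viability field with ground truth
#'
#' Renders `n_live` bright (dye-excluding) and `n_dead` dark (stained)
#' heads on a mid-grey background with Gaussian noise, for testing the
#' intensity-based live/dead classifier.
#'
#' @param n_live,n_dead head counts.
#' @param head_area mean head area (px^2).
#' @param area_sd head-area SD.
#' @param background_level background intensity.
#' @param live_level,dead_level head interior intensities.
#' @param noise_sd Gaussian noise SD.
#' @param width,height image size.
#' @param seed integer RNG seed.
#' @return list with `image` and `truth` (classes, counts).
#' @export
gen_viability_field <- function(n_live = 60L, n_dead = 40L, head_area = 80,
                                area_sd = 8, background_level = 128,
                                live_level = 215, dead_level = 45,
                                noise_sd = 3, width = 512L, height = 512L,
                                seed = 1L) {
  with_seed(seed, {
    n <- n_live + n_dead
    areas <- pmax(rnorm(n, head_area, area_sd), 4)
    radii <- sqrt(areas / pi)
    classes <- rep(c("live", "dead"), c(n_live, n_dead))
    levels <- rep(c(live_level, dead_level), c(n_live, n_dead))
    pts <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(2000L)) {
        p <- c(runif(1, radii[i] + 2, height - radii[i] - 1),
               runif(1, radii[i] + 2, width - radii[i] - 1))
        others <- which(!is.na(pts[, 1]))
        if (length(others) == 0L ||
            all(sqrt((pts[others, 1] - p[1])^2 + (pts[others, 2] - p[2])^2)
                >= radii[others] + radii[i] + 8)) {
          pts[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stop_spermfx("could not place viability-field cells", "placement_error")
    }
    img <- matrix(background_level, height, width)
    for (i in seq_len(n))
      img <- draw_disc(img, pts[i, 1], pts[i, 2], radii[i],
                       levels[i] - background_level)
    if (noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, noise_sd), height, width)
    img <- round(clamp(img, 0, 255))
    truth <- structure(list(n_live = n_live, n_dead = n_dead,
                            percent_viable = 100 * n_live / n,
                            classes = classes, positions = pts, seed = seed),
                       class = "scene_ground_truth")
    list(image = img, truth = truth)
  })
}

#' Paired-measurement table specification
#'
#' @param n number of sample pairs.
#' @param true_slope,true_intercept generating line relating the device
#'   measurement to the latent true value.
#' @param noise_sd_device,noise_sd_reference measurement noise SDs.
#' @param value_range range of the latent true values, within \[0, 100\].
#' @param seed integer RNG seed.
#' @return object of class `paired_data_spec`.
#' @export
paired_data_spec <- function(n = 102L, true_slope = 1, true_intercept = 0,
                             noise_sd_device = 3, noise_sd_reference = 3,
                             value_range = c(0, 100), seed = 1L) {
  if (n < 2L) stop_spermfx("need n >= 2", "parameter_error")
  if (noise_sd_device < 0 || noise_sd_reference < 0)
    stop_spermfx("noise SDs must be >= 0", "parameter_error")
  if (value_range[1] < 0 || value_range[2] > 100 || value_range[1] >= value_range[2])
    stop_spermfx("value_range must be an increasing interval within [0, 100]",
                 "parameter_error")
  structure(list(n = as.integer(n), true_slope = true_slope,
                 true_intercept = true_intercept,
                 noise_sd_device = noise_sd_device,
                 noise_sd_reference = noise_sd_reference,
                 value_range = value_range, seed = as.integer(seed)),
            class = "paired_data_spec")
}

#' Generate a paired measurement table with known generating parameters
#'
#' Latent true values are uniform on `value_range`; the reference
#' measurement adds its noise to the latent value, the device measurement
#' is `intercept + slope * latent` plus its noise; both are clamped to
#' \[0, 100\].
#'
#' @param spec a [paired_data_spec()].
#' @return list with `table` (a [measurement_table()]) and `truth` (the
#'   generating parameters and latent values).
#' @export
gen_paired_table <- function(spec) {
  stopifnot(inherits(spec, "paired_data_spec"))
  with_seed(spec$seed, {
    latent <- runif(spec$n, spec$value_range[1], spec$value_range[2])
    reference <- clamp(latent + rnorm(spec$n, 0, spec$noise_sd_reference), 0, 100)
    device <- clamp(spec$true_intercept + spec$true_slope * latent +
                      rnorm(spec$n, 0, spec$noise_sd_device), 0, 100)
    truth <- structure(c(unclass(spec), list(latent = latent)),
                       class = "scene_ground_truth")
    list(table = measurement_table(sprintf("S%03d", seq_len(spec$n)),
                                   device, reference),
         truth = truth)
  })
}
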