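# Small scenes keep the unit tests fast; the full-size default scenes are
# exercised by the acceptance suite.

small_scene <- function(n_motile, n_immotile = 5L, seed = 1L, ...) {
  motility_scene(n_motile = n_motile, n_immotile = n_immotile,
                 width = 160L, height = 120L, frames = 20L, seed = seed, ...)
}

small_halo <- function(frag_fraction, seed = 1L, n_cells = 40L, ...) {
  halo_scene(n_cells = n_cells, frag_fraction = frag_fraction,
             width = 360L, height = 360L, seed = seed, ...)
}

# A noise-free static video: identical constant frames.
static_video <- function(level = 100, frames = 12L, h = 40L, w = 50L) {
  frame_sequence(replicate(frames, matrix(level, h, w), simplify = FALSE))
}

random_table <- function(n, seed) {
  with_seed_local(seed, {
    x <- round(runif(n, 5, 95), 1)
    y <- round(pmin(pmax(x + rnorm(n, 0, 8), 0), 100), 1)
    measurement_table(paste0("s", seq_len(n)), y, x)
  })
}

clamp_vec <- function(v) pmin(pmax(v, 0), 100)

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
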