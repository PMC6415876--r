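#' Load a configuration file of tunables
#'
#' Plain-text key-value (YAML) configuration naming any of the tunables of
#' the assay modules. Keys are grouped by section: `background_model`
#' (K, alpha, match_sigmas, bg_weight_fraction, initial_variance, burn_in),
#' `size_gate` (min_area_px, max_area_px), `adaptive_threshold` (window,
#' offset, polarity), `segment_filter` (sanity_min_px, sanity_max_px), and
#' scalars `hba_threshold`, `a_star`, `stain_cutoff`, `viability_minimum`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return list with elements `bg_params`, `gate`, `thresh_params`,
#'   `filter`, `hba_threshold`, `a_star`, `stain_cutoff`,
#'   `viability_minimum`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_spermfx(paste0("no such file: ", path), "io_error")
    yaml::read_yaml(path) %||% list()
  }
  take <- function(defaults, section) {
    user <- raw[[section]] %||% list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop_spermfx(paste0("unknown ", section, " keys: ",
                          paste(unknown, collapse = ", ")), "schema_error")
    utils::modifyList(defaults, user)
  }
  bg <- take(unclass(bg_model_params()), "background_model")
  gt <- take(unclass(size_gate()), "size_gate")
  at <- take(unclass(adaptive_threshold_params()), "adaptive_threshold")
  sf <- take(unclass(segment_filter()), "segment_filter")
  list(
    bg_params = do.call(bg_model_params, bg),
    gate = do.call(size_gate, gt),
    thresh_params = do.call(adaptive_threshold_params, at),
    filter = do.call(segment_filter, sf),
    hba_threshold = raw$hba_threshold %||% 80,
    a_star = raw$a_star %||% NULL,
    stain_cutoff = raw$stain_cutoff %||% 0.5,
    viability_minimum = raw$viability_minimum %||% 200L
  )
}
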