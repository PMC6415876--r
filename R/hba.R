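#' Hyaluronan binding assay (HBA) score
#'
#' Mature sperm bind hyaluronic-acid-coated glass and lose their mobility,
#' so the motile count in the HA-coated region drops relative to the
#' uncoated region. The HBA score is the percentage of motile sperm bound:
#' `(1 - m_ha / m_nc) * 100`, clamped to \[0, 100\] (a motile count in the
#' coated region exceeding the uncoated one can only be counting noise and
#' a negative percent bound is physically meaningless).
#'
#' @param m_ha aggregate motile count in the HA-coated region (>= 0).
#' @param m_nc aggregate motile count in the non-coated region (> 0).
#' @return HBA score in \[0, 100\].
#' @export
compute_hba_score <- function(m_ha, m_nc) {
  if (m_ha < 0 || m_nc < 0)
    stop_spermfx("motile counts must be non-negative", "parameter_error")
  if (m_nc == 0)
    stop_spermfx("uncountable: no motile sperm in the non-coated region",
                 "undefined_denominator_error")
  clamp((1 - m_ha / m_nc) * 100, 0, 100)
}

#' Classify an HBA score against the clinical threshold
#'
#' A sample is positive (reduced binding, abnormal) when its score falls
#' below the threshold; a score at or above the threshold (including
#' exactly at it) is negative.
#'
#' @param score HBA score in \[0, 100\].
#' @param threshold score cutoff, default 80 (the assay manufacturer's).
#' @return `"positive"` or `"negative"`.
#' @export
classify_hba <- function(score, threshold = 80) {
  if (score < 0 || score > 100)
    stop_spermfx("score must lie in [0, 100]", "parameter_error")
  if (score < threshold) "positive" else "negative"
}

#' Run the full HBA assay on a pair of videos
#'
#' Counts motile sperm in the HA-coated and non-coated region videos with
#' [count_motile()], computes the percent-bound score and classifies it.
#' The two videos are independent fields; no registration between the chip
#' regions is attempted.
#'
#' @param video_ha [frame_sequence()] of the HA-coated region.
#' @param video_nc [frame_sequence()] of the non-coated region.
#' @param params [bg_model_params()].
#' @param gate [size_gate()].
#' @param threshold classification cutoff (default 80).
#' @return object of class `hba_result` with fields `m_ha`, `m_nc`,
#'   `percent_bound`, `classification`, `threshold`, and a `report`
#'   ([analysis_report()]) echoing all parameters.
#' @export
run_hba_assay <- function(video_ha, video_nc, params = bg_model_params(),
                          gate = size_gate(), threshold = 80) {
  res_ha <- count_motile(video_ha, params, gate)
  res_nc <- count_motile(video_nc, params, gate)
  score <- compute_hba_score(res_ha$M, res_nc$M)
  cls <- classify_hba(score, threshold)
  pars <- c(unclass(params), unclass(gate), list(threshold = threshold))
  rep <- analysis_report(
    "hba", parameters = pars,
    results = list(m_ha = res_ha$M, m_nc = res_nc$M, percent_bound = score,
                   classification = cls),
    inputs = c(video_ha$source_id, video_nc$source_id))
  structure(list(m_ha = res_ha$M, m_nc = res_nc$M, percent_bound = score,
                 classification = cls, threshold = threshold,
                 counts_ha = res_ha, counts_nc = res_nc, report = rep),
            class = "hba_result")
}

#' @export
print.hba_result <- function(x, ...) {
  cat(sprintf("<hba_result> percent bound = %.1f%% (%s at threshold %g)\n",
              x$percent_bound, x$classification, x$threshold))
  cat(sprintf("  motile counts: HA region %.2f, uncoated %.2f\n", x$m_ha, x$m_nc))
  invisible(x)
}
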