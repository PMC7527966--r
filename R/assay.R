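# Assay arithmetic used in biocement characterization.

#' Precipitate weight by filter-paper difference
#'
#' `W_precipitates = W_total - W_paper`.
#'
#' @param w_total Weight of the filter paper plus precipitate, g.
#' @param w_paper Weight of the empty filter paper, g.
#' @return Precipitate weight, g.
#' @export
precipitate_weight <- function(w_total, w_paper) {
  if (any(w_total < w_paper))
    stop("measurement-order error: total weight below empty-paper weight")
  w_total - w_paper
}

#' Compressive-strength gain of biocement over control
#'
#' `100 (treatment - control) / control`, percent. Full precision is
#' returned; round to one decimal for reporting.
#'
#' @param treatment_mpa Treated-cement compressive strength, MPa.
#' @param control_mpa Control compressive strength, MPa (> 0).
#' @return Gain in percent (vectorized).
#' @export
#' @examples
#' round(strength_gain(37.02, 29.05), 1)  # 27.4
strength_gain <- function(treatment_mpa, control_mpa) {
  stopifnot(all(treatment_mpa > 0), all(control_mpa > 0))
  100 * (treatment_mpa - control_mpa) / control_mpa
}
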