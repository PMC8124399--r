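#' Serial dilution plan for an ethanol-water series
#'
#' Builds the design table of a serial halving dilution: sample 0 is pure
#' water, sample 1 receives `total_volume / 100` mL of ethanol stock, and
#' every subsequent sample receives half the ethanol volume of the previous
#' one, the flask being filled to `total_volume` with water. Calculated
#' concentrations are `volume_etoh * stock_concentration / total_volume`
#' in volume percent.
#'
#' @param stock_concentration Ethanol content of the stock, Vol% in (0, 100].
#' @param total_volume Flask volume in mL, > 0.
#' @param n_samples Number of solutions including the pure-water sample 0.
#'
#' @return A tibble with columns `sample_number` (0-based), `volume_water`
#'   and `volume_etoh` (mL), and `concentration` (Vol% ethanol).
#'
#' @examples
#' dilution_series()
#' @export
dilution_series <- function(stock_concentration = 96.2,
                            total_volume = 50,
                            n_samples = 10) {
  if (!is.numeric(stock_concentration) || length(stock_concentration) != 1 ||
      stock_concentration <= 0 || stock_concentration > 100) {
    abort("`stock_concentration` must be a single Vol% value in (0, 100].",
          class = "ramanboost_invalid_argument")
  }
  if (!is.numeric(total_volume) || length(total_volume) != 1 ||
      total_volume <= 0) {
    abort("`total_volume` must be a single positive volume in mL.",
          class = "ramanboost_invalid_argument")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) {
    abort("`n_samples` must be an integer >= 1.",
          class = "ramanboost_invalid_argument")
  }
  sample_number <- seq_len(n_samples) - 1L
  # sample 0 holds no ethanol; sample s >= 1 holds total_volume/100 / 2^(s-1)
  volume_etoh <- c(0, total_volume / 100 / 2^(seq_len(n_samples - 1L) - 1))[
    seq_len(n_samples)]
  tibble::tibble(
    sample_number = sample_number,
    volume_water = total_volume - volume_etoh,
    volume_etoh = volume_etoh,
    concentration = volume_etoh * stock_concentration / total_volume
  )
}
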