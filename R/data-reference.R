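#' Reference median parameter table (basic model, systolic)
#'
#' Published per-subject median parameter estimates from a 14-day
#' cuffless-monitor pilot of six healthy adults, fitted with the basic
#' piecewise-exponential model on the systolic channel, plus the pooled
#' overall row. Useful as a realistic anchor for examples and for
#' quantifying day/night levels with [bp_dipping()] without access to raw
#' recordings.
#'
#' @return A tibble with columns `subject_id`, `base`, `incr` (mmHg), `k`
#'   (per hour), `t1`, `t2` (hours after midnight).
#' @examples
#' ref <- bp_reference_params()
#' bp_dipping(ref[ref$subject_id == "9906", ])
#' @export
bp_reference_params <- function() {
  path <- system.file("extdata", "reference_median_params_systolic.csv",
                      package = "circbp", mustWork = TRUE)
  readr::read_csv(path, col_types = "cddddd", progress = FALSE)
}
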