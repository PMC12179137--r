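#' Weighted residuals in percent of the observed value
#'
#' The fit diagnostic used throughout: residuals divided by the observed
#' values, in percent, i.e. `100 * (observed - predicted) / observed`.
#' For a well-specified model they scatter randomly about zero with no
#' time trend.
#'
#' @param observed Observed pressures (mmHg); must be positive.
#' @param predicted Model predictions (mmHg), same length.
#' @return Numeric vector of percentages.
#' @examples
#' weighted_residuals(c(120, 100), c(114, 110))
#' @export
weighted_residuals <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  if (any(observed <= 0)) abort("`observed` must be positive.")
  100 * (observed - predicted) / observed
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n − 1) standard deviation.
#' Computed per subject across days it measures intra-individual
#' variability; pooled across all subjects' day-level estimates it measures
#' inter-individual variability.
#'
#' @param x Numeric vector, length at least 2, with non-zero mean.
#' @return The coefficient of variation (%).
#' @examples
#' cv_percent(c(90, 110))
#' @export
cv_percent <- function(x) {
  if (length(x) < 2) abort("CV needs at least two values.")
  m <- mean(x)
  if (m == 0) abort("CV undefined for zero mean.")
  100 * sd(x) / m
}

param_summary_cols <- function(df) {
  out <- list(n_days = nrow(df))
  for (p in c("base", "incr", "k", "t1", "t2")) {
    v <- df[[p]]
    out[[paste0(p, "_median")]] <- median(v)
    out[[paste0(p, "_min")]] <- min(v)
    out[[paste0(p, "_max")]] <- max(v)
  }
  out$cv_base <- if (nrow(df) >= 2 && mean(df$base) != 0) cv_percent(df$base) else NA_real_
  out$cv_incr <- if (nrow(df) >= 2 && mean(df$incr) != 0) cv_percent(df$incr) else NA_real_
  as_tibble(out)
}

#' Summaries of parameter estimates and their variability
#'
#' Condenses day-level fits into the median and range (min–max) of each
#' parameter plus coefficients of variation of `base` and `incr`.
#' `level = "subject"` summarises each subject's fitted days
#' (intra-individual variability); `level = "population"` pools the
#' day-level estimates of all subjects (inter-individual variability, the
#' "overall" row of a summary table). Skipped (unfitted) days are excluded.
#' A CV over fewer than two fitted days is reported as `NA`.
#'
#' @param x A [fit_bp()] result, or a tidy day-level parameter table with
#'   columns `subject_id`, `channel`, `variant`, `base`, `incr`, `k`, `t1`,
#'   `t2` and (optionally) `fitted`.
#' @param level `"subject"` or `"population"`.
#' @return A tibble with one row per subject × channel × variant (or per
#'   channel × variant for the population level): `n_days`,
#'   `<param>_median`, `<param>_min`, `<param>_max` for each parameter, and
#'   `cv_base`, `cv_incr` (%).
#' @examples
#' sim <- simulate_bp(bp_sim_config(n_subjects = 2, n_days = 3), seed = 1)
#' fit <- fit_bp(sim$measurements, channels = "systolic")
#' summarize_bp(fit, level = "subject")
#' @export
summarize_bp <- function(x, level = c("subject", "population")) {
  level <- match.arg(level)
  df <- if (inherits(x, "bp_fit")) tidy(x) else as_tibble(x)
  need <- c("subject_id", "channel", "variant", "base", "incr", "k", "t1", "t2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) abort(paste0("Missing column(s): ", toString(missing), "."))
  if ("fitted" %in% names(df)) df <- filter(df, .data$fitted)
  if (nrow(df) == 0) abort("No fitted days to summarise.")
  if (level == "subject") {
    df %>%
      group_by(.data$subject_id, .data$channel, .data$variant) %>%
      dplyr::group_modify(~param_summary_cols(.x)) %>%
      ungroup()
  } else {
    if (dplyr::n_distinct(df$subject_id) < 2) {
      abort("Population summary needs at least two subjects.")
    }
    df %>%
      group_by(.data$channel, .data$variant) %>%
      dplyr::group_modify(~param_summary_cols(.x)) %>%
      ungroup() %>%
      mutate(subject_id = "overall", .before = 1)
  }
}
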