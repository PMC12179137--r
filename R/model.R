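#' Circadian blood-pressure model parameters
#'
#' Bundles the five parameters of the piecewise-exponential circadian
#' blood-pressure curve into a validated parameter set.
#'
#' The model describes one subject-day as a nocturnal baseline `base` from
#' which pressure rises after wake time `t1` towards a daytime plateau
#' `base + incr`, and decays back towards `base` after bedtime `t2`. Both
#' transitions are exponential with a common rate constant `k`.
#'
#' @param base Nocturnal baseline pressure (mmHg); must be positive.
#' @param incr Daytime increment above baseline (mmHg); must be non-negative.
#'   `base + incr` is the daytime plateau.
#' @param k Exponential rate constant of the morning rise and the
#'   evening/overnight decay (per hour); must be positive.
#' @param t1 Wake time, decimal hours after midnight; `0 < t1 < t2`.
#' @param t2 Bedtime, decimal hours after midnight; may exceed 24 for
#'   bedtimes past midnight (bounded at 25 under the default fitting bounds).
#'
#' @return A named numeric vector of class `"bp_params"` with elements
#'   `base`, `incr`, `k`, `t1`, `t2`.
#' @examples
#' p <- bp_params(base = 100, incr = 20, k = 0.3, t1 = 5, t2 = 22)
#' bp_predict(p, t = c(3, 10, 23))
#' @export
bp_params <- function(base, incr, k, t1, t2) {
  p <- c(base = as.numeric(base), incr = as.numeric(incr), k = as.numeric(k),
         t1 = as.numeric(t1), t2 = as.numeric(t2))
  validate_bp_params(p)
  structure(p, class = "bp_params")
}

validate_bp_params <- function(p) {
  if (length(p) != 5L || anyNA(p) || any(!is.finite(p))) {
    abort("bp_params requires five finite values: base, incr, k, t1, t2.")
  }
  if (p[["base"]] <= 0) abort("`base` must be positive.")
  if (p[["incr"]] < 0) abort("`incr` must be non-negative.")
  if (p[["k"]] <= 0) abort("`k` must be positive.")
  if (p[["t1"]] <= 0) abort("`t1` must be positive.")
  if (p[["t2"]] <= p[["t1"]]) abort("`t2` must exceed `t1`.")
  invisible(p)
}

as_bp_params <- function(x) {
  if (inherits(x, "bp_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort("Expected exactly one row of parameters.")
    x <- unlist(x[, c("base", "incr", "k", "t1", "t2")])
  }
  bp_params(x[["base"]], x[["incr"]], x[["k"]], x[["t1"]], x[["t2"]])
}

#' @export
print.bp_params <- function(x, ...) {
  cat("<bp_params>  base", format(x[["base"]]), "mmHg | incr",
      format(x[["incr"]]), "mmHg | k", format(x[["k"]]), "/h | wake",
      format(x[["t1"]]), "h | bed", format(x[["t2"]]), "h\n")
  invisible(x)
}

#' Classify clock time into circadian model phase
#'
#' Assigns each time of day to the model branch it falls in: `pre_wake`
#' (night before waking, `t < t1`), `wake` (daytime, `t1 <= t < min(t2, 24)`)
#' or `post_bed` (night after bedtime, `t >= t2`, only reachable when
#' `t2 < 24`). Boundaries are half-open with the wake phase closed at `t1`;
#' the curve is continuous across both boundaries, so the closure convention
#' does not affect predicted values.
#'
#' @param t Numeric vector of decimal hours in `[0, 24)`.
#' @param params A [bp_params()] parameter set.
#' @return A character vector in `c("pre_wake", "wake", "post_bed")`.
#' @examples
#' p <- bp_params(100, 20, 0.3, 5, 22)
#' bp_phase(c(3, 10, 23), p)
#' @export
bp_phase <- function(t, params) {
  params <- as_bp_params(params)
  check_hours(t)
  out <- rep("wake", length(t))
  out[t < params[["t1"]]] <- "pre_wake"
  out[t >= params[["t2"]]] <- "post_bed"
  out
}

check_hours <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0) || any(t >= 24)) {
    abort("`t` must be numeric hours in [0, 24).")
  }
  invisible(t)
}

#' Predict blood pressure from the piecewise-exponential model
#'
#' Evaluates the circadian blood-pressure curve at clock times `t` for one
#' day's parameters. In the wake phase the pressure rises exponentially from
#' the baseline towards `base + incr`; after bedtime it decays back towards
#' `base`; before wake time it continues the overnight decay, measured as
#' elapsed time since the previous bedtime (`t + 24 - t2`, floored at zero
#' for bedtimes past midnight).
#'
#' With `carry` supplied, the extended model is evaluated: the pre-wake
#' segment uses the previous day's baseline and increment (`carry`) while
#' keeping the current day's `k`, `t1` and `t2`, assigning the sleep phase
#' before waking to the previous physiological day. Wake and post-bed
#' segments are unaffected by `carry`.
#'
#' @inheritParams bp_phase
#' @param carry Optional previous-day carry: a numeric vector or list with
#'   elements `base` and `incr`, or `NULL` (default) for the basic model.
#' @return Numeric vector of predicted pressures (mmHg), same length as `t`.
#' @examples
#' p <- bp_params(100, 20, 0.3, 5, 22)
#' bp_predict(p, c(3, 10, 23))
#' bp_predict(p, 3, carry = c(base = 90, incr = 10))
#' @export
bp_predict <- function(params, t, carry = NULL) {
  params <- as_bp_params(params)
  check_hours(t)
  if (!is.null(carry)) carry <- check_carry(carry)
  base <- params[["base"]]; incr <- params[["incr"]]; k <- params[["k"]]
  t1 <- params[["t1"]]; t2 <- params[["t2"]]
  # amplitude reached at bedtime; common to both night branches
  amp <- incr * (1 - exp(-k * (t2 - t1)))
  pred <- numeric(length(t))
  phase <- bp_phase(t, params)
  w <- phase == "wake"
  pred[w] <- base + incr * (1 - exp(-k * (t[w] - t1)))
  pb <- phase == "post_bed"
  pred[pb] <- base + amp * exp(-k * (t[pb] - t2))
  pw <- phase == "pre_wake"
  if (any(pw)) {
    tau <- pmax(t[pw] + 24 - t2, 0)
    if (is.null(carry)) {
      pred[pw] <- base + amp * exp(-k * tau)
    } else {
      amp_prev <- carry[["incr"]] * (1 - exp(-k * (t2 - t1)))
      pred[pw] <- carry[["base"]] + amp_prev * exp(-k * tau)
    }
  }
  pred
}

check_carry <- function(carry) {
  carry <- unlist(carry)
  if (!all(c("base", "incr") %in% names(carry))) {
    abort("`carry` must have elements `base` and `incr`.")
  }
  carry <- carry[c("base", "incr")]
  if (anyNA(carry) || carry[["base"]] <= 0 || carry[["incr"]] < 0) {
    abort("`carry` must have base > 0 and incr >= 0.")
  }
  carry
}

#' Evaluate a multi-day blood-pressure profile
#'
#' Stitches per-day parameter sets into one continuous multi-day prediction,
#' as drawn over 14-day recordings. Each evaluation time is matched to its
#' day's parameters; under the extended variant the pre-wake segment of day
#' `d` uses day `d - 1`'s `base` and `incr` as the carry, and the first day
#' carries its own values (equivalent to the basic model there).
#'
#' @param times A data frame with columns `day_index` (integer, matching
#'   `day_params$day_index`) and `t` (decimal hours in `[0, 24)`).
#' @param day_params A data frame with columns `day_index`, `base`, `incr`,
#'   `k`, `t1`, `t2`: one row per day, ordered or orderable by `day_index`.
#' @param variant `"basic"` or `"extended"`.
#' @return `times` as a tibble with a `pred` column (mmHg) appended.
#' @examples
#' days <- tibble::tibble(day_index = 0:1, base = c(100, 95), incr = 20,
#'                        k = 0.3, t1 = 5, t2 = 22)
#' grid <- tidyr::expand_grid(day_index = 0:1, t = seq(0, 23.5, by = 0.5))
#' head(bp_profile(grid, days, variant = "extended"))
#' @export
bp_profile <- function(times, day_params, variant = c("basic", "extended")) {
  variant <- match.arg(variant)
  if (!all(c("day_index", "t") %in% names(times))) {
    abort("`times` needs columns `day_index` and `t`.")
  }
  day_params <- as_tibble(day_params) %>% arrange(.data$day_index)
  if (anyDuplicated(day_params$day_index)) {
    abort("`day_params` must have one row per `day_index`.")
  }
  missing_days <- setdiff(unique(times$day_index), day_params$day_index)
  if (length(missing_days) > 0) {
    abort(paste0("No parameters for day index ", toString(missing_days), "."))
  }
  times <- as_tibble(times)
  pred <- numeric(nrow(times))
  for (i in seq_len(nrow(day_params))) {
    d <- day_params$day_index[i]
    sel <- which(times$day_index == d)
    if (length(sel) == 0) next
    p <- as_bp_params(day_params[i, ])
    carry <- NULL
    if (variant == "extended") {
      prev <- if (i > 1L) day_params[i - 1L, ] else day_params[i, ]
      carry <- c(base = prev$base, incr = prev$incr)
    }
    pred[sel] <- bp_predict(p, times$t[sel], carry = carry)
  }
  times$pred <- pred
  times
}

#' Day plateau and nocturnal trough of a fitted profile
#'
#' Quantifies nocturnal dipping from model parameters: as the overnight
#' exponential decay completes, the predicted pressure approaches the
#' `base` parameter (nocturnal trough); as the wake-phase rise saturates
#' (`k * (t - t1)` large), it approaches `base + incr` (daytime plateau).
#' The nocturnal dip is their difference, `incr`, also expressed as a
#' percentage of the plateau — the conventional dipping percentage.
#'
#' @param x A [bp_params()] set or a data frame with columns `base` and
#'   `incr` (e.g. a row of [tidy()] output or a summary-table median row).
#' @return A tibble with columns `trough`, `plateau`, `dip` (all mmHg) and
#'   `dip_pct` (%), one row per input row.
#' @examples
#' bp_dipping(bp_params(101.7, 20.8, 0.4, 5.4, 22.4))
#' @export
bp_dipping <- function(x) {
  if (inherits(x, "bp_params")) x <- tibble(base = x[["base"]], incr = x[["incr"]])
  x <- as_tibble(x)
  if (!all(c("base", "incr") %in% names(x))) {
    abort("`x` needs columns `base` and `incr`.")
  }
  tibble(
    trough = x$base,
    plateau = x$base + x$incr,
    dip = x$incr,
    dip_pct = 100 * x$incr / (x$base + x$incr)
  )
}

#' Round to nearest, halves away from zero
#'
#' Decimal rounding with the "halves up" convention used for reporting
#' integer blood-pressure values (in contrast to [round()]'s round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(122.5) # 123
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
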