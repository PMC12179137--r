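#' Default parameter bounds for the bounded least-squares fit
#'
#' Box constraints on (`base`, `incr`, `k`, `t1`, `t2`) enforced during
#' fitting, per channel. Systolic baselines are bounded in 80–200 mmHg,
#' diastolic in 20–120 mmHg; both channels share increment bounds 0–60 mmHg,
#' rate bounds 0.01–2 per hour, wake time 1–11 h and bedtime 18–25 h (a
#' bedtime past 25 h, i.e. 1 a.m., is not considered).
#'
#' @param channel `"systolic"` or `"diastolic"`.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @examples
#' bp_bounds("systolic")
#' @export
bp_bounds <- function(channel = c("systolic", "diastolic")) {
  channel <- match.arg(channel)
  base_lower <- if (channel == "systolic") 80 else 20
  base_upper <- if (channel == "systolic") 200 else 120
  tibble(
    parameter = c("base", "incr", "k", "t1", "t2"),
    lower = c(base_lower, 0, 0.01, 1, 18),
    upper = c(base_upper, 60, 2, 11, 25)
  )
}

bounds_vectors <- function(bounds) {
  bounds <- as_tibble(bounds)
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)))
  lower <- setNames(bounds$lower, bounds$parameter)[c("base", "incr", "k", "t1", "t2")]
  upper <- setNames(bounds$upper, bounds$parameter)[c("base", "incr", "k", "t1", "t2")]
  if (any(lower >= upper)) abort("Bounds must satisfy lower < upper elementwise.")
  list(lower = lower, upper = upper)
}

#' Starting values for one day's fit
#'
#' The baseline starts at the day's minimum observed pressure and the
#' increment at the observed range (max minus min); the rate, wake time and
#' bedtime start at 0.3 per hour, 5 h and 22 h. Each component is clipped
#' into the fitting bounds.
#'
#' @param t Decimal hours of the day's observations.
#' @param bp Observed pressures (mmHg), same length as `t`.
#' @param bounds Bounds tibble from [bp_bounds()].
#' @return A [bp_params()] starting set.
#' @examples
#' bp_init(c(4, 9, 14, 20), c(95, 110, 130, 102), bp_bounds("systolic"))
#' @export
bp_init <- function(t, bp, bounds = bp_bounds("systolic")) {
  if (length(bp) == 0) abort("No observations to initialise from.")
  if (anyNA(bp) || any(!is.finite(bp))) abort("Non-finite pressures.")
  b <- bounds_vectors(bounds)
  init <- c(base = min(bp), incr = max(bp) - min(bp), k = 0.3, t1 = 5, t2 = 22)
  init <- pmin(pmax(init, b$lower), b$upper)
  structure(init, class = "bp_params")
}

#' Fitting control settings
#'
#' @param ftol,ptol Relative function / parameter convergence tolerances of
#'   the bounded Levenberg–Marquardt solver.
#' @param maxiter Maximum solver iterations.
#' @param min_obs Minimum observations required to fit a day; days below it
#'   are skipped and flagged rather than fitted (default 6, one more than
#'   the number of free parameters).
#' @param t1_starts,k_starts Restart grid: additional starting values of
#'   the wake time `t1` and rate `k` the solver is restarted from (all
#'   combinations; the lowest-sse solution is kept). The objective can have
#'   local minima in both; `numeric(0)` for both disables restarts.
#' @return A list of class `"bp_control"`.
#' @export
bp_control <- function(ftol = 1e-10, ptol = 1e-10, maxiter = 200L, min_obs = 6L,
                       t1_starts = c(2, 3, 7, 9), k_starts = 1.2) {
  stopifnot(ftol > 0, ptol > 0, maxiter >= 1, min_obs >= 1)
  structure(list(ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 min_obs = as.integer(min_obs), t1_starts = t1_starts,
                 k_starts = k_starts),
            class = "bp_control")
}

empty_day_row <- function(subject_id, day_index, channel, variant, n_obs) {
  tibble(
    subject_id = subject_id, day_index = day_index, channel = channel,
    variant = variant, base = NA_real_, incr = NA_real_, k = NA_real_,
    t1 = NA_real_, t2 = NA_real_, carry_base = NA_real_, carry_incr = NA_real_,
    n_obs = n_obs, fitted = FALSE, converged = NA, sse = NA_real_,
    t = list(numeric(0)), observed = list(numeric(0)),
    residuals = list(numeric(0)), weighted_residuals = list(numeric(0))
  )
}

#' Fit one subject-day by bounded nonlinear least squares
#'
#' Minimises the unweighted sum of squared residuals of the piecewise
#' exponential model over the five parameters within box constraints,
#' starting from [bp_init()] values (or a supplied `init`), using bounded
#' Levenberg–Marquardt ([minpack.lm::nls.lm()]). For the extended variant a
#' previous-day `carry` (fixed constants) replaces the baseline and
#' increment in the pre-wake segment. Days with fewer than
#' `control$min_obs` observations are returned skipped and flagged; if the
#' solver stops without meeting its convergence tolerances the best iterate
#' is returned with `converged = FALSE`.
#'
#' @param data A data frame with columns `t` (hours in `[0, 24)`) and `bp`
#'   (observed pressure, mmHg).
#' @param variant `"basic"` or `"extended"`.
#' @param carry Previous-day carry (`base`, `incr`) for the extended
#'   variant, or `NULL`.
#' @param bounds Bounds tibble from [bp_bounds()].
#' @param init Optional starting [bp_params()]; defaults to [bp_init()].
#' @param control A [bp_control()] list.
#' @param subject_id,day_index,channel Identifiers stored in the result.
#' @return A one-row tibble: identifiers, fitted parameters, the carry used,
#'   `n_obs`, `fitted` and `converged` flags, `sse`, and list-columns `t`,
#'   `observed`, `residuals` (observed − predicted, mmHg) and
#'   `weighted_residuals` (%).
#' @examples
#' p <- bp_params(105, 18, 0.5, 6, 22)
#' t <- seq(0.25, 23.75, length.out = 48)
#' fit_bp_day(data.frame(t = t, bp = bp_predict(p, t)))
#' @export
fit_bp_day <- function(data, variant = c("basic", "extended"), carry = NULL,
                       bounds = bp_bounds("systolic"), init = NULL,
                       control = bp_control(), subject_id = NA_character_,
                       day_index = 0L, channel = "systolic") {
  variant <- match.arg(variant)
  if (!all(c("t", "bp") %in% names(data))) abort("`data` needs columns `t` and `bp`.")
  data <- as_tibble(data) %>% arrange(.data$t)
  n <- nrow(data)
  if (n > 0 && (anyNA(data$bp) || any(!is.finite(data$bp)))) {
    abort("Non-finite blood-pressure values.")
  }
  if (n < control$min_obs) {
    return(empty_day_row(subject_id, day_index, channel, variant, n))
  }
  check_hours(data$t)
  if (!is.null(carry)) carry <- check_carry(carry)
  if (variant == "extended" && is.null(carry)) variant_eff <- "basic" else variant_eff <- variant
  b <- bounds_vectors(bounds)
  if (is.null(init)) init <- bp_init(data$t, data$bp, bounds)
  # keep the start strictly usable: clip into the box
  start <- pmin(pmax(unclass(init), b$lower), b$upper)

  tt <- data$t
  yy <- data$bp
  resid_fn <- function(par) {
    p <- structure(par, names = c("base", "incr", "k", "t1", "t2"))
    yy - bp_predict_raw(p, tt, carry = if (variant_eff == "extended") carry else NULL)
  }
  # The objective is multimodal in the wake time (kinks park at data
  # points) and in the rate, so the solver is restarted from a fixed grid
  # of wake-time/rate starts and the lowest-sse solution kept. The supplied
  # start is always the first candidate, so the solution never inflates
  # its objective.
  starts <- list()
  for (k_alt in unique(c(start[["k"]], control$k_starts))) {
    for (t1_alt in unique(c(start[["t1"]], control$t1_starts))) {
      alt <- start
      alt[["k"]] <- min(max(k_alt, b$lower[["k"]]), b$upper[["k"]])
      alt[["t1"]] <- min(max(t1_alt, b$lower[["t1"]]), b$upper[["t1"]])
      starts <- c(starts, list(alt))
    }
  }
  fit <- NULL
  best_sse <- Inf
  for (st in starts) {
    cand <- minpack.lm::nls.lm(
      par = st, lower = b$lower, upper = b$upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = control$ftol, ptol = control$ptol, maxiter = control$maxiter)
    )
    if (cand$deviance < best_sse - 1e-12) {
      fit <- cand
      best_sse <- cand$deviance
    }
  }
  par <- pmin(pmax(coef(fit), b$lower), b$upper)
  pred <- yy - resid_fn(par)
  resid <- yy - pred
  used_carry <- if (variant_eff == "extended") carry else c(base = par[["base"]], incr = par[["incr"]])
  tibble(
    subject_id = subject_id, day_index = day_index, channel = channel,
    variant = variant,
    base = par[["base"]], incr = par[["incr"]], k = par[["k"]],
    t1 = par[["t1"]], t2 = par[["t2"]],
    carry_base = if (variant == "extended") used_carry[["base"]] else NA_real_,
    carry_incr = if (variant == "extended") used_carry[["incr"]] else NA_real_,
    n_obs = n, fitted = TRUE, converged = fit$info %in% 1:3,
    sse = sum(resid^2),
    t = list(tt), observed = list(yy), residuals = list(resid),
    weighted_residuals = list(weighted_residuals(yy, pred))
  )
}

# Unvalidated fast path used inside the solver loop: parameters supplied by
# the optimiser always lie in the bounds box, and t was checked once.
bp_predict_raw <- function(p, t, carry = NULL) {
  base <- p[["base"]]; incr <- p[["incr"]]; k <- p[["k"]]
  t1 <- p[["t1"]]; t2 <- p[["t2"]]
  amp <- incr * (1 - exp(-k * (t2 - t1)))
  pred <- base + incr * (1 - exp(-k * (t - t1)))
  pb <- t >= t2
  pred[pb] <- base + amp * exp(-k * (t[pb] - t2))
  pw <- t < t1
  if (any(pw)) {
    tau <- pmax(t[pw] + 24 - t2, 0)
    if (is.null(carry)) {
      pred[pw] <- base + amp * exp(-k * tau)
    } else {
      pred[pw] <- carry[["base"]] +
        carry[["incr"]] * (1 - exp(-k * (t2 - t1))) * exp(-k * tau)
    }
  }
  pred
}

fit_bp_subject <- function(data, channel, variant, bounds, control, bp_col) {
  days <- sort(unique(data$day_index))
  rows <- vector("list", length(days))
  last_fitted <- NULL # (base, incr) of most recent fitted day (extended carry)
  for (i in seq_along(days)) {
    d <- days[i]
    day_dat <- data[data$day_index == d, ]
    obs <- tibble(t = day_dat$t, bp = day_dat[[bp_col]])
    carry <- if (variant == "extended") last_fitted else NULL
    row <- fit_bp_day(obs, variant = variant, carry = carry, bounds = bounds,
                      control = control, subject_id = data$subject_id[1],
                      day_index = d, channel = channel)
    if (row$fitted) last_fitted <- c(base = row$base, incr = row$incr)
    rows[[i]] <- row
  }
  bind_rows(rows)
}

#' Fit the circadian model across subjects, days and channels
#'
#' The estimation double loop: measurements are split by subject (outer
#' loop), then each subject's days are fitted in chronological order (inner
#' loop), independently for the systolic and diastolic channels. Under the
#' extended variant, day `d`'s pre-wake segment carries the fitted `base`
#' and `incr` of the most recent previously fitted day; the first fitted day
#' of a subject has no predecessor and is fitted with the carry tied to its
#' own parameters, which reduces to the basic model.
#'
#' Fitting is deterministic: re-running on the same data and settings gives
#' an identical parameter table.
#'
#' @param data A data frame of measurements with columns `subject_id`, `t`
#'   (decimal hours in `[0, 24)`), `day_index` (integer) and the pressure
#'   columns `sbp` and/or `dbp` (mmHg). If `day_index`/`t` are absent but a
#'   `timestamp` column is present, they are derived as in [read_bp_csv()].
#' @param variant `"basic"` or `"extended"`.
#' @param channels Channels to fit, subset of `c("systolic", "diastolic")`.
#' @param bounds Optional named list of bounds tibbles per channel, e.g.
#'   `list(systolic = bp_bounds("systolic"))`; defaults to [bp_bounds()].
#' @param control A [bp_control()] list.
#' @return An object of class `"bp_fit"`: a list with `fits` (day-level
#'   tibble as in [fit_bp_day()]), `variant`, `channels` and `control`.
#'   Use [tidy()], [glance()], [augment()], [summarize_bp()] and
#'   [autoplot()] on it.
#' @examples
#' sim <- simulate_bp(bp_sim_config(n_subjects = 1, n_days = 2), seed = 1)
#' fit <- fit_bp(sim$measurements, channels = "systolic")
#' tidy(fit)
#' @export
fit_bp <- function(data, variant = c("basic", "extended"),
                   channels = c("systolic", "diastolic"),
                   bounds = NULL, control = bp_control()) {
  variant <- match.arg(variant)
  channels <- match.arg(channels, several.ok = TRUE)
  data <- prepare_measurements(data, require = channel_cols(channels))
  if (nrow(data) == 0) abort("No measurements to fit.")
  fits <- purrr::map(channels, function(ch) {
    col <- if (ch == "systolic") "sbp" else "dbp"
    bnd <- bounds[[ch]] %||% bp_bounds(ch)
    data %>%
      dplyr::group_split(.data$subject_id) %>%
      purrr::map(fit_bp_subject, channel = ch, variant = variant,
                 bounds = bnd, control = control, bp_col = col) %>%
      bind_rows()
  }) %>% bind_rows()
  structure(list(fits = fits, variant = variant, channels = channels,
                 control = control),
            class = "bp_fit")
}

channel_cols <- function(channels) {
  c(systolic = "sbp", diastolic = "dbp")[channels]
}

# Ensures subject_id, day_index, t and the requested pressure columns exist,
# deriving day_index/t from a timestamp column when needed.
prepare_measurements <- function(data, require = c("sbp", "dbp")) {
  data <- as_tibble(data)
  if (!"subject_id" %in% names(data)) abort("`data` needs a `subject_id` column.")
  if (!all(c("day_index", "t") %in% names(data))) {
    if (!"timestamp" %in% names(data)) {
      abort("`data` needs `day_index` and `t`, or a `timestamp` column.")
    }
    ts <- parse_timestamps(data$timestamp)
    data <- data %>%
      mutate(.date = ts$date, t = ts$t) %>%
      group_by(.data$subject_id) %>%
      mutate(day_index = as.integer(.data$.date - min(.data$.date))) %>%
      ungroup() %>%
      select(-".date")
  }
  missing <- setdiff(require, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing pressure column(s): ", toString(missing), "."))
  }
  data %>% arrange(.data$subject_id, .data$day_index, .data$t)
}

#' @export
print.bp_fit <- function(x, ...) {
  g <- glance(x)
  cat("<bp_fit> ", x$variant, " model; ", g$n_subjects, " subject(s), ",
      g$n_days, " subject-day-channel fits (", g$n_skipped, " skipped, ",
      g$n_nonconverged, " non-converged)\n", sep = "")
  invisible(x)
}

#' @rdname fit_bp
#' @param x A `bp_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bp_fit <- function(x, ...) {
  x$fits %>%
    select(-all_of(c("t", "observed", "residuals", "weighted_residuals")))
}

#' @rdname fit_bp
#' @exportS3Method generics::glance
glance.bp_fit <- function(x, ...) {
  f <- x$fits
  tibble(
    variant = x$variant,
    n_subjects = dplyr::n_distinct(f$subject_id),
    n_days = nrow(f),
    n_fitted = sum(f$fitted),
    n_skipped = sum(!f$fitted),
    n_nonconverged = sum(f$fitted & !f$converged),
    n_obs = sum(f$n_obs),
    total_sse = sum(f$sse, na.rm = TRUE),
    rmse = sqrt(sum(f$sse, na.rm = TRUE) / max(sum(f$n_obs[f$fitted]), 1))
  )
}

#' @rdname fit_bp
#' @exportS3Method generics::augment
augment.bp_fit <- function(x, ...) {
  x$fits %>%
    filter(.data$fitted) %>%
    select(all_of(c("subject_id", "day_index", "channel", "variant",
                    "t", "observed", "residuals", "weighted_residuals"))) %>%
    tidyr::unnest(all_of(c("t", "observed", "residuals", "weighted_residuals"))) %>%
    mutate(.fitted = .data$observed - .data$residuals) %>%
    dplyr::rename(.resid = "residuals", .wresid = "weighted_residuals")
}
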