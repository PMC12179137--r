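#' Configuration for the synthetic cuffless-monitor generator
#'
#' Defines the population a simulated study draws from. Defaults emulate a
#' two-week cuffless-monitor recording of six healthy young adults: 14 days
#' per subject, on average 32 automated measurements per day at
#' unpredictable times, a daytime systolic plateau near 120 mmHg and a
#' nocturnal trough near 104 mmHg, with day-to-day (within-subject)
#' parameter variation smaller than the between-subject variation.
#'
#' Subject-level parameter means are drawn from truncated normal
#' distributions inside the fitting bounds; each day then perturbs `base`
#' and `incr` with within-subject noise (clipped into bounds) while `k`,
#' `t1` and `t2` stay at the subject level — wake/bed times and the rate are
#' treated as subject traits shared by the systolic and diastolic channels.
#'
#' @param n_subjects,n_days Cohort shape (defaults 6 subjects, 14 days).
#' @param mean_obs_per_day Mean daily measurement count (Poisson, default 32).
#' @param noise_sd_sys,noise_sd_dia Measurement noise sd (mmHg; 5 and 4).
#' @param mean_sys,mean_dia Named vectors of population means for
#'   `base`, `incr`, `k`, `t1`, `t2` per channel.
#' @param sd_between_sys,sd_between_dia Between-subject sds of the same
#'   five parameters.
#' @param sd_within Named vector: within-subject day-to-day sds for `base`
#'   and `incr` (mmHg).
#' @param start_date Calendar date of day 0 for generated timestamps.
#' @return A list of class `"bp_sim_config"`.
#' @export
bp_sim_config <- function(n_subjects = 6, n_days = 14, mean_obs_per_day = 32,
                          noise_sd_sys = 5, noise_sd_dia = 4,
                          mean_sys = c(base = 104, incr = 16, k = 0.33,
                                       t1 = 4.8, t2 = 23.0),
                          mean_dia = c(base = 62, incr = 12, k = 0.33,
                                       t1 = 4.8, t2 = 23.0),
                          sd_between_sys = c(base = 10, incr = 5, k = 0.10,
                                             t1 = 1.0, t2 = 0.8),
                          sd_between_dia = c(base = 7, incr = 4, k = 0.10,
                                             t1 = 1.0, t2 = 0.8),
                          sd_within = c(base = 5, incr = 4),
                          start_date = as.Date("2023-05-01")) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
              mean_obs_per_day = mean_obs_per_day,
              noise_sd_sys = noise_sd_sys, noise_sd_dia = noise_sd_dia,
              mean_sys = mean_sys, mean_dia = mean_dia,
              sd_between_sys = sd_between_sys, sd_between_dia = sd_between_dia,
              sd_within = sd_within, start_date = as.Date(start_date))
  validate_sim_config(cfg)
  structure(cfg, class = "bp_sim_config")
}

validate_sim_config <- function(cfg) {
  pn <- c("base", "incr", "k", "t1", "t2")
  if (cfg$n_subjects < 1 || cfg$n_days < 1) abort("Counts must be >= 1.")
  if (cfg$mean_obs_per_day <= 0) abort("`mean_obs_per_day` must be positive.")
  sds <- c(cfg$noise_sd_sys, cfg$noise_sd_dia, cfg$sd_between_sys,
           cfg$sd_between_dia, cfg$sd_within)
  if (any(sds < 0)) abort("Standard deviations must be non-negative.")
  for (ch in c("systolic", "diastolic")) {
    m <- if (ch == "systolic") cfg$mean_sys else cfg$mean_dia
    if (!all(pn %in% names(m))) abort("Parameter means need names base, incr, k, t1, t2.")
    b <- bounds_vectors(bp_bounds(ch))
    if (any(m[pn] < b$lower | m[pn] > b$upper)) {
      abort(paste("Population means must lie inside the", ch, "fitting bounds."))
    }
  }
  invisible(cfg)
}

# Normal truncated to [lower, upper] by rejection; falls back to clipping
# (relevant only for means very close to a bound).
rtruncnorm_vec <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

#' Draw ground-truth model parameters for a simulated cohort
#'
#' @param config A [bp_sim_config()].
#' @return A tibble of truth records: `subject_id`, `day_index`, `channel`,
#'   `base`, `incr`, `k`, `t1`, `t2` — the parameters each day's
#'   measurements are generated from. Uses the current RNG state; seed via
#'   [simulate_bp()] or [set.seed()].
#' @export
bp_sim_truth <- function(config = bp_sim_config()) {
  validate_sim_config(config)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  pn <- c("base", "incr", "k", "t1", "t2")
  rows <- list()
  for (s in seq_along(ids)) {
    # shared chronotype: k, t1, t2 drawn once per subject from the systolic
    # spread, reused for both channels
    bsys <- bounds_vectors(bp_bounds("systolic"))
    shared <- sapply(c("k", "t1", "t2"), function(p) {
      rtruncnorm_vec(1, config$mean_sys[[p]], config$sd_between_sys[[p]],
                     bsys$lower[[p]], bsys$upper[[p]])
    })
    for (ch in c("systolic", "diastolic")) {
      m <- if (ch == "systolic") config$mean_sys else config$mean_dia
      sb <- if (ch == "systolic") config$sd_between_sys else config$sd_between_dia
      b <- bounds_vectors(bp_bounds(ch))
      subj <- c(
        base = rtruncnorm_vec(1, m[["base"]], sb[["base"]], b$lower[["base"]], b$upper[["base"]]),
        incr = rtruncnorm_vec(1, m[["incr"]], sb[["incr"]], b$lower[["incr"]], b$upper[["incr"]]),
        shared
      )
      day_base <- rtruncnorm_vec(config$n_days, subj[["base"]],
                                 config$sd_within[["base"]],
                                 b$lower[["base"]], b$upper[["base"]])
      day_incr <- rtruncnorm_vec(config$n_days, subj[["incr"]],
                                 config$sd_within[["incr"]],
                                 b$lower[["incr"]], b$upper[["incr"]])
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = ids[s], day_index = seq_len(config$n_days) - 1L,
        channel = ch, base = day_base, incr = day_incr,
        k = subj[["k"]], t1 = subj[["t1"]], t2 = subj[["t2"]]
      )
    }
  }
  bind_rows(rows)
}

#' Draw one day's measurement times
#'
#' The cuffless monitor measures automatically at times the wearer does not
#' control; the generator draws the daily count from a Poisson distribution
#' with mean `mean_obs_per_day` and spreads the times uniformly over the
#' 24-hour day.
#'
#' @param config A [bp_sim_config()].
#' @return Sorted numeric vector of decimal hours in `[0, 24)`.
#' @export
bp_sim_times <- function(config = bp_sim_config()) {
  n <- rpois(1, config$mean_obs_per_day)
  sort(runif(n, 0, 24))
}

#' Simulate a multi-day cuffless blood-pressure dataset with known truth
#'
#' Draws ground-truth parameters per subject-day-channel
#' ([bp_sim_truth()]), samples measurement times ([bp_sim_times()]) and
#' emits noisy observations on the basic model curve:
#' `sbp = model(truth_sys, t) + N(0, noise_sd_sys)` and likewise for `dbp`.
#' A diastolic draw at or above its systolic partner is redrawn so every
#' record satisfies `sbp > dbp > 0`.
#'
#' @param config A [bp_sim_config()].
#' @param seed Integer seed; identical `config` + `seed` reproduce the
#'   dataset exactly. `NULL` uses the current RNG state.
#' @return A list of class `"bp_sim"`: `measurements` (tibble with
#'   `subject_id`, `timestamp` (POSIXct, UTC), `day_index`, `t`, `sbp`,
#'   `dbp`), `truth` (tibble from [bp_sim_truth()]) and `config`.
#' @examples
#' sim <- simulate_bp(bp_sim_config(n_subjects = 2, n_days = 3), seed = 42)
#' dplyr::count(sim$measurements, subject_id)
#' @export
simulate_bp <- function(config = bp_sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  truth <- bp_sim_truth(config)
  key <- function(ch) truth[truth$channel == ch, ]
  sys_t <- key("systolic"); dia_t <- key("diastolic")
  rows <- list()
  for (i in seq_len(nrow(sys_t))) {
    tr_s <- sys_t[i, ]; tr_d <- dia_t[i, ]
    tt <- bp_sim_times(config)
    if (length(tt) == 0) next
    mu_s <- bp_predict(as_bp_params(tr_s[, c("base", "incr", "k", "t1", "t2")]), tt)
    mu_d <- bp_predict(as_bp_params(tr_d[, c("base", "incr", "k", "t1", "t2")]), tt)
    sbp <- mu_s + rnorm(length(tt), 0, config$noise_sd_sys)
    dbp <- mu_d + rnorm(length(tt), 0, config$noise_sd_dia)
    for (j in 1:100) {
      bad <- dbp >= sbp | dbp <= 0
      if (!any(bad)) break
      dbp[bad] <- mu_d[bad] + rnorm(sum(bad), 0, config$noise_sd_dia)
    }
    dbp <- pmin(dbp, sbp - 1) # guard for pathological noise settings
    rows[[length(rows) + 1L]] <- tibble(
      subject_id = tr_s$subject_id, day_index = tr_s$day_index,
      t = tt, sbp = sbp, dbp = dbp
    )
  }
  meas <- bind_rows(rows) %>%
    mutate(timestamp = as.POSIXct(config$start_date, tz = "UTC") +
             (.data$day_index * 24 + .data$t) * 3600, .after = "subject_id") %>%
    arrange(.data$subject_id, .data$day_index, .data$t)
  structure(list(measurements = meas, truth = truth, config = config),
            class = "bp_sim")
}

#' @export
print.bp_sim <- function(x, ...) {
  cat("<bp_sim> ", x$config$n_subjects, " subject(s) x ", x$config$n_days,
      " day(s); ", nrow(x$measurements), " measurements\n", sep = "")
  invisible(x)
}
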