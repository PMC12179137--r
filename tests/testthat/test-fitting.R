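test_that("default bounds match the per-channel port-style boxes", {
  s <- bp_bounds("systolic")
  d <- bp_bounds("diastolic")
  expect_equal(s$lower, c(80, 0, 0.01, 1, 18))
  expect_equal(s$upper, c(200, 60, 2, 11, 25))
  expect_equal(d$lower[1], 20)
  expect_equal(d$upper[1], 120)
  # both channels share the incr/k/t1/t2 box
  expect_equal(s[-1, ], d[-1, ])
  expect_error(bp_bounds("mean arterial"))
})

test_that("starting values come from the day's extrema, clipped into bounds", {
  init <- bp_init(c(4, 9, 14, 20), c(95, 110, 130, 102))
  expect_equal(unclass(init),
               c(base = 95, incr = 35, k = 0.3, t1 = 5, t2 = 22))
  flat <- bp_init(c(4, 9), c(100, 100))
  expect_equal(flat[["incr"]], 0)
  # a day minimum below the systolic floor is clipped to the bound
  clipped <- bp_init(c(4, 9, 14), c(70, 90, 120))
  expect_equal(clipped[["base"]], 80)
  expect_error(bp_init(numeric(0), numeric(0)), "No observations")
})

test_that("noise-free days are recovered to tight relative error", {
  truths <- list(c(105, 18, 0.5, 6, 22), c(92, 30, 0.8, 4, 20.5),
                 c(130, 12, 0.2, 7, 23), c(100, 25, 1.2, 3.5, 21))
  for (tr in truths) {
    day <- make_day(tr[1], tr[2], tr[3], tr[4], tr[5])
    fit <- fit_bp_day(day)
    est <- unlist(fit[c("base", "incr", "k", "t1", "t2")])
    expect_lt(max(abs(est[1:2] - tr[1:2]) / tr[1:2]), 1e-3)
    expect_lt(max(abs(est[3:5] - tr[3:5]) / tr[3:5]), 1e-2)
    expect_lt(fit$sse, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("sparse days are skipped and flagged, not fitted", {
  fit <- fit_bp_day(data.frame(t = c(2, 8, 14, 20), bp = c(100, 115, 118, 116)))
  expect_false(fit$fitted)
  expect_true(is.na(fit$base))
  expect_equal(fit$n_obs, 4L)
  # the threshold is configurable
  five <- data.frame(t = c(2, 8, 14, 18, 20), bp = c(100, 115, 118, 117, 116))
  expect_false(fit_bp_day(five)$fitted)
  fit2 <- fit_bp_day(five, control = bp_control(min_obs = 5))
  expect_true(fit2$fitted)
  expect_error(fit_bp_day(data.frame(t = c(2, 8, 14, 20, 21, 22),
                                     bp = c(100, 115, NA, 116, 117, 115))),
               "Non-finite")
})

test_that("a constant profile drives incr to its lower bound", {
  day <- data.frame(t = even_grid(24), bp = rep(100, 24))
  fit <- fit_bp_day(day)
  expect_equal(fit$incr, 0, tolerance = 1e-6)
  expect_equal(fit$base, 100, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-8)
})

test_that("solutions respect bounds and never inflate the objective", {
  set.seed(42)
  for (i in 1:8) {
    day <- make_day(100 + i * 3, 20, 0.4 + 0.1 * i, 5, 22, n = 30, sd = 6)
    init <- bp_init(day$t, day$bp)
    fit <- fit_bp_day(day, init = init)
    b <- bp_bounds("systolic")
    est <- unlist(fit[c("base", "incr", "k", "t1", "t2")])
    expect_true(all(est >= b$lower - 1e-12 & est <= b$upper + 1e-12))
    sse_init <- sum((day$bp - bp_predict(init, day$t))^2)
    expect_lte(fit$sse, sse_init + 1e-9)
  }
})

test_that("solver agrees with nls(port) as an independent route", {
  b <- bp_bounds("systolic")
  run_port <- function(day) suppressWarnings(stats::nls(
    bp ~ bp_predict(bp_params(base, incr, k, t1, t2), t),
    data = day, algorithm = "port",
    start = as.list(unclass(bp_init(day$t, day$bp))),
    lower = b$lower, upper = b$upper,
    control = stats::nls.control(warnOnly = TRUE)
  ))
  # noise-free: both routes must land on the same (true) optimum
  clean <- make_day(105, 22, 0.5, 6, 22, n = 40)
  ours <- fit_bp_day(clean)
  port <- run_port(clean)
  expect_equal(unlist(ours[c("base", "incr", "k", "t1", "t2")]),
               coef(port), tolerance = 1e-4)
  # noisy: both routes reach the same objective value to within the
  # micro-multimodality induced by the wake/bed kinks
  set.seed(7)
  noisy <- make_day(105, 22, 0.5, 6, 22, n = 40, sd = 4)
  ours_n <- fit_bp_day(noisy)
  port_n <- run_port(noisy)
  sse_port <- sum(residuals(port_n)^2)
  expect_lt(abs(ours_n$sse - sse_port) / sse_port, 1e-3)
})

test_that("the double loop fits every subject-day-channel and is deterministic", {
  sim <- simulate_bp(bp_sim_config(n_subjects = 2, n_days = 3), seed = 5)
  fit <- fit_bp(sim$measurements)
  expect_s3_class(fit, "bp_fit")
  expect_equal(nrow(fit$fits), 2 * 3 * 2)
  expect_setequal(unique(fit$fits$channel), c("systolic", "diastolic"))
  refit <- fit_bp(sim$measurements)
  expect_identical(tidy(fit), tidy(refit))
  # single-subject input equals the per-subject slice of the full fit
  s1 <- dplyr::filter(sim$measurements, subject_id == "S01")
  solo <- fit_bp(s1)
  expect_equal(tidy(solo), dplyr::filter(tidy(fit), subject_id == "S01"))
})

test_that("systolic fits are unaffected by the diastolic channel", {
  sim <- simulate_bp(bp_sim_config(n_subjects = 1, n_days = 2), seed = 9)
  meas <- sim$measurements
  permuted <- dplyr::mutate(meas, dbp = sample(dbp))
  f1 <- fit_bp(meas, channels = "systolic")
  f2 <- fit_bp(permuted, channels = "systolic")
  expect_identical(tidy(f1), tidy(f2))
})

test_that("extended carries chain through the most recent fitted day", {
  p <- c(base = 105, incr = 18, k = 0.5, t1 = 6, t2 = 22)
  meas <- make_subject(p, n_days = 4)
  # cripple day 2: three measurements only -> skipped
  meas <- rbind(meas[meas$day_index != 2, ],
                data.frame(subject_id = "S01", day_index = 2,
                           t = c(8, 12, 16), sbp = c(120, 122, 121),
                           dbp = c(80, 82, 81)))
  fit <- fit_bp(meas, variant = "extended", channels = "systolic")
  td <- tidy(fit)
  expect_equal(td$fitted, c(TRUE, TRUE, FALSE, TRUE))
  # first day's carry is tied to its own fit
  expect_equal(td$carry_base[1], td$base[1])
  expect_equal(td$carry_incr[1], td$incr[1])
  # day 3's carry skips the unfitted day 2 and comes from day 1
  expect_equal(td$carry_base[4], td$base[2])
  expect_equal(td$carry_incr[4], td$incr[2])
})

test_that("timestamps can stand in for day_index/t and empty input errors", {
  sim <- simulate_bp(bp_sim_config(n_subjects = 1, n_days = 2), seed = 3)
  via_ts <- dplyr::select(sim$measurements, subject_id, timestamp, sbp, dbp)
  f1 <- fit_bp(via_ts, channels = "systolic")
  f2 <- fit_bp(sim$measurements, channels = "systolic")
  expect_equal(tidy(f1), tidy(f2), tolerance = 1e-6)
  expect_error(fit_bp(sim$measurements[0, ]), "No measurements")
})

test_that("tidy, glance and augment expose coherent views of a fit", {
  sim <- simulate_bp(bp_sim_config(n_subjects = 2, n_days = 2), seed = 21)
  fit <- fit_bp(sim$measurements, channels = "systolic")
  td <- tidy(fit)
  expect_false(any(c("residuals", "observed") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_days, 4)
  expect_equal(g$n_fitted + g$n_skipped, nrow(td))
  au <- augment(fit)
  expect_equal(nrow(au), sum(td$n_obs[td$fitted]))
  expect_equal(au$.resid, au$observed - au$.fitted)
  expect_equal(au$.wresid, 100 * au$.resid / au$observed)
  expect_equal(g$total_sse, sum(au$.resid^2), tolerance = 1e-9)
})
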