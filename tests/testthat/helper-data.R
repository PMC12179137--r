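# Test fixtures are built in code.

# Independent closed-form evaluation of the piecewise-exponential curve,
# written directly from the published branch formulas (kept separate from
# the package's prediction path on purpose).
direct_eval <- function(base, incr, k, t1, t2, t,
                        base_prev = base, incr_prev = incr) {
  amp_own <- incr * (1 - exp(-k * (t2 - t1)))
  amp_prev <- incr_prev * (1 - exp(-k * (t2 - t1)))
  ifelse(t >= t1 & t < pmin(t2, 24),
         base + incr * (1 - exp(-k * (t - t1))),
         ifelse(t >= t2,
                base + amp_own * exp(-k * (t - t2)),
                base_prev + amp_prev * exp(-k * pmax(t + 24 - t2, 0))))
}

# Even within-day time grid avoiding the exact day boundaries.
even_grid <- function(n = 48) seq(0.25, 23.75, length.out = n)

# Noise-free one-day dataset from known parameters.
make_day <- function(base, incr, k, t1, t2, n = 48, sd = 0) {
  t <- even_grid(n)
  bp <- direct_eval(base, incr, k, t1, t2, t)
  if (sd > 0) bp <- bp + rnorm(n, 0, sd)
  data.frame(t = t, bp = bp)
}

# Multi-day measurement table for fit_bp(), same parameters every day.
make_subject <- function(params, n_days = 3, n = 48, subject_id = "S01",
                         dbp_shift = 40) {
  do.call(rbind, lapply(seq_len(n_days) - 1L, function(d) {
    day <- make_day(params[["base"]], params[["incr"]], params[["k"]],
                    params[["t1"]], params[["t2"]], n = n)
    data.frame(subject_id = subject_id, day_index = d, t = day$t,
               sbp = day$bp, dbp = day$bp - dbp_shift)
  }))
}

# Random valid parameter sets with both night branches reachable (t2 < 24),
# drawn inside the default systolic fitting box.
random_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    base = runif(n, 80, 200), incr = runif(n, 0, 60),
    k = runif(n, 0.01, 2), t1 = runif(n, 1, 11), t2 = runif(n, 18, 23.9)
  )
}
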