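# Exhaustive grid-search oracle for the bounded least-squares fit.
#
# Enumerates the full k x t1 x t2 grid. For fixed (k, t1, t2) the model is
# linear in (base, incr), so the sum of squares is a convex quadratic
#   sse(b, i) = Syy - 2 b Sy - 2 i Shy + n b^2 + 2 b i Sh + i^2 Shh
# in terms of the basis h(t) multiplying incr. The discrete optimum over
# the base grid, conditional on each incr grid value, is one of the two
# grid neighbours of the continuous minimiser (Sy - i Sh) / n (a 1-D convex
# quadratic on a uniform grid), so checking both neighbours is exactly
# equivalent to enumerating the whole base grid.
grid_search_bp <- function(t, y, lower = c(80, 0, 0.01, 1, 18),
                           upper = c(200, 60, 2, 11, 25),
                           bp_step = 1, k_step = 0.01, time_step = 0.25) {
  n <- length(y)
  Sy <- sum(y); Syy <- sum(y^2)
  kg <- seq(lower[3], upper[3], by = k_step)
  t1g <- seq(lower[4], upper[4], by = time_step)
  t2g <- seq(lower[5], upper[5], by = time_step)
  ig <- seq(lower[2], upper[2], by = bp_step)
  clamp_snap <- function(x) {
    lo <- lower[1] + floor((x - lower[1]) / bp_step) * bp_step
    pmin(pmax(lo, lower[1]), upper[1])
  }
  best <- list(sse = Inf)
  for (t1 in t1g) for (t2 in t2g) {
    if (t2 <= t1) next
    wake <- t >= t1 & t < pmin(t2, 24)
    post <- t >= t2
    pre <- t < t1
    tau <- pmax(t + 24 - t2, 0)
    # H: one basis row per k value (the factor multiplying incr)
    A <- 1 - exp(-kg * (t2 - t1))
    H <- matrix(0, length(kg), n)
    if (any(wake)) H[, wake] <- 1 - exp(-outer(kg, t[wake] - t1))
    if (any(post)) H[, post] <- A * exp(-outer(kg, t[post] - t2))
    if (any(pre)) H[, pre] <- A * exp(-outer(kg, tau[pre]))
    Sh <- rowSums(H); Shh <- rowSums(H^2); Shy <- as.vector(H %*% y)
    # continuous conditional minimiser of base per (k, incr)
    Bc <- (Sy - outer(Sh, ig)) / n
    for (shift in c(0, bp_step)) {
      B <- pmin(pmax(clamp_snap(Bc) + shift, lower[1]), upper[1])
      I <- matrix(ig, length(kg), length(ig), byrow = TRUE)
      sse <- Syy - 2 * B * Sy - 2 * I * Shy + n * B^2 + 2 * B * I * Sh + I^2 * Shh
      m <- which.min(sse)
      if (sse[m] < best$sse) {
        ki <- (m - 1) %% length(kg) + 1
        ii <- (m - 1) %/% length(kg) + 1
        best <- list(sse = sse[m], base = B[m], incr = ig[ii], k = kg[ki],
                     t1 = t1, t2 = t2)
      }
    }
  }
  best
}
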