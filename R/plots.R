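#' Multi-day blood-pressure profile plot
#'
#' Observed measurements as dots over cumulative hours
#' (`day_index * 24 + t`) with the fitted piecewise-exponential prediction
#' overlaid as a red line (sampled at 10-minute resolution), one panel per
#' subject. Under the extended variant the prediction's pre-wake segments
#' use each day's stored carry.
#'
#' @param fit A [fit_bp()] result.
#' @param channel Channel to plot (default the first fitted channel).
#' @param subjects Optional subset of subject ids.
#' @param path Optional file path; if given the plot is also saved with
#'   [ggplot2::ggsave()].
#' @param ... Passed to [ggplot2::ggsave()].
#' @return A ggplot object.
#' @export
plot_bp_profile <- function(fit, channel = NULL, subjects = NULL, path = NULL, ...) {
  stopifnot(inherits(fit, "bp_fit"))
  channel <- channel %||% fit$channels[1]
  fits <- fit$fits %>% filter(.data$channel == !!channel)
  if (!is.null(subjects)) fits <- filter(fits, .data$subject_id %in% subjects)
  fitted_days <- filter(fits, .data$fitted)
  if (nrow(fitted_days) == 0) abort("No fitted days to plot.")

  obs <- fits %>%
    select(all_of(c("subject_id", "day_index", "t", "observed"))) %>%
    tidyr::unnest(all_of(c("t", "observed"))) %>%
    mutate(hours = .data$day_index * 24 + .data$t)

  grid_t <- seq(0, 24 - 1 / 6, by = 1 / 6)
  curves <- fitted_days %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(function(d, key) {
      times <- tidyr::expand_grid(day_index = d$day_index, t = grid_t)
      pred <- numeric(nrow(times))
      for (i in seq_len(nrow(d))) {
        sel <- which(times$day_index == d$day_index[i])
        p <- as_bp_params(d[i, c("base", "incr", "k", "t1", "t2")])
        carry <- if (fit$variant == "extended") {
          c(base = d$carry_base[i], incr = d$carry_incr[i])
        } else NULL
        pred[sel] <- bp_predict(p, times$t[sel], carry = carry)
      }
      mutate(times, pred = pred)
    }) %>%
    ungroup() %>%
    mutate(hours = .data$day_index * 24 + .data$t)

  gg <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$hours, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$pred),
                       colour = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~subject_id, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = paste0(channel, " blood pressure (mmHg)"),
                  title = paste0(cap1(fit$variant),
                                 " model - ", channel, " profiles")) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, ...)
  gg
}

#' Weighted-residual diagnostic plot
#'
#' Weighted residuals (%) against cumulative time with a zero reference
#' line, one panel per subject. For a well-specified model the residuals
#' scatter randomly about zero with no time trend.
#'
#' @inheritParams plot_bp_profile
#' @return A ggplot object.
#' @export
plot_bp_residuals <- function(fit, channel = NULL, subjects = NULL, path = NULL, ...) {
  stopifnot(inherits(fit, "bp_fit"))
  channel <- channel %||% fit$channels[1]
  res <- augment(fit) %>% filter(.data$channel == !!channel)
  if (!is.null(subjects)) res <- filter(res, .data$subject_id %in% subjects)
  if (nrow(res) == 0) abort("No fitted days to plot.")
  res <- mutate(res, hours = .data$day_index * 24 + .data$t)
  gg <- ggplot2::ggplot(res, ggplot2::aes(x = .data$hours, y = .data$.wresid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point(shape = 15, colour = "blue", size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "Time (h)", y = "Weighted residuals (%)",
                  title = paste0(cap1(fit$variant),
                                 " model - weighted residuals (", channel, ")")) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, gg, ...)
  gg
}

#' @rdname fit_bp
#' @param object A `bp_fit` object.
#' @param type `"profile"` or `"residuals"`.
#' @exportS3Method ggplot2::autoplot
autoplot.bp_fit <- function(object, type = c("profile", "residuals"), ...) {
  type <- match.arg(type)
  switch(type,
         profile = plot_bp_profile(object, ...),
         residuals = plot_bp_residuals(object, ...))
}

cap1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
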