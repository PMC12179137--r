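parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) {
    ts <- x
  } else {
    # ISO-8601 without a zone designator, read as wall-clock time
    ts <- suppressWarnings(readr::parse_datetime(as.character(x), locale = readr::locale(tz = "UTC")))
  }
  lt <- as.POSIXlt(ts, tz = "UTC")
  list(ok = !is.na(ts),
       date = as.Date(ts, tz = "UTC"),
       t = lt$hour + lt$min / 60 + lt$sec / 3600,
       ts = ts)
}

#' Read a measurements CSV
#'
#' Reads a long-format export with columns `subject_id`, `timestamp`
#' (ISO-8601, treated as local wall clock — the circadian model is
#' wall-clock based, so no timezone conversion is applied), `sbp` and `dbp`
#' (mmHg). Derives, per subject, `day_index` (calendar days since the
#' subject's first date, midnight to midnight) and `t` (decimal hours after
#' midnight).
#'
#' Rows with missing columns, unparseable timestamps, non-numeric pressures
#' or `sbp <= dbp` are invalid. In `"strict"` mode any invalid row aborts
#' with a report; in `"lenient"` mode invalid rows are dropped with a
#' warning and attached as the `"rejected"` attribute.
#'
#' @param path CSV file path.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A tibble with columns `subject_id`, `timestamp`, `day_index`,
#'   `t`, `sbp`, `dbp`.
#' @export
read_bp_csv <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("subject_id", "timestamp", "sbp", "dbp")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ", toString(missing), "."))
  }
  sbp <- suppressWarnings(as.numeric(raw$sbp))
  dbp <- suppressWarnings(as.numeric(raw$dbp))
  ts <- parse_timestamps(raw$timestamp)
  problem <- dplyr::case_when(
    !ts$ok ~ "unparseable timestamp",
    is.na(sbp) | is.na(dbp) ~ "non-numeric pressure",
    dbp <= 0 | sbp <= dbp ~ "requires sbp > dbp > 0",
    .default = NA_character_
  )
  bad <- !is.na(problem)
  if (any(bad)) {
    report <- paste0("row ", which(bad), ": ", problem[bad])
    if (mode == "strict") {
      abort(c(paste0(sum(bad), " invalid row(s) in ", path, ":"),
              utils::head(report, 10)))
    }
    warn(paste0("Dropped ", sum(bad), " invalid row(s) from ", path, "."))
  }
  out <- tibble(subject_id = raw$subject_id, timestamp = ts$ts,
                .date = ts$date, t = ts$t, sbp = sbp, dbp = dbp)[!bad, ] %>%
    group_by(.data$subject_id) %>%
    mutate(day_index = as.integer(.data$.date - min(.data$.date)), .after = "timestamp") %>%
    ungroup() %>%
    select(-".date") %>%
    arrange(.data$subject_id, .data$day_index, .data$t)
  if (any(bad)) {
    attr(out, "rejected") <- tibble(row = which(bad), problem = problem[bad])
  }
  out
}

#' Write measurements to CSV
#'
#' Writes the four-column interchange format read back by [read_bp_csv()]:
#' `subject_id`, `timestamp` (ISO-8601), `sbp`, `dbp`.
#'
#' @param measurements Tibble with those columns (e.g.
#'   `simulate_bp()$measurements`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bp_csv <- function(measurements, path) {
  df <- as_tibble(measurements)
  need <- c("subject_id", "timestamp", "sbp", "dbp")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) abort(paste0("Missing column(s): ", toString(missing), "."))
  out <- tibble(
    subject_id = df$subject_id,
    timestamp = format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    sbp = sprintf("%.3f", df$sbp),
    dbp = sprintf("%.3f", df$dbp)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write day-level fits to CSV
#'
#' One row per subject-day-channel with the fitted parameters at reporting
#' precision (1 decimal for `base`/`incr`, 2 for `k`/`t1`/`t2`), the
#' observation count, convergence flag and sum of squared errors. Output is
#' deterministic: rerunning on the same fit yields a byte-identical file.
#'
#' @param fit A [fit_bp()] result or its [tidy()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bp_fits <- function(fit, path) {
  df <- if (inherits(fit, "bp_fit")) tidy(fit) else as_tibble(fit)
  if (nrow(df) == 0) abort("Nothing to write.")
  out <- tibble(
    subject_id = df$subject_id, day_index = df$day_index,
    channel = df$channel, variant = df$variant,
    base = fmt_num(df$base, 1), incr = fmt_num(df$incr, 1),
    k = fmt_num(df$k, 2), t1 = fmt_num(df$t1, 2), t2 = fmt_num(df$t2, 2),
    n_obs = df$n_obs, fitted = df$fitted, converged = df$converged,
    sse = fmt_num(df$sse, 3)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a summary table to CSV
#'
#' Renders [summarize_bp()] output (subject rows, optionally with the
#' population "overall" row appended) at reporting precision: medians and
#' ranges of `base`/`incr` to 1 decimal, `k`/`t1`/`t2` to 2 decimals, CVs
#' to 1 decimal.
#'
#' @param summary A [summarize_bp()] tibble (or several row-bound together).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bp_summary <- function(summary, path) {
  df <- as_tibble(summary)
  if (nrow(df) == 0) abort("Nothing to write.")
  digits_for <- function(p) if (p %in% c("base", "incr")) 1 else 2
  out <- df
  for (p in c("base", "incr", "k", "t1", "t2")) {
    for (s in c("_median", "_min", "_max")) {
      col <- paste0(p, s)
      if (col %in% names(out)) out[[col]] <- fmt_num(df[[col]], digits_for(p))
    }
  }
  for (col in c("cv_base", "cv_incr")) {
    if (col %in% names(out)) out[[col]] <- fmt_num(df[[col]], 1)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
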