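#' Flag description-rate anomalies with a five-year moving window
#'
#' For every year `t` with five preceding and four following years on the
#' grid, compares the mean yearly description count of the preceding five
#' years (`pre_mean`, years `t-5..t-1`) with the mean of the focal window
#' (`window_mean`, years `t..t+4`). The year is a candidate `"low"` if
#' `pre_mean >= 2 * window_mean` ("at least double") and a candidate `"high"`
#' if `pre_mean < window_mean / 2` ("less than half"). To avoid calling the
#' rebound after a genuine shock as a second, opposite anomaly, a candidate
#' is suppressed to `"none"` when any of its five preceding years already
#' carries the opposite label (years are processed in ascending order). A
#' year with `pre_mean == 0` and `window_mean == 0` carries no signal and is
#' `"none"`; `pre_mean == 0` with positive activity afterwards is `"high"`.
#' The rule compares ratios only, so labels are invariant to positive scaling
#' of the counts.
#'
#' @param series A yearly series tibble from [build_yearly_series()] or
#'   [simulate_description_history()] (columns `group`, `year`, `count`).
#' @return A tibble with one row per year of the grid: `group`, `year`,
#'   `label` (`"high"`, `"low"` or `"none"`), `pre_mean`, `window_mean`
#'   (`NA` for the unclassifiable first five / last four boundary years).
#' @export
detect_anomalies <- function(series) {
  stopifnot(all(c("group", "year", "count") %in% names(series)))
  if (nrow(series) < 10) {
    abort("Series must span at least 10 years.",
      class = "descurves_error_params"
    )
  }
  counts <- as.numeric(series$count)
  n <- length(counts)
  pre <- window <- rep(NA_real_, n)
  label <- rep("none", n)
  for (t in 6:(n - 4)) {
    ## compare window sums, not means: the thresholds are ratios, and sums
    ## of integer counts keep the boundary cases ("at least double") exact
    pre_s <- sum(counts[(t - 5):(t - 1)])
    win_s <- sum(counts[t:(t + 4)])
    pre[t] <- pre_s / 5
    window[t] <- win_s / 5
    cand <- classify_window(pre_s, win_s)
    if (cand != "none") {
      opposite <- if (cand == "high") "low" else "high"
      if (any(label[(t - 5):(t - 1)] == opposite)) cand <- "none"
    }
    label[t] <- cand
  }
  tibble(
    group = series$group,
    year = series$year,
    label = label,
    pre_mean = pre,
    window_mean = window
  )
}

## Raw window rule, before rebound suppression.
classify_window <- function(pre, window) {
  if (pre == 0 && window == 0) {
    "none"
  } else if (pre >= 2 * window) {
    "low"
  } else if (pre < window / 2) {
    "high"
  } else {
    "none"
  }
}

#' Classify a single year of a count series
#'
#' Convenience wrapper around the moving-window rule of [detect_anomalies()]
#' for one focal year.
#'
#' @param counts Numeric vector of yearly description counts.
#' @param t Index of the focal year within `counts`.
#' @return `"high"`, `"low"` or `"none"` (boundary years are `"none"` by
#'   contract: both windows must exist).
#' @export
classify_year <- function(counts, t) {
  n <- length(counts)
  if (t < 6 || t > n - 4) {
    return("none")
  }
  series <- tibble(group = "g", year = seq_len(n), count = counts)
  detect_anomalies(series)$label[t]
}

#' Count anomalous groups per year
#'
#' Aggregates anomaly calls of several groups (computed on a common year
#' grid) into per-year counts of groups flagged high and low — the
#' description-rate anomaly summary across the taxonomy.
#'
#' @param calls Anomaly calls for all groups, row-bound output of
#'   [detect_anomalies()].
#' @return A tibble with columns `year`, `n_high`, `n_low`, and an attribute
#'   `n_groups_total`.
#' @export
anomaly_counts <- function(calls) {
  grids <- split(calls$year, calls$group)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1) {
    abort("All groups must share the same year grid.",
      class = "descurves_error_params"
    )
  }
  out <- calls |>
    group_by(.data$year) |>
    summarise(
      n_high = sum(.data$label == "high"),
      n_low = sum(.data$label == "low"),
      .groups = "drop"
    )
  attr(out, "n_groups_total") <- length(grids)
  out
}

#' Plot per-year counts of anomalous groups
#'
#' @param counts Output of [anomaly_counts()].
#' @return A ggplot object: high anomalies plotted upwards, low anomalies
#'   downwards.
#' @export
plot_anomaly_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, c("n_high", "n_low"),
    names_to = "direction", values_to = "n"
  )
  long$n <- ifelse(long$direction == "n_low", -long$n, long$n)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$year, y = .data$n, fill = .data$direction
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(
      values = c(n_high = "#2166ac", n_low = "#b2182b"),
      labels = c(n_high = "high", n_low = "low"), name = "Anomaly"
    ) +
    ggplot2::labs(
      x = "Year", y = "Groups with rate anomaly",
      title = "Description-rate anomalies (five-year moving window)"
    ) +
    ggplot2::theme_minimal()
}
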