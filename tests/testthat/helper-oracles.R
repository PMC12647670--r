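## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the anomaly oracle works on integer window
## sums, the curve oracles on the renormalised truth curve via bisection.

## Brute-force five-year moving-window labels. Integer arithmetic on window
## sums, so threshold boundaries are exact.
oracle_anomaly_labels <- function(counts) {
  n <- length(counts)
  lab <- rep("none", n)
  for (t in seq_len(n)) {
    if (t < 6 || t > n - 4) next
    s_pre <- sum(counts[(t - 5):(t - 1)])
    s_win <- sum(counts[t:(t + 4)])
    cand <- "none"
    if (!(s_pre == 0 && s_win == 0)) {
      if (s_pre >= 2 * s_win) {
        cand <- "low"
      } else if (2 * s_pre < s_win) {
        cand <- "high"
      }
    }
    if (cand != "none") {
      opp <- if (cand == "high") "low" else "high"
      if (any(lab[(t - 5):(t - 1)] == opp)) cand <- "none"
    }
    lab[t] <- cand
  }
  lab
}

## Renormalised half-normal truth curve on [0,1]: value at `year` of the
## curve scaled so the final grid year equals 1. Independent of k.
oracle_truth_curve <- function(year, a, b, end_year = 2017) {
  z <- function(y) exp(-0.5 * ((pmin(y, b) - b) / a)^2)
  z(year) / z(end_year)
}

## Asymptote of the renormalised truth curve = analytic future ratio.
oracle_future_ratio <- function(a, b, end_year = 2017) {
  1 / exp(-0.5 * ((pmin(end_year, b) - b) / a)^2)
}

## Bisection solution of truth_curve(Y) = target; returns years since 1753.
oracle_initial_time <- function(a, b, target = 0.1, end_year = 2017) {
  lo <- b - 30 * a
  hi <- b
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_truth_curve(mid, a, b, end_year) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 - 1753
}

## Tiny MCMC settings for unit tests (acceptance tests size their own runs).
quick_mcmc <- function(seed = 1L) {
  mcmc_config(chains = 2L, draws = 600L, warmup = 600L, seed = seed)
}

## A small description-record table written to a temp file.
write_temp_records <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
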