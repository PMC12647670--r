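as_series <- function(counts, group = "g") {
  tibble::tibble(
    group = group,
    year = seq(1753, length.out = length(counts)),
    count = as.integer(counts)
  )
}

test_that("hand-worked window cases classify as expected", {
  ## drop to a quarter: first low year flagged
  lab <- detect_anomalies(as_series(c(4, 4, 4, 4, 4, 1, 1, 1, 1, 1)))$label
  expect_identical(lab[6], "low")
  ## constant series: nothing flagged
  expect_true(all(detect_anomalies(as_series(rep(3, 40)))$label == "none"))
  ## step up then back down: the rebound low is suppressed
  lab2 <- detect_anomalies(
    as_series(c(1, 1, 1, 1, 1, 4, 4, 4, 4, 4, 1, 1, 1, 1, 1))
  )$label
  expect_identical(lab2[6], "high")
  expect_identical(lab2[11], "none") # preceding years carry 'high'
  expect_identical(oracle_anomaly_labels(c(1, 1, 1, 1, 1, 4, 4, 4, 4, 4, 1, 1, 1, 1, 1)), lab2)
  ## zero history followed by activity counts as high
  lab3 <- detect_anomalies(as_series(c(rep(0, 8), rep(5, 7))))$label
  expect_identical(lab3[6], "high")
  ## all-zero series carries no signal
  expect_true(all(detect_anomalies(as_series(rep(0, 20)))$label == "none"))
  ## boundary years are unclassifiable by contract
  expect_identical(classify_year(c(4, 4, 4, 4, 4, 1, 1, 1, 1, 1), 3), "none")
  expect_error(detect_anomalies(as_series(rep(1, 5))), class = "descurves_error_params")
})

test_that("labels agree exactly with the brute-force oracle on random series", {
  set.seed(99)
  for (i in 1:200) {
    counts <- rpois(265, lambda = sample(c(0.2, 1, 5, 20), 1))
    got <- detect_anomalies(as_series(counts))$label
    expect_identical(got, oracle_anomaly_labels(counts))
  }
})

test_that("labels are invariant to positive scaling of counts", {
  set.seed(100)
  counts <- rpois(80, 4)
  base <- detect_anomalies(as_series(counts))$label
  expect_identical(detect_anomalies(as_series(counts * 10L))$label, base)
  ## and no year is ever both high and low by construction
  expect_true(all(base %in% c("high", "low", "none")))
})

test_that("an injected multi-year shock yields one high run and no rebound low", {
  shock <- data.frame(start_year = 1900, length_years = 5, rate_multiplier = 4)
  h <- simulate_description_history(
    sim_spec("g", 50000, k = 8, a = 60, b = 1950, shocks = shock, seed = 12)
  )
  calls <- detect_anomalies(h)
  highs <- calls$year[calls$label == "high"]
  lows <- calls$year[calls$label == "low"]
  expect_true(1900 %in% highs)
  expect_true(all(highs >= 1896 & highs <= 1904)) # one run at the onset
  expect_false(1905 %in% lows) # the immediate offset rebound is suppressed
})

test_that("per-year counts aggregate across groups and demand a common grid", {
  s1 <- as_series(c(rep(4, 10), rep(1, 10)), "g1")
  s2 <- as_series(rep(2, 20), "g2")
  s3 <- as_series(rep(3, 20), "g3")
  calls <- dplyr::bind_rows(lapply(list(s1, s2, s3), detect_anomalies))
  counts <- anomaly_counts(calls)
  expect_equal(attr(counts, "n_groups_total"), 3L)
  ## only g1 is anomalous; its per-year lows match the oracle labels
  oracle <- oracle_anomaly_labels(c(rep(4, 10), rep(1, 10)))
  expect_equal(counts$n_low, as.integer(oracle == "low"))
  expect_equal(sum(counts$n_high), 0L)
  ## permuting group order changes nothing
  perm <- dplyr::bind_rows(lapply(list(s3, s1, s2), detect_anomalies))
  expect_equal(anomaly_counts(perm), counts, ignore_attr = TRUE)
  ## mismatched grids are an error
  s4 <- as_series(rep(1, 21), "g4")
  expect_error(
    anomaly_counts(dplyr::bind_rows(detect_anomalies(s1), detect_anomalies(s4))),
    class = "descurves_error_params"
  )
})
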