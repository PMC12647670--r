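test_that("noiseless histories hit richness_total exactly and are seeded", {
  sp <- sim_spec("g", richness_total = 5000, k = 1, a = 40, b = 1900, seed = 7)
  h1 <- simulate_description_history(sp)
  h2 <- simulate_description_history(sp)
  expect_identical(h1, h2)
  expect_identical(tail(h1$cumulative, 1), 5000L)
  expect_true(all(diff(h1$cumulative) >= 0))
  expect_equal(tail(h1$scaled, 1), 1)
  ## noisy runs are seeded too, and remain monotone
  spn <- sim_spec("g", 5000, k = 1, a = 40, b = 1900, noise_sd = 0.01, seed = 7)
  expect_identical(
    simulate_description_history(spn),
    simulate_description_history(spn)
  )
  expect_true(all(simulate_description_history(spn)$count >= 0))
})

test_that("shocks scale the in-window expectation and unit shocks are a no-op", {
  ## average realised count across seeds vs the analytic expectation
  a <- 40
  b <- 1950
  rich <- 20000
  base <- rich * diff(oracle_truth_curve(1913:1918, a, b))
  shock <- data.frame(start_year = 1914, length_years = 5, rate_multiplier = 0.25)
  means <- vapply(1:40, function(s) {
    h <- simulate_description_history(sim_spec("g", rich,
      k = 0.5, a = a, b = b,
      noise_sd = 0.001, shocks = shock, seed = s
    ))
    mean(h$count[h$year %in% 1914:1918])
  }, numeric(1))
  expect_equal(mean(means), 0.25 * mean(base), tolerance = 0.05)
  ## multiplier 1.0 reproduces the unshocked series exactly (same seed)
  unit <- data.frame(start_year = 1900, length_years = 10, rate_multiplier = 1)
  s1 <- simulate_description_history(
    sim_spec("g", 3000, k = 1, a = 30, b = 1920, noise_sd = 0.01, seed = 3)
  )
  s2 <- simulate_description_history(
    sim_spec("g", 3000, k = 1, a = 30, b = 1920, noise_sd = 0.01, shocks = unit, seed = 3)
  )
  expect_identical(s1, s2)
  ## invalid windows are rejected
  expect_error(
    sim_spec("g", 1000, k = 1, a = 30, b = 1900,
      shocks = data.frame(start_year = 2015, length_years = 5, rate_multiplier = 2)
    ),
    class = "descurves_error_shock_window"
  )
})

test_that("predictor systems respect their generating truth", {
  ## null structure: no coefficient signal at large n
  null_truth <- default_path_truth(n_groups = 10000, seed = 5, null_model = TRUE)
  tab <- simulate_predictor_system(null_truth)
  exo <- build_model_spec()$exogenous
  expect_true(all(vapply(tab[exo], min, numeric(1)) >= 0))
  expect_true(all(vapply(tab[exo], max, numeric(1)) <= 1))
  for (eq in build_model_spec()$equations) {
    for (p in eq$predictors) {
      expect_lt(abs(cor(tab[[eq$response]], tab[[p]])), 0.05)
    }
  }
  ## zero endogenous covariance: residual covariance of the pair ~ 0
  ## (residuals computed against the known truth equations)
  tr <- default_path_truth(n_groups = 10000, seed = 6)
  tr$endo_covariance <- 0
  tab2 <- simulate_predictor_system(tr)
  resid_of <- function(resp) {
    eq <- Filter(function(e) e$response == resp, build_model_spec()$equations)[[1]]
    cf <- tr$coefficients[tr$coefficients$response == resp, ]
    cf <- setNames(cf$value, cf$predictor)[eq$predictors]
    xb <- as.matrix(tab2[eq$predictors]) %*% cf
    tab2[[resp]] - as.numeric(xb)
  }
  rc <- cov(resid_of("initial_time"), resid_of("future_ratio"))
  expect_lt(abs(rc), 1.5e-3) # MC error scale at n = 10,000
  ## seeded reproducibility
  expect_identical(
    simulate_predictor_system(default_path_truth(n_groups = 50, seed = 9)),
    simulate_predictor_system(default_path_truth(n_groups = 50, seed = 9))
  )
})

test_that("truth validation rejects malformed systems", {
  expect_error(default_path_truth(n_groups = 0), class = "descurves_error_params")
  tr <- default_path_truth()
  bad <- tr$coefficients[-1, ]
  expect_error(
    path_truth(bad, tr$residual_sds, 0.01),
    class = "descurves_error_params"
  )
  expect_error(
    path_truth(tr$coefficients, tr$residual_sds, endo_covariance = 1),
    class = "descurves_error_params"
  )
})
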