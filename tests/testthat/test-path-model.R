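test_that("the path specification matches the hypothesis graph", {
  spec <- build_model_spec()
  expect_length(spec$equations, 5L)
  expect_equal(nrow(path_edges(spec)), 20L)
  expect_identical(spec$covariance, c("initial_time", "future_ratio"))
  expect_true(path_spec_is_acyclic(spec))
  ## the analysis variant changes the input table, never the graph
  agg <- build_model_spec("insecta_aggregated")
  expect_identical(path_edges(agg), path_edges(spec))
  expect_identical(agg$covariance, spec$covariance)
})

test_that("coefficients are recovered on a moderate synthetic system", {
  syn <- simulate_predictor_system(default_path_truth(n_groups = 200, seed = 31))
  fit <- suppressWarnings(fit_path_model(syn,
    check_unit_interval = FALSE,
    mcmc = mcmc_config(chains = 2, draws = 1500, warmup = 1500, seed = 31)
  ))
  truth <- attr(syn, "truth")$coefficients
  est <- dplyr::filter(tidy(fit), .data$predictor != "(Intercept)")
  merged <- dplyr::left_join(truth, est, by = c("response", "predictor"))
  expect_equal(nrow(merged), 20L)
  ## calibrated recovery: no edge further from truth than 4 posterior SDs
  expect_lt(max(abs(merged$mean - merged$value) / merged$sd), 4)
  ## and the weak-prior posterior means agree with the OLS reference
  ols <- purrr::map_dfr(build_model_spec()$equations, function(eq) {
    cf <- coef(stats::lm(stats::reformulate(eq$predictors, eq$response), data = syn))[-1]
    tibble::tibble(response = eq$response, predictor = names(cf), ols = unname(cf))
  })
  merged2 <- dplyr::left_join(merged, ols, by = c("response", "predictor"))
  expect_lt(max(abs(merged2$mean - merged2$ols)), 0.03)
  expect_gte(fit$ppp, 0)
  expect_lte(fit$ppp, 1)
  ## glance carries the fit summary
  gl <- glance(fit)
  expect_identical(gl$n, 200L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("validation catches missing columns, bad ranges and short tables", {
  fx <- scale_unit_interval(description_curve_fixture(),
    cols = setdiff(names(description_curve_fixture()), "group")
  )
  expect_error(
    fit_path_model(dplyr::select(fx, -"aquatic")),
    regexp = "aquatic", class = "descurves_error_missing_column"
  )
  expect_error(
    fit_path_model(dplyr::mutate(fx, aquatic = .data$aquatic + 5)),
    class = "descurves_error_params"
  )
  expect_error(fit_path_model(fx[1:5, ]), class = "descurves_error_params")
})

test_that("the posterior predictive p-value is calibrated on self-generated data", {
  ## data simulated from the model itself should not be flagged as misfit
  ppps <- vapply(1:6, function(s) {
    syn <- simulate_predictor_system(default_path_truth(n_groups = 47, seed = 200 + s))
    fit <- suppressWarnings(fit_path_model(syn,
      check_unit_interval = FALSE,
      mcmc = mcmc_config(chains = 2, draws = 500, warmup = 500, seed = s)
    ))
    fit$ppp
  }, numeric(1))
  expect_true(all(ppps >= 0.2 & ppps <= 0.8))
  ## and the value recomputes reproducibly from the stored fit
  syn <- simulate_predictor_system(default_path_truth(n_groups = 47, seed = 300))
  fit <- suppressWarnings(fit_path_model(syn,
    check_unit_interval = FALSE,
    mcmc = mcmc_config(chains = 2, draws = 500, warmup = 500, seed = 4)
  ))
  expect_equal(posterior_predictive_p(fit), fit$ppp)
})

test_that("PPP is stable under permutation of group rows", {
  syn <- simulate_predictor_system(default_path_truth(n_groups = 80, seed = 55))
  mc <- mcmc_config(chains = 2, draws = 600, warmup = 600, seed = 9)
  f1 <- suppressWarnings(fit_path_model(syn, check_unit_interval = FALSE, mcmc = mc))
  perm <- syn[sample(seq_len(nrow(syn))), ]
  f2 <- suppressWarnings(fit_path_model(perm, check_unit_interval = FALSE, mcmc = mc))
  expect_lt(abs(f1$ppp - f2$ppp), 0.06) # identical up to Monte Carlo error
})

test_that("omitting a strong edge is detected as misfit", {
  syn <- simulate_predictor_system(default_path_truth(n_groups = 470, seed = 77))
  spec <- build_model_spec()
  ## drop the strongest determinant of initial description time
  spec$equations[[4]]$predictors <-
    setdiff(spec$equations[[4]]$predictors, "authors_per_year")
  fit <- suppressWarnings(fit_path_model(syn,
    spec = spec, check_unit_interval = FALSE,
    mcmc = mcmc_config(chains = 2, draws = 600, warmup = 600, seed = 10)
  ))
  expect_lt(fit$ppp, 0.05)
})
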