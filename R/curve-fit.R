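#' Priors for Bayesian curve fitting
#'
#' Weakly-informative defaults, expressed on the \[0,1\]-scaled cumulative
#' response. For the half-normal model: `b ~ Normal(b_mean, b_sd)` (calendar
#' years), `a ~ half-Normal(0, a_sd)` (years), `k ~ half-Cauchy(0, k_scale)`
#' (scaled units; the heavy tail admits the very large scale parameters that
#' strongly unsaturated groups require, while still shrinking towards small
#' values), and `sigma ~ half-Normal(0, sigma_sd)` for the Gaussian
#' observation noise. The alternative saturating models use half-Cauchy
#' priors on their asymptote and rate and a Normal prior on their location
#' year.
#'
#' @param model One of `"halfnormal"`, `"gompertz"`, `"bertalanffy"`.
#' @param ... Named overrides of the defaults listed above.
#' @return A named list of prior hyperparameters.
#' @export
curve_priors <- function(model = "halfnormal", ...) {
  defaults <- switch(model,
    halfnormal = list(
      b_mean = 1950, b_sd = 100, a_sd = 100, k_scale = 10, sigma_sd = 0.1
    ),
    gompertz = list(
      m_mean = 1950, m_sd = 100, K_scale = 10, c_scale = 0.5, sigma_sd = 0.1
    ),
    bertalanffy = list(
      t0_mean = 1753, t0_sd = 100, K_scale = 10, r_scale = 0.5, sigma_sd = 0.1
    ),
    abort(paste0("Unknown model: ", model), class = "descurves_error_params")
  )
  over <- list(...)
  defaults[names(over)] <- over
  defaults
}

#' MCMC settings
#'
#' @param chains Number of chains (default 4).
#' @param draws Posterior draws per chain after warm-up (default 1000).
#' @param warmup Warm-up (adaptation + burn-in) iterations (default 1000).
#' @param seed Integer seed; chain `i` is seeded deterministically from it.
#' @return A named list.
#' @export
mcmc_config <- function(chains = 4L, draws = 1000L, warmup = 1000L, seed = 1L) {
  list(
    chains = as.integer(chains), draws = as.integer(draws),
    warmup = as.integer(warmup), seed = as.integer(seed)
  )
}

jags_curve_model <- function(model) {
  common <- "  sigma ~ dnorm(0, 1 / (sigma_sd * sigma_sd)) T(0,)\n  tau <- pow(sigma, -2)\n}"
  switch(model,
    halfnormal = paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    mu[i] <- M * exp(-0.5 * pow((year[i] - b) / a, 2) * step(b - year[i]))\n",
      "    y[i] ~ dnorm(mu[i], tau)\n",
      "  }\n",
      "  M <- k / (a * sqrt(2 * 3.141592653589793)) + 1\n",
      "  k ~ dt(0, 1 / (k_scale * k_scale), 1) T(0,)\n",
      "  a ~ dnorm(0, 1 / (a_sd * a_sd)) T(0,)\n",
      "  b ~ dnorm(b_mean, 1 / (b_sd * b_sd))\n",
      common
    ),
    gompertz = paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    mu[i] <- K * exp(-exp(-c * (year[i] - m)))\n",
      "    y[i] ~ dnorm(mu[i], tau)\n",
      "  }\n",
      "  K ~ dt(0, 1 / (K_scale * K_scale), 1) T(0,)\n",
      "  c ~ dt(0, 1 / (c_scale * c_scale), 1) T(0,)\n",
      "  m ~ dnorm(m_mean, 1 / (m_sd * m_sd))\n",
      common
    ),
    bertalanffy = paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    mu[i] <- K * (1 - exp(-r * (year[i] - t0))) * step(year[i] - t0)\n",
      "    y[i] ~ dnorm(mu[i], tau)\n",
      "  }\n",
      "  K ~ dt(0, 1 / (K_scale * K_scale), 1) T(0,)\n",
      "  r ~ dt(0, 1 / (r_scale * r_scale), 1) T(0,)\n",
      "  t0 ~ dnorm(t0_mean, 1 / (t0_sd * t0_sd))\n",
      common
    )
  )
}

## Data-driven initial values; `jitter` differentiates chains.
curve_inits <- function(model, series, jitter = 1) {
  sc <- series$scaled
  yr <- series$year
  q_year <- function(p) yr[which(sc >= p)[1]]
  n <- length(yr)
  still_rising <- (sc[n] - sc[n - 10]) > 0.03
  a0 <- max(5, min(120, (q_year(0.9) - q_year(0.3)) / 1.2)) * jitter
  init <- switch(model,
    halfnormal = list(
      a = a0,
      b = if (still_rising) yr[n] + 25 * jitter else q_year(0.99),
      k = 0.5 * jitter
    ),
    gompertz = list(
      K = 1.05 * jitter,
      m = q_year(0.37),
      c = max(0.005, min(0.5, 1.5 / (q_year(0.75) - q_year(0.25) + 1)))
    ),
    bertalanffy = list(
      K = 1.05 * jitter,
      t0 = max(1600, q_year(0.02) - 10),
      r = max(0.005, min(0.5, 0.7 / (q_year(0.5) - q_year(0.02) + 1)))
    )
  )
  c(init, list(sigma = 0.05 * jitter))
}

#' Fit a cumulative description-curve model by MCMC
#'
#' Fits the chosen saturating model to the \[0,1\]-scaled cumulative series
#' with a Gaussian observation model, using JAGS (4 chains by default).
#' Convergence is summarised by split-chain potential scale reduction
#' factors; a fit with any R-hat above 1.1 is flagged (with a warning), not
#' silently returned.
#'
#' @param series Yearly series tibble (from [build_yearly_series()] or
#'   [simulate_description_history()]); the `scaled` column is the response.
#' @param model `"halfnormal"` (default), `"gompertz"` or `"bertalanffy"`.
#' @param priors See [curve_priors()].
#' @param mcmc See [mcmc_config()].
#' @return An object of class `descurves_curve_fit`: posterior `draws`
#'   (matrix), `point_estimate` (posterior means), `predicted` (tibble of
#'   year, observed, predicted and 95% credible band), `diagnostics`
#'   (R-hat, effective sample sizes, `converged` flag), plus the inputs.
#' @export
fit_curve <- function(series, model = c("halfnormal", "gompertz", "bertalanffy"),
                      priors = NULL, mcmc = mcmc_config()) {
  model <- match.arg(model)
  priors <- priors %||% curve_priors(model)
  if (length(unique(series$cumulative[series$cumulative > 0])) < 2) {
    abort(
      "Degenerate series: need at least two distinct nonzero cumulative values.",
      class = "descurves_error_degenerate_series"
    )
  }
  pars <- switch(model,
    halfnormal = c("k", "a", "b", "sigma"),
    gompertz = c("K", "c", "m", "sigma"),
    bertalanffy = c("K", "r", "t0", "sigma")
  )
  data <- c(
    list(y = series$scaled, year = as.numeric(series$year), N = nrow(series)),
    priors
  )
  jit <- c(1, 0.8, 1.2, 1.05, 0.9, 1.1)
  inits <- lapply(seq_len(mcmc$chains), function(i) {
    c(
      curve_inits(model, series, jitter = jit[(i - 1) %% 6 + 1]),
      list(
        .RNG.name = "base::Mersenne-Twister",
        .RNG.seed = mcmc$seed * 101L + i
      )
    )
  })
  jm <- rjags::jags.model(
    textConnection(jags_curve_model(model)),
    data = data, inits = inits, n.chains = mcmc$chains, quiet = TRUE
  )
  invisible(utils::capture.output(stats::update(jm, mcmc$warmup)))
  samp <- rjags::coda.samples(jm, pars, n.iter = mcmc$draws)
  draws <- as.matrix(samp)
  point <- colMeans(draws)
  rhat <- if (mcmc$chains > 1) {
    coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  } else {
    setNames(rep(NA_real_, length(pars)), pars)
  }
  ess <- coda::effectiveSize(samp)
  converged <- all(is.na(rhat)) || max(rhat, na.rm = TRUE) < 1.1
  if (!converged) {
    warn(paste0(
      "Curve fit for group '", series$group[1],
      "' flagged: max R-hat = ", round(max(rhat, na.rm = TRUE), 3)
    ))
  }
  ## posterior predictive curve band from a subsample of draws
  sub <- draws[seq(1, nrow(draws), length.out = min(500, nrow(draws))), ,
    drop = FALSE
  ]
  curves <- apply(sub, 1, function(th) {
    curve_value(model, series$year, th[pars[1:3]])
  })
  predicted <- tibble(
    year = series$year,
    observed = series$scaled,
    predicted = curve_value(model, series$year, point[pars[1:3]]),
    lower = apply(curves, 1, quantile, 0.025),
    upper = apply(curves, 1, quantile, 0.975)
  )
  structure(
    list(
      model = model,
      group = series$group[1],
      draws = draws,
      point_estimate = point,
      predicted = predicted,
      diagnostics = list(rhat = rhat, ess = ess, converged = converged),
      series = series,
      priors = priors,
      mcmc = mcmc
    ),
    class = "descurves_curve_fit"
  )
}

#' Derive the three curve parameters from a fitted curve
#'
#' From the posterior-mean curve: the initial description time (years since
#' 1753 until the fitted curve reaches 10% of the observed current
#' descriptions, solved on the continuous curve and rounded to the nearest
#' integer), the future descriptions ratio (fitted asymptote divided by the
#' observed scaled current value, i.e. the projected eventual total relative
#' to today's), and the curve residual sum of squares (observed minus
#' predicted scaled cumulative, summed over the year grid).
#'
#' @param fit A [fit_curve()] result.
#' @return A one-row tibble: `group`, `model`, `initial_description_time`,
#'   `future_descriptions_ratio`, `residual_ss`.
#' @export
extract_curve_parameters <- function(fit) {
  stopifnot(inherits(fit, "descurves_curve_fit"))
  if (!fit$diagnostics$converged) {
    warn("Extracting curve parameters from a fit flagged as unconverged.")
  }
  point <- fit$point_estimate
  obs_current <- tail(fit$predicted$observed, 1)
  asy <- curve_asymptote(fit$model, point)
  if (asy < obs_current) {
    abort(
      paste0(
        "Fitted asymptote (", signif(asy, 4),
        ") is below the observed current value (", signif(obs_current, 4),
        "); the future descriptions ratio is undefined."
      ),
      class = "descurves_error_asymptote"
    )
  }
  y10 <- curve_inverse(fit$model, point, 0.1 * obs_current)
  tibble(
    group = fit$group,
    model = fit$model,
    initial_description_time = round(y10 - START_YEAR),
    future_descriptions_ratio = asy / obs_current,
    residual_ss = sum((fit$predicted$observed - fit$predicted$predicted)^2)
  )
}

#' @export
print.descurves_curve_fit <- function(x, ...) {
  cat(
    "<descurves_curve_fit> ", x$model, " model, group '", x$group, "'\n",
    sep = ""
  )
  cat(
    " chains:", x$mcmc$chains, " draws/chain:", x$mcmc$draws,
    " converged:", x$diagnostics$converged, "\n"
  )
  print(round(rbind(
    estimate = x$point_estimate,
    rhat = x$diagnostics$rhat[names(x$point_estimate)]
  ), 4))
  invisible(x)
}

#' @rdname fit_curve
#' @param x A `descurves_curve_fit`.
#' @param ... Unused.
#' @method tidy descurves_curve_fit
#' @export
tidy.descurves_curve_fit <- function(x, ...) {
  qs <- apply(x$draws, 2, quantile, c(0.025, 0.975))
  tibble(
    term = colnames(x$draws),
    estimate = unname(x$point_estimate[colnames(x$draws)]),
    std.error = unname(apply(x$draws, 2, sd)),
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    rhat = unname(x$diagnostics$rhat[colnames(x$draws)]),
    ess = unname(x$diagnostics$ess[colnames(x$draws)])
  )
}

#' @rdname fit_curve
#' @method glance descurves_curve_fit
#' @export
glance.descurves_curve_fit <- function(x, ...) {
  tibble(
    group = x$group,
    model = x$model,
    converged = x$diagnostics$converged,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    n_years = nrow(x$series),
    residual_ss = sum((x$predicted$observed - x$predicted$predicted)^2)
  )
}

#' @rdname fit_curve
#' @param object A `descurves_curve_fit`.
#' @method autoplot descurves_curve_fit
#' @export
autoplot.descurves_curve_fit <- function(object, ...) {
  ggplot2::ggplot(object$predicted, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed),
      size = 0.4, colour = "grey30"
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$predicted),
      colour = "steelblue", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "Year", y = "Scaled cumulative descriptions",
      title = paste0(object$group, ": ", object$model, " fit")
    ) +
    ggplot2::theme_minimal()
}
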