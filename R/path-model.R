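#' Build the description-curve path-model specification
#'
#' The fixed hypothesis graph linking societal and biological predictors to
#' the three curve parameters. Five regression equations over ten observed
#' variables: public interest responds to current descriptions; author
#' numbers to public interest and current descriptions; and each of the
#' three curve parameters (curve residuals, initial description time, future
#' descriptions ratio) to body size, author numbers, region fraction,
#' soil-dwelling/endoparasitic and aquatic ordinals — the latter two curve
#' parameters additionally to the curve residuals — plus one residual
#' covariance between initial description time and future descriptions
#' ratio. The graph is recursive (acyclic); the analysis variant (insect
#' orders vs aggregated Insecta) only changes the input table, never the
#' graph.
#'
#' @param variant `"orders"` (default) or `"insecta_aggregated"`; recorded on
#'   the spec for bookkeeping.
#' @return An object of class `descurves_path_spec` with elements
#'   `equations` (list of `response` / `predictors`), `covariance` (the
#'   endogenous pair), `exogenous`, `endogenous`, `variant`.
#' @export
build_model_spec <- function(variant = c("orders", "insecta_aggregated")) {
  variant <- match.arg(variant)
  exo <- c(
    "current_descriptions", "body_size", "region_fraction",
    "soil_endo", "aquatic"
  )
  curve_preds <- c(
    "body_size", "authors_per_year", "region_fraction", "soil_endo", "aquatic"
  )
  equations <- list(
    list(response = "public_interest", predictors = "current_descriptions"),
    list(
      response = "authors_per_year",
      predictors = c("public_interest", "current_descriptions")
    ),
    list(response = "residual_ss", predictors = curve_preds),
    list(
      response = "initial_time", predictors = c(curve_preds, "residual_ss")
    ),
    list(
      response = "future_ratio", predictors = c(curve_preds, "residual_ss")
    )
  )
  spec <- structure(
    list(
      equations = equations,
      covariance = c("initial_time", "future_ratio"),
      exogenous = exo,
      endogenous = vapply(equations, `[[`, character(1), "response"),
      variant = variant
    ),
    class = "descurves_path_spec"
  )
  stopifnot(path_spec_is_acyclic(spec))
  spec
}

#' Directed edges of a path-model specification
#'
#' @param spec A [build_model_spec()] result.
#' @return A tibble with columns `response`, `predictor`, one row per
#'   directed edge (intercepts and the residual covariance excluded).
#' @export
path_edges <- function(spec) {
  purrr::map_dfr(spec$equations, function(eq) {
    tibble(response = eq$response, predictor = eq$predictors)
  })
}

#' Is the path graph acyclic?
#'
#' Kahn-style elimination over the directed edge set.
#'
#' @param spec A [build_model_spec()] result.
#' @return `TRUE` if a topological order exists.
#' @export
path_spec_is_acyclic <- function(spec) {
  edges <- path_edges(spec)
  nodes <- union(edges$response, edges$predictor)
  repeat {
    sinks_free <- setdiff(nodes, edges$response) # no incoming edge
    if (length(sinks_free) == 0) {
      return(length(nodes) == 0)
    }
    nodes <- setdiff(nodes, sinks_free)
    edges <- edges[!(edges$predictor %in% sinks_free), ]
    if (length(nodes) == 0) {
      return(TRUE)
    }
  }
}

## Generate the JAGS model string for a path spec. Variables are mapped to
## data vectors v1..v10 (exogenous first, then endogenous in equation
## order); the covarying endogenous pair is modelled jointly via dmnorm.
jags_path_model <- function(spec) {
  vars <- c(spec$exogenous, spec$endogenous)
  vid <- setNames(seq_along(vars), vars)
  pair <- spec$covariance
  lines <- c("model {", "  for (i in 1:n) {")
  mu_expr <- function(eq, j) {
    terms <- sprintf(
      "b.%d.%d * v%d[i]", j, seq_along(eq$predictors),
      vid[eq$predictors]
    )
    paste(c(sprintf("a.%d", j), terms), collapse = " + ")
  }
  for (j in seq_along(spec$equations)) {
    eq <- spec$equations[[j]]
    if (eq$response %in% pair) {
      slot <- match(eq$response, pair)
      lines <- c(lines, sprintf(
        "    mup[i, %d] <- %s", slot, mu_expr(eq, j)
      ))
    } else {
      lines <- c(lines, sprintf(
        "    v%d[i] ~ dnorm(%s, tau.%d)", vid[eq$response], mu_expr(eq, j), j
      ))
    }
  }
  lines <- c(
    lines,
    "    yp[i, 1:2] ~ dmnorm(mup[i, 1:2], Omega[1:2, 1:2])",
    "  }"
  )
  for (j in seq_along(spec$equations)) {
    eq <- spec$equations[[j]]
    lines <- c(
      lines,
      sprintf("  a.%d ~ dnorm(0, coef_prec)", j),
      sprintf(
        "  b.%d.%d ~ dnorm(0, coef_prec)", j, seq_along(eq$predictors)
      ),
      sprintf("  sd.%d ~ dt(0, sd_prec, 1) T(0,)", j)
    )
    if (!(eq$response %in% pair)) {
      lines <- c(lines, sprintf("  tau.%d <- pow(sd.%d, -2)", j, j))
    }
  }
  p1 <- match(pair[1], spec$endogenous)
  p2 <- match(pair[2], spec$endogenous)
  lines <- c(
    lines,
    "  rho ~ dunif(-1, 1)",
    sprintf("  Sig[1, 1] <- pow(sd.%d, 2)", p1),
    sprintf("  Sig[2, 2] <- pow(sd.%d, 2)", p2),
    sprintf("  Sig[1, 2] <- rho * sd.%d * sd.%d", p1, p2),
    "  Sig[2, 1] <- Sig[1, 2]",
    "  Omega[1:2, 1:2] <- inverse(Sig[1:2, 1:2])",
    "  cov.pair <- Sig[1, 2]",
    "}"
  )
  paste(lines, collapse = "\n")
}

#' Fit the Bayesian path model
#'
#' Fits the recursive system of [build_model_spec()] by MCMC (JAGS): Normal
#' (mean 0, sd 10) priors on intercepts and coefficients, half-Cauchy (scale
#' 2.5) priors on residual SDs, and a uniform prior on the residual
#' correlation of the endogenous pair. Exogenous predictors are treated as
#' fixed regressors. A posterior predictive p-value (likelihood-ratio
#' discrepancy; see [posterior_predictive_p()]) is computed on the fitted
#' object.
#'
#' @param data Tibble with all ten model variables, min-max scaled to \[0,1\]
#'   (see [scale_unit_interval()]); extra columns such as `group` are
#'   ignored.
#' @param spec A [build_model_spec()] result.
#' @param mcmc See [mcmc_config()]; defaults here to 4 chains x 2000 draws
#'   after 2000 warm-up iterations.
#' @param check_unit_interval If `TRUE` (default), error when a model column
#'   lies outside \[0,1\]. Disable for recovery studies on synthetic systems
#'   whose Gaussian noise can leave the unit interval.
#' @param priors Named list overriding `coef_sd` (default 10) and
#'   `resid_sd_scale` (half-Cauchy scale, default 2.5).
#' @return An object of class `descurves_path_fit`: `coefficients` (tibble
#'   of posterior mean, sd, 95% credible interval and sign per edge and
#'   intercept), `endo_covariance` (posterior mean of the raw residual
#'   covariance), `endo_covariance_std` (posterior mean of the standardized
#'   residual covariance: per draw, the covariance divided by the
#'   model-implied total SDs of the pair), `rho`, `ppp`, `diagnostics`,
#'   `draws`, and the inputs.
#' @export
fit_path_model <- function(data, spec = build_model_spec(),
                           mcmc = mcmc_config(draws = 2000L, warmup = 2000L),
                           check_unit_interval = TRUE,
                           priors = list()) {
  vars <- c(spec$exogenous, spec$endogenous)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "descurves_error_missing_column"
    )
  }
  mat <- as.matrix(data[vars])
  if (!all(is.finite(mat))) {
    abort("Model columns must be complete and finite.",
      class = "descurves_error_params"
    )
  }
  n <- nrow(mat)
  if (n < 10) {
    abort("Need at least 10 rows to fit the path model.",
      class = "descurves_error_params"
    )
  }
  if (check_unit_interval && (min(mat) < -1e-8 || max(mat) > 1 + 1e-8)) {
    abort(
      "Model columns must lie in [0,1]; scale with scale_unit_interval().",
      class = "descurves_error_params"
    )
  }
  coef_sd <- priors$coef_sd %||% 10
  resid_sd_scale <- priors$resid_sd_scale %||% 2.5
  pair <- spec$covariance
  jdata <- c(
    setNames(
      lapply(setdiff(vars, pair), function(v) as.numeric(mat[, v])),
      paste0("v", match(setdiff(vars, pair), vars))
    ),
    list(
      yp = mat[, pair],
      n = n,
      coef_prec = 1 / coef_sd^2,
      sd_prec = 1 / resid_sd_scale^2
    )
  )
  inits <- lapply(seq_len(mcmc$chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = mcmc$seed * 131L + i
    )
  })
  jm <- rjags::jags.model(
    textConnection(jags_path_model(spec)),
    data = jdata, inits = inits, n.chains = mcmc$chains, quiet = TRUE
  )
  invisible(utils::capture.output(stats::update(jm, mcmc$warmup)))
  monitor <- c(
    sprintf("a.%d", seq_along(spec$equations)),
    unlist(lapply(seq_along(spec$equations), function(j) {
      sprintf("b.%d.%d", j, seq_along(spec$equations[[j]]$predictors))
    })),
    sprintf("sd.%d", seq_along(spec$equations)),
    "rho", "cov.pair"
  )
  samp <- rjags::coda.samples(jm, monitor, n.iter = mcmc$draws)
  draws <- as.matrix(samp)
  rhat <- coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  ess <- coda::effectiveSize(samp)
  converged <- max(rhat, na.rm = TRUE) < 1.1
  if (!converged) {
    warn(paste0(
      "Path-model fit flagged: max R-hat = ", round(max(rhat, na.rm = TRUE), 3)
    ))
  }
  ## coefficient table
  coef_rows <- purrr::map_dfr(seq_along(spec$equations), function(j) {
    eq <- spec$equations[[j]]
    tibble(
      response = eq$response,
      predictor = c("(Intercept)", eq$predictors),
      param = c(
        sprintf("a.%d", j),
        sprintf("b.%d.%d", j, seq_along(eq$predictors))
      )
    )
  })
  qs <- apply(draws, 2, quantile, c(0.025, 0.975))
  coefficients <- coef_rows |>
    mutate(
      mean = colMeans(draws)[.data$param],
      sd = apply(draws, 2, sd)[.data$param],
      conf.low = qs[1, .data$param],
      conf.high = qs[2, .data$param],
      sign = ifelse(.data$mean >= 0, "+", "-")
    ) |>
    select(-"param")
  std <- standardized_pair_covariance(draws, mat, spec)
  fit <- structure(
    list(
      spec = spec,
      data = as_tibble(as.data.frame(mat)),
      n = n,
      draws = draws,
      coefficients = coefficients,
      endo_covariance = mean(draws[, "cov.pair"]),
      endo_covariance_std = mean(std),
      rho = mean(draws[, "rho"]),
      diagnostics = list(rhat = rhat, ess = ess, converged = converged),
      mcmc = mcmc
    ),
    class = "descurves_path_fit"
  )
  fit$ppp <- posterior_predictive_p(fit)
  fit
}

## Structural matrices for one posterior draw.
## Returns B (endo x endo), G (endo x (1 + exo)), Psi (endo x endo).
draw_matrices <- function(theta, spec) {
  ne <- length(spec$endogenous)
  nx <- length(spec$exogenous)
  B <- matrix(0, ne, ne)
  G <- matrix(0, ne, 1 + nx)
  for (j in seq_along(spec$equations)) {
    eq <- spec$equations[[j]]
    G[j, 1] <- theta[sprintf("a.%d", j)]
    for (k in seq_along(eq$predictors)) {
      p <- eq$predictors[k]
      val <- theta[sprintf("b.%d.%d", j, k)]
      if (p %in% spec$endogenous) {
        B[j, match(p, spec$endogenous)] <- val
      } else {
        G[j, 1 + match(p, spec$exogenous)] <- val
      }
    }
  }
  sds <- theta[sprintf("sd.%d", seq_len(ne))]
  Psi <- diag(sds^2, ne)
  i1 <- match(spec$covariance[1], spec$endogenous)
  i2 <- match(spec$covariance[2], spec$endogenous)
  Psi[i1, i2] <- Psi[i2, i1] <- theta["cov.pair"]
  list(B = B, G = G, Psi = Psi, pair = c(i1, i2))
}

## Per-draw standardized covariance of the endogenous pair: raw residual
## covariance over the model-implied total SDs of the two variables (the
## convention Bayesian-SEM software uses for standardized solutions).
standardized_pair_covariance <- function(draws, mat, spec) {
  Xe <- mat[, spec$exogenous, drop = FALSE]
  Sxx <- cov(Xe) * (nrow(Xe) - 1) / nrow(Xe)
  apply(draws, 1, function(theta) {
    m <- draw_matrices(theta, spec)
    IBi <- solve(diag(nrow(m$B)) - m$B)
    Gx <- m$G[, -1, drop = FALSE]
    Vtot <- IBi %*% (Gx %*% Sxx %*% t(Gx) + m$Psi) %*% t(IBi)
    theta["cov.pair"] / sqrt(Vtot[m$pair[1], m$pair[1]] *
      Vtot[m$pair[2], m$pair[2]])
  })
}

#' Posterior predictive p-value of a path-model fit
#'
#' For each posterior draw, the discrepancy is the likelihood-ratio statistic
#' of the endogenous data against the model-implied conditional moments
#' (conditional on the exogenous predictors), relative to the saturated
#' model (unrestricted multivariate regression with unrestricted residual
#' covariance): \eqn{D = -2(\ell_{model} - \ell_{saturated})}. Replicated
#' endogenous data are simulated from the draw's implied moments and their
#' discrepancy recomputed (with the saturated model refitted to the
#' replicate); the PPP is the fraction of draws whose replicated discrepancy
#' is at least the observed one. Values near 0.5 indicate good fit; values
#' near 0 indicate misfit.
#'
#' @param fit A [fit_path_model()] result.
#' @param seed Seed for the replicate simulations; defaults to the fit's
#'   MCMC seed, making the value reproducible from the fitted object.
#' @return A single value in \[0, 1\].
#' @export
posterior_predictive_p <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "descurves_path_fit"))
  spec <- fit$spec
  mat <- as.matrix(fit$data)
  seed <- seed %||% (fit$mcmc$seed * 977L + 7L)
  Y <- mat[, spec$endogenous, drop = FALSE]
  X <- cbind(1, mat[, spec$exogenous, drop = FALSE])
  n <- nrow(Y)
  p <- ncol(Y)
  proj <- solve(crossprod(X), t(X))
  sat_loglik <- function(Ym) {
    E <- Ym - X %*% (proj %*% Ym)
    S <- crossprod(E) / n
    ld <- determinant(S)$modulus[1]
    -n / 2 * (p * log(2 * pi) + ld + p)
  }
  ll_sat_obs <- sat_loglik(Y)
  draws <- fit$draws
  with_seed(seed, {
    d_obs <- d_rep <- numeric(nrow(draws))
    for (i in seq_len(nrow(draws))) {
      m <- draw_matrices(draws[i, ], spec)
      IBi <- solve(diag(p) - m$B)
      Mu <- X %*% t(IBi %*% m$G)
      Sg <- IBi %*% m$Psi %*% t(IBi)
      ch <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ch)) {
        abort("Degenerate model-implied covariance in posterior draw.",
          class = "descurves_error_degenerate_covariance"
        )
      }
      Sgi <- chol2inv(ch)
      ld <- 2 * sum(log(diag(ch)))
      E <- Y - Mu
      ll <- -n / 2 * (p * log(2 * pi) + ld) - 0.5 * sum((E %*% Sgi) * E)
      d_obs[i] <- -2 * (ll - ll_sat_obs)
      Yr <- Mu + matrix(rnorm(n * p), n, p) %*% ch
      Er <- Yr - Mu
      ll_r <- -n / 2 * (p * log(2 * pi) + ld) - 0.5 * sum((Er %*% Sgi) * Er)
      d_rep[i] <- -2 * (ll_r - sat_loglik(Yr))
    }
    mean(d_rep >= d_obs)
  })
}

#' @export
print.descurves_path_fit <- function(x, ...) {
  cat("<descurves_path_fit> n =", x$n, "groups\n")
  cat(
    " ppp:", round(x$ppp, 3),
    " residual covariance (raw):", signif(x$endo_covariance, 3),
    " (standardized):", round(x$endo_covariance_std, 3), "\n"
  )
  cat(
    " converged:", x$diagnostics$converged,
    " max R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n"
  )
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' @rdname fit_path_model
#' @param x A `descurves_path_fit`.
#' @param ... Unused.
#' @method tidy descurves_path_fit
#' @export
tidy.descurves_path_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_path_model
#' @method glance descurves_path_fit
#' @export
glance.descurves_path_fit <- function(x, ...) {
  tibble(
    n = x$n,
    ppp = x$ppp,
    endo_covariance = x$endo_covariance,
    endo_covariance_std = x$endo_covariance_std,
    rho = x$rho,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$diagnostics$converged
  )
}

#' @rdname fit_path_model
#' @param object A `descurves_path_fit`.
#' @method autoplot descurves_path_fit
#' @export
autoplot.descurves_path_fit <- function(object, ...) {
  cf <- object$coefficients |>
    filter(.data$predictor != "(Intercept)") |>
    mutate(edge = paste(.data$response, "~", .data$predictor))
  ggplot2::ggplot(cf, ggplot2::aes(
    x = .data$mean, y = .data$edge, colour = .data$sign
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$conf.low, xmax = .data$conf.high
    )) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#2166ac", "-" = "#b2182b"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Posterior mean (95% credible interval)", y = NULL,
      title = "Path-model coefficients"
    ) +
    ggplot2::theme_minimal()
}
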