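#' Specification for a synthetic description history
#'
#' Bundles the ground truth for one simulated taxonomic group: the
#' half-normal curve parameters, the total species richness reached by the
#' final year, optional rate-level noise, and optional multi-year rate shocks
#' (e.g. war-time collapses of taxonomic activity).
#'
#' @param group_id Character label for the group.
#' @param richness_total Positive integer; cumulative number of described
#'   species at `end_year` under the noiseless curve.
#' @param k,a,b Half-normal curve truth; see [halfnormal_cumulative()].
#' @param noise_sd Nonnegative; standard deviation of the accumulated
#'   rate-level noise at the final year, in scaled-cumulative units (the
#'   per-year Gaussian rate perturbation has sd `noise_sd / sqrt(n_years)`).
#' @param shocks A data frame (or `NULL`) with columns `start_year`,
#'   `length_years`, `rate_multiplier`: within each window the expected
#'   yearly description rate is multiplied by `rate_multiplier` (> 0).
#' @param seed Integer seed controlling all randomness of the simulation.
#' @param end_year Final year of the grid (default 2017).
#' @return An object of class `descurves_sim_spec`.
#' @seealso [simulate_description_history()]
#' @export
sim_spec <- function(group_id, richness_total, k, a, b, noise_sd = 0,
                     shocks = NULL, seed = 1L, end_year = 2017L) {
  if (!is.numeric(richness_total) || richness_total < 1) {
    abort("`richness_total` must be a positive integer.",
      class = "descurves_error_params"
    )
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "descurves_error_params")
  }
  if (!is.null(shocks)) {
    shocks <- as_tibble(shocks)
    need <- c("start_year", "length_years", "rate_multiplier")
    if (!all(need %in% names(shocks))) {
      abort(
        paste0("`shocks` needs columns: ", paste(need, collapse = ", ")),
        class = "descurves_error_params"
      )
    }
    if (any(shocks$rate_multiplier <= 0)) {
      abort("Shock `rate_multiplier` must be > 0.",
        class = "descurves_error_params"
      )
    }
    bad <- shocks$start_year < START_YEAR |
      (shocks$start_year + shocks$length_years - 1) > end_year
    if (any(bad)) {
      abort(
        paste0(
          "Shock window outside the year range ", START_YEAR, "-", end_year,
          " (rows ", paste(which(bad), collapse = ", "), ")."
        ),
        class = "descurves_error_shock_window"
      )
    }
  }
  structure(
    list(
      group_id = as.character(group_id),
      richness_total = as.integer(round(richness_total)),
      truth = list(k = k, a = a, b = b),
      noise_sd = noise_sd,
      shocks = shocks,
      seed = as.integer(seed),
      end_year = as.integer(end_year)
    ),
    class = "descurves_sim_spec"
  )
}

## Noiseless scaled expected yearly increments for a sim spec: the truth
## curve renormalised so the final-year cumulative equals 1. Mass below the
## grid start is assigned to the first year.
expected_scaled_increments <- function(spec) {
  yrs <- year_grid(spec$end_year)
  tr <- spec$truth
  f <- halfnormal_cumulative(yrs, tr$k, tr$a, tr$b)
  g <- f / f[length(f)]
  c(g[1], diff(g))
}

## Per-year shock multipliers (1 outside all windows; windows multiply).
shock_multipliers <- function(spec) {
  yrs <- year_grid(spec$end_year)
  mult <- rep(1, length(yrs))
  if (!is.null(spec$shocks)) {
    for (i in seq_len(nrow(spec$shocks))) {
      s <- spec$shocks[i, ]
      idx <- yrs >= s$start_year & yrs < s$start_year + s$length_years
      mult[idx] <- mult[idx] * s$rate_multiplier
    }
  }
  mult
}

#' Simulate a yearly description history with known ground truth
#'
#' Generates per-year counts of species descriptions whose noiseless scaled
#' cumulative equals the half-normal truth curve of the spec, renormalised so
#' the cumulative at the final year equals `richness_total`. Shocks multiply
#' the expected yearly rate inside their windows. With `noise_sd = 0` counts
#' are a deterministic (largest-remainder) rounding of the expected
#' cumulative, so the final cumulative equals `richness_total` exactly (absent
#' shocks); with `noise_sd > 0` Gaussian noise is added to the scaled yearly
#' rates (truncated at zero, preserving monotonicity of the cumulative) and
#' counts are Poisson draws around the resulting expectations.
#'
#' @param spec A [sim_spec()].
#' @return A tibble with columns `group`, `year`, `count`, `cumulative`,
#'   `scaled` — the same shape [build_yearly_series()] produces.
#' @export
simulate_description_history <- function(spec) {
  stopifnot(inherits(spec, "descurves_sim_spec"))
  yrs <- year_grid(spec$end_year)
  n <- length(yrs)
  rate <- expected_scaled_increments(spec) * shock_multipliers(spec)
  counts <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      eps <- rnorm(n, 0, spec$noise_sd / sqrt(n))
      lambda <- pmax(0, rate + eps) * spec$richness_total
      rpois(n, lambda)
    } else {
      as.integer(diff(c(0, round(cumsum(rate) * spec$richness_total))))
    }
  })
  cum <- cumsum(counts)
  fin <- cum[n]
  tibble(
    group = spec$group_id,
    year = yrs,
    count = as.integer(counts),
    cumulative = as.integer(cum),
    scaled = if (fin > 0) cum / fin else rep(0, n)
  )
}

#' Expand a simulated history into individual description records
#'
#' Produces one row per described species with synthetic species and author
#' names, so the ingest readers and author statistics can be exercised
#' end-to-end. Author names are drawn (seeded) from a small per-group pool.
#'
#' @param spec A [sim_spec()].
#' @param n_authors Size of the synthetic author pool for this group.
#' @return A tibble with columns `group`, `species`, `year`, `authors`
#'   (semicolon-joined string), matching [read_description_table()] output
#'   once parsed.
#' @export
simulate_description_records <- function(spec, n_authors = 12L) {
  series <- simulate_description_history(spec)
  pool <- sprintf("%s_author_%02d", spec$group_id, seq_len(n_authors))
  idx <- rep(seq_len(nrow(series)), series$count)
  n_sp <- length(idx)
  auth <- with_seed(spec$seed + 1L, {
    vapply(seq_len(n_sp), function(i) {
      paste(sample(pool, sample(1:3, 1)), collapse = ";")
    }, character(1))
  })
  tibble(
    group = spec$group_id,
    species = sprintf("%s_sp%06d", spec$group_id, seq_len(n_sp)),
    year = series$year[idx],
    authors = auth
  )
}

#' Ground truth for a synthetic predictor/parameter system
#'
#' Defines the data-generating linear path system used by
#' [simulate_predictor_system()]: one coefficient per directed edge of the
#' description-curve path model (see [build_model_spec()]), residual standard
#' deviations for the five endogenous variables, and the residual covariance
#' of the (initial description time, future descriptions ratio) pair.
#'
#' @param coefficients Tibble with columns `response`, `predictor`, `value`;
#'   its edge set must equal the path-model edge set exactly.
#' @param residual_sds Named numeric vector of positive residual SDs, one per
#'   endogenous variable.
#' @param endo_covariance Residual covariance of `initial_time` and
#'   `future_ratio`.
#' @param n_groups Positive integer number of groups to simulate.
#' @param seed Integer seed.
#' @return An object of class `descurves_path_truth`.
#' @export
path_truth <- function(coefficients, residual_sds, endo_covariance = 0,
                       n_groups = 47L, seed = 1L) {
  if (!is.numeric(n_groups) || n_groups < 1) {
    abort("`n_groups` must be a positive integer.",
      class = "descurves_error_params"
    )
  }
  spec <- build_model_spec()
  edges <- path_edges(spec)
  coefficients <- as_tibble(coefficients)
  key <- function(d) paste(d$response, d$predictor, sep = "~")
  if (!setequal(key(edges), key(coefficients)) ||
    nrow(coefficients) != nrow(edges)) {
    abort("`coefficients` must cover exactly the path-model edge set.",
      class = "descurves_error_params"
    )
  }
  endo <- vapply(spec$equations, `[[`, character(1), "response")
  if (!setequal(names(residual_sds), endo) || any(residual_sds <= 0)) {
    abort("`residual_sds` must name every endogenous variable, all > 0.",
      class = "descurves_error_params"
    )
  }
  rmax <- prod(residual_sds[spec$covariance])
  if (abs(endo_covariance) >= rmax) {
    abort("`endo_covariance` implies |correlation| >= 1.",
      class = "descurves_error_params"
    )
  }
  structure(
    list(
      coefficients = coefficients,
      residual_sds = residual_sds,
      endo_covariance = endo_covariance,
      n_groups = as.integer(n_groups),
      seed = as.integer(seed)
    ),
    class = "descurves_path_truth"
  )
}

#' Default ground truth mirroring the hypothesised path structure
#'
#' Coefficient signs follow the a-priori hypothesis table of the path model
#' (societal drivers boost author numbers; accessible regions reduce curve
#' residuals; etc.), with magnitudes of the order seen on real group-level
#' data. Useful as a realistic starting point for recovery studies.
#'
#' @inheritParams path_truth
#' @param null_model If `TRUE`, all coefficients and the covariance are zero.
#' @return A [path_truth()] object.
#' @export
default_path_truth <- function(n_groups = 47L, seed = 1L, null_model = FALSE) {
  edges <- path_edges(build_model_spec())
  vals <- c(
    "public_interest~current_descriptions" = 0.35,
    "authors_per_year~public_interest" = 0.30,
    "authors_per_year~current_descriptions" = 0.60,
    "residual_ss~body_size" = -0.10,
    "residual_ss~authors_per_year" = -0.15,
    "residual_ss~region_fraction" = -0.35,
    "residual_ss~soil_endo" = 0.10,
    "residual_ss~aquatic" = 0.15,
    "initial_time~body_size" = -0.30,
    "initial_time~authors_per_year" = -0.50,
    "initial_time~region_fraction" = -0.10,
    "initial_time~soil_endo" = 0.10,
    "initial_time~aquatic" = -0.05,
    "initial_time~residual_ss" = -0.45,
    "future_ratio~body_size" = 0.10,
    "future_ratio~authors_per_year" = -0.25,
    "future_ratio~region_fraction" = -0.10,
    "future_ratio~soil_endo" = -0.05,
    "future_ratio~aquatic" = -0.05,
    "future_ratio~residual_ss" = -0.25
  )
  edges$value <- unname(vals[paste(edges$response, edges$predictor, sep = "~")])
  if (null_model) edges$value <- 0
  path_truth(
    coefficients = edges,
    residual_sds = c(
      public_interest = 0.15, authors_per_year = 0.10, residual_ss = 0.17,
      initial_time = 0.16, future_ratio = 0.17
    ),
    endo_covariance = if (null_model) 0 else 0.012,
    n_groups = n_groups,
    seed = seed
  )
}

#' Simulate a predictor-and-curve-parameter table from a known path system
#'
#' Exogenous predictors are drawn from Beta(2, 2) (interior support, so the
#' subsequent min-max scaling is non-degenerate) and scaled to \[0,1\];
#' endogenous variables are generated recursively from the linear equations
#' of the path graph plus Gaussian noise, with correlated residuals for the
#' (initial description time, future descriptions ratio) pair. Intercepts are
#' chosen to centre each endogenous variable near 0.5.
#'
#' @param truth A [path_truth()].
#' @return A tibble with a `group` column and the ten model variables; the
#'   generating `truth` is attached as attribute `"truth"` for recovery
#'   testing.
#' @export
simulate_predictor_system <- function(truth) {
  stopifnot(inherits(truth, "descurves_path_truth"))
  spec <- build_model_spec()
  n <- truth$n_groups
  with_seed(truth$seed, {
    exo <- spec$exogenous
    dat <- as_tibble(setNames(
      lapply(exo, function(v) rbeta(n, 2, 2)), exo
    ))
    dat <- scale_unit_interval(dat)
    attr(dat, "scaling") <- NULL
    ## correlated residual pair, then the remaining independent residuals
    pair <- spec$covariance
    sds <- truth$residual_sds
    rho_cov <- truth$endo_covariance
    sig <- matrix(
      c(
        sds[pair[1]]^2, rho_cov,
        rho_cov, sds[pair[2]]^2
      ),
      2, 2
    )
    ch <- chol(sig)
    zpair <- matrix(rnorm(2 * n), n, 2) %*% ch
    colnames(zpair) <- pair
    for (eq in spec$equations) {
      resp <- eq$response
      coefs <- truth$coefficients[truth$coefficients$response == resp, ]
      coefs <- setNames(coefs$value, coefs$predictor)[eq$predictors]
      xb <- as.matrix(dat[eq$predictors]) %*% coefs
      eps <- if (resp %in% pair) {
        zpair[, resp]
      } else {
        rnorm(n, 0, sds[resp])
      }
      intercept <- 0.5 - sum(coefs * 0.5)
      dat[[resp]] <- as.numeric(intercept + xb + eps)
    }
    out <- dplyr::bind_cols(
      tibble(group = sprintf("g%03d", seq_len(n))), dat
    )
    attr(out, "truth") <- truth
    out
  })
}
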