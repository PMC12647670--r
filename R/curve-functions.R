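#' Left-sided half-normal cumulative description curve
#'
#' Evaluates the modified half-normal model for cumulative species
#' descriptions. Up to the mean year `b` the curve follows a scaled Gaussian
#' density shape; after `b` it stays constant at its maximum, so the fitted
#' asymptote is reached exactly at `b`:
#' \deqn{D(Y) = \left(\frac{k}{a\sqrt{2\pi}} + 1\right)
#'   \exp\!\left(-\tfrac12\left(\frac{Y-b}{a}\right)^2\right) \quad (Y \le b),}
#' and \eqn{D(Y) = k/(a\sqrt{2\pi}) + 1} for \eqn{Y > b}. The `+ 1` in the
#' scale term guarantees an asymptote of at least 1, so on \[0,1\]-scaled data
#' the fitted maximum can never fall below the observed maximum.
#'
#' @param year Numeric vector of calendar years (may be fractional).
#' @param k Nonnegative scale parameter (scaled-cumulative units).
#' @param a Positive standard deviation of the underlying normal, in years.
#' @param b Mean of the underlying normal, a calendar year.
#' @return Numeric vector of curve values; nondecreasing and continuous in
#'   `year`, with maximum `k / (a * sqrt(2 * pi)) + 1`.
#' @seealso [gompertz_cumulative()], [bertalanffy_cumulative()], [fit_curve()]
#' @examples
#' halfnormal_cumulative(1900, k = 5, a = 40, b = 1950)
#' halfnormal_cumulative(2000, k = 5, a = 40, b = 1950) # == maximum
#' @export
halfnormal_cumulative <- function(year, k, a, b) {
  if (!is.numeric(a) || any(a <= 0)) {
    abort("`a` (standard deviation, years) must be > 0.",
      class = "descurves_error_params"
    )
  }
  if (!is.numeric(k) || any(k < 0)) {
    abort("`k` (scale parameter) must be >= 0.",
      class = "descurves_error_params"
    )
  }
  m <- k / (a * sqrt(2 * pi)) + 1
  z <- pmin(year - b, 0) / a
  m * exp(-0.5 * z^2)
}

#' Gompertz cumulative description curve
#'
#' Saturating alternative to [halfnormal_cumulative()]:
#' \eqn{D(Y) = K \exp(-\exp(-c (Y - m)))}, with asymptote `K` and inflection
#' at year `m` (where the curve passes `K / e`).
#'
#' @param year Numeric vector of calendar years.
#' @param K Positive asymptote (scaled-cumulative units).
#' @param c Positive growth rate (1/years).
#' @param m Inflection year.
#' @return Numeric vector of curve values, nondecreasing in `year`.
#' @export
gompertz_cumulative <- function(year, K, c, m) {
  if (any(K <= 0) || any(c <= 0)) {
    abort("`K` and `c` must be > 0.", class = "descurves_error_params")
  }
  K * exp(-exp(-c * (year - m)))
}

#' Von Bertalanffy cumulative description curve
#'
#' Saturating alternative to [halfnormal_cumulative()]:
#' \eqn{D(Y) = K \max(0, 1 - \exp(-r (Y - t_0)))}, zero at `t0`, asymptote
#' `K`, half-saturation at `t0 + log(2) / r`.
#'
#' @param year Numeric vector of calendar years.
#' @param K Positive asymptote (scaled-cumulative units).
#' @param r Positive rate constant (1/years).
#' @param t0 Year at which the curve leaves zero.
#' @return Numeric vector of curve values, nondecreasing in `year`.
#' @export
bertalanffy_cumulative <- function(year, K, r, t0) {
  if (any(K <= 0) || any(r <= 0)) {
    abort("`K` and `r` must be > 0.", class = "descurves_error_params")
  }
  K * pmax(0, 1 - exp(-r * (year - t0)))
}

## Evaluate a fitted model's curve at arbitrary years, given a named
## parameter vector/list.
curve_value <- function(model, year, params) {
  p <- as.list(params)
  switch(model,
    halfnormal = halfnormal_cumulative(year, p$k, p$a, p$b),
    gompertz = gompertz_cumulative(year, p$K, p$c, p$m),
    bertalanffy = bertalanffy_cumulative(year, p$K, p$r, p$t0),
    abort(paste0("Unknown model: ", model), class = "descurves_error_params")
  )
}

## Asymptote of a fitted model.
curve_asymptote <- function(model, params) {
  p <- as.list(params)
  switch(model,
    halfnormal = p$k / (p$a * sqrt(2 * pi)) + 1,
    gompertz = p$K,
    bertalanffy = p$K
  )
}

## Smallest year at which the curve reaches `target` (continuous solution).
curve_inverse <- function(model, params, target) {
  p <- as.list(params)
  asy <- curve_asymptote(model, params)
  if (target > asy) {
    abort("Target value exceeds the curve asymptote.",
      class = "descurves_error_params"
    )
  }
  switch(model,
    halfnormal = p$b - p$a * sqrt(2 * log(asy / target)),
    gompertz = p$m - log(-log(target / p$K)) / p$c,
    bertalanffy = p$t0 - log(1 - target / p$K) / p$r
  )
}
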