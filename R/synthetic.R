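#' Default seasonal profile of a monthly outpatient series
#'
#' Multiplicative month factors with a January-February peak (1.25, 1.20), a
#' sharp July dip (0.80) and a stable remainder; the factors average exactly
#' 1 so that an unseasonal month contributes no seasonal deviation.
#'
#' @return A numeric vector of 12 factors, named Jan..Dec.
#' @export
default_monthly_profile <- function() {
  setNames(c(1.25, 1.20, 1.00, 0.98, 0.96, 0.95, 0.80, 0.95, 0.96, 0.98, 0.99, 0.98),
           month.abb)
}

#' Simulate a monthly outpatient-visit series
#'
#' Generates `12 * n_years` months of
#' `value(t) = (baseline + trend_per_month * t) * profile[month] + N(0, noise_sd)`
#' with `t` the 0-based month offset — a slowly trending level, a
#' multiplicative seasonal swing that grows mildly with the level, and
#' additive Gaussian noise. Defaults emulate a ~9-year hospital series of
#' roughly 30000 visits/month with a winter peak and a July dip. Fully
#' determined by `seed`.
#'
#' @param n_years Number of years (>= 2; default 9).
#' @param baseline Mean level at the first month, visits/month (default 30000).
#' @param monthly_profile 12 positive multiplicative month factors
#'   (default [default_monthly_profile()]).
#' @param trend_per_month Linear level drift, visits/month per month
#'   (default 50).
#' @param noise_sd Standard deviation of the additive noise, visits
#'   (default 1000).
#' @param seed Integer seed (default 1).
#' @param start First month as `"YYYY-MM"` (default "2005-01").
#' @return A monthly series tibble (`date`, `value`).
#' @examples
#' x <- simulate_outpatient_series(seed = 1)
#' nrow(x)  # 108
#' @export
simulate_outpatient_series <- function(n_years = 9L, baseline = 30000,
                                       monthly_profile = default_monthly_profile(),
                                       trend_per_month = 50, noise_sd = 1000,
                                       seed = 1L, start = "2005-01") {
  comp <- simulate_components(n_years, baseline, monthly_profile,
                              trend_per_month, noise_sd, seed, start)
  tibble::tibble(date = comp$date,
                 value = comp$seasonal + comp$trend + comp$noise)
}

#' Ground-truth additive components of the simulated series
#'
#' The same draw as [simulate_outpatient_series()] (same seed, same
#' arguments), split into additive parts that sum exactly to the generated
#' values: `trend` is the affine level `baseline + trend_per_month * t`,
#' `seasonal` is the level times `(profile - 1)`, and `noise` is the Gaussian
#' draw. Used as the oracle in decomposition-recovery checks.
#'
#' @inheritParams simulate_outpatient_series
#' @return A tibble with columns `date`, `seasonal`, `trend`, `noise`.
#' @export
simulate_components <- function(n_years = 9L, baseline = 30000,
                                monthly_profile = default_monthly_profile(),
                                trend_per_month = 50, noise_sd = 1000,
                                seed = 1L, start = "2005-01") {
  if (n_years < 2) abort("`n_years` must be >= 2.", class = "emdcast_invalid_input")
  if (baseline <= 0) abort("`baseline` must be > 0.", class = "emdcast_invalid_input")
  if (length(monthly_profile) != 12 || any(monthly_profile <= 0)) {
    abort("`monthly_profile` must be 12 positive factors.", class = "emdcast_invalid_input")
  }
  n <- 12L * as.integer(n_years)
  t <- seq_len(n) - 1L
  level <- baseline + trend_per_month * t
  dates <- month_seq(parse_month(start), n)
  factors <- as.numeric(monthly_profile)[as.integer(format(dates, "%m"))]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n)
  tibble::tibble(date = dates,
                 seasonal = level * (factors - 1),
                 trend = level,
                 noise = noise)
}
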