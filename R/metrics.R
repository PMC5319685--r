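#' Forecast evaluation criteria
#'
#' The four level-prediction criteria used throughout the package:
#' * `r_criterion()` — Pearson linear correlation between predictions and
#'   observations, in \[-1, 1\];
#' * `rmse()` — root mean squared error, in the units of the series;
#' * `mape()` — mean absolute percentage error, returned as a fraction
#'   (multiply by 100 to display as percent);
#' * `sse()` — sum of squared errors, which satisfies `sse = n * rmse^2`.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return A single numeric value.
#' @examples
#' rmse(c(3, 4), c(0, 0))       # sqrt(12.5)
#' mape(c(110), c(100))         # 0.10
#' @name criteria
NULL

#' @rdname criteria
#' @export
r_criterion <- function(predicted, observed) {
  check_equal_length(predicted, observed)
  if (length(observed) < 2) {
    abort("Correlation needs at least 2 points.", class = "emdcast_invalid_input")
  }
  if (sd(predicted) == 0 || sd(observed) == 0) {
    abort("Correlation is undefined for a constant vector.",
          class = "emdcast_degenerate_input")
  }
  cor(predicted, observed)
}

#' @rdname criteria
#' @export
rmse <- function(predicted, observed) {
  check_equal_length(predicted, observed)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname criteria
#' @export
mape <- function(predicted, observed) {
  check_equal_length(predicted, observed)
  if (any(observed == 0)) {
    abort("MAPE is undefined when an observed value is zero.",
          class = "emdcast_degenerate_input")
  }
  mean(abs(predicted - observed) / abs(observed))
}

#' @rdname criteria
#' @export
sse <- function(predicted, observed) {
  check_equal_length(predicted, observed)
  sum((predicted - observed)^2)
}

#' Bundle all four criteria into one row
#'
#' @inheritParams criteria
#' @return A one-row tibble with columns `R`, `RMSE`, `MAPE`, `SSE`, `n`.
#' @export
metric_bundle <- function(predicted, observed) {
  tibble::tibble(R = r_criterion(predicted, observed),
                 RMSE = rmse(predicted, observed),
                 MAPE = mape(predicted, observed),
                 SSE = sse(predicted, observed),
                 n = length(observed))
}

#' Seasonal fluctuation index by calendar month
#'
#' For each calendar month c, the absolute deviation of that month's
#' across-year average from the overall average, normalized by the overall
#' average: `|mean_same - mean_all| / mean_all`. High values flag strongly
#' seasonal months (for outpatient series, typically the January-February
#' peak and the July dip).
#'
#' @param data Monthly series tibble spanning at least 2 full years.
#' @return A 12-row tibble with columns `month` (1-12) and `sfi1`.
#' @export
sfi1 <- function(data) {
  data <- validate_monthly_series(data)
  if (nrow(data) < 24) {
    abort("SFI1 needs at least 2 full years of data.", class = "emdcast_invalid_input")
  }
  overall <- mean(data$value)
  if (overall == 0) {
    abort("SFI1 is undefined for a zero-mean series.", class = "emdcast_degenerate_input")
  }
  data |>
    dplyr::mutate(month = as.integer(format(.data$date, "%m"))) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(sfi1 = abs(mean(.data$value) - overall) / abs(overall),
                     .groups = "drop") |>
    dplyr::arrange(.data$month)
}

#' Seasonal fluctuation index of each step of a segment
#'
#' Per step i: `|x_i - mean(x)| / mean(x)` with the mean taken over the
#' segment (typically the forecast horizon).
#'
#' @param x Numeric vector with nonzero mean.
#' @return Numeric vector, same length as `x`.
#' @export
sfi2 <- function(x) {
  m <- mean(x)
  if (m == 0) {
    abort("SFI2 is undefined for a zero-mean segment.", class = "emdcast_degenerate_input")
  }
  abs(x - m) / abs(m)
}

#' Relative error of each predicted step
#'
#' Per step: `|predicted_i - observed_i| / observed_i`. Equals MAPE when the
#' horizon has a single step.
#'
#' @inheritParams criteria
#' @return Numeric vector of per-step relative errors.
#' @export
relative_error <- function(predicted, observed) {
  check_equal_length(predicted, observed)
  if (any(observed == 0)) {
    abort("Relative error is undefined when an observed value is zero.",
          class = "emdcast_degenerate_input")
  }
  abs(predicted - observed) / abs(observed)
}

check_equal_length <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.",
          class = "emdcast_invalid_input")
  }
  invisible(TRUE)
}
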