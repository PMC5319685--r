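#' Build a monthly time-series tibble
#'
#' The package's working representation of a monthly series is a tibble with a
#' `date` column (class `Date`, always the first day of the month, strictly
#' consecutive calendar months) and a numeric `value` column. All pipeline
#' functions take and return this shape.
#'
#' @param values Numeric vector of observations (length >= 2, all finite).
#' @param start First month, as `"YYYY-MM"` or a `Date`.
#' @return A tibble with columns `date` and `value`.
#' @examples
#' monthly_series(c(100, 120, 90), start = "2005-01")
#' @export
monthly_series <- function(values, start = "2005-01") {
  if (length(values) < 2) {
    abort("`values` must contain at least 2 observations.", class = "emdcast_invalid_input")
  }
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort("`values` must be finite numeric.", class = "emdcast_invalid_input")
  }
  tibble::tibble(date = month_seq(parse_month(start), length(values)),
                 value = as.numeric(values))
}

#' Validate a monthly series tibble
#'
#' Checks the contract described in [monthly_series()]: a `date` column of
#' consecutive first-of-month dates and a finite numeric `value` column.
#' Called internally by every function that consumes a series; exported so
#' callers can validate external data early.
#'
#' @param data A data frame with columns `date` and `value`.
#' @return `data`, invisibly, as a tibble; errors describe the first violation.
#' @export
validate_monthly_series <- function(data) {
  if (!is.data.frame(data) || !all(c("date", "value") %in% names(data))) {
    abort("`data` must be a data frame with columns `date` and `value`.",
          class = "emdcast_invalid_input")
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2) {
    abort("Monthly series must have at least 2 rows.", class = "emdcast_invalid_input")
  }
  d <- as.Date(data$date)
  if (anyNA(d)) abort("`date` contains unparseable entries.", class = "emdcast_invalid_input")
  if (!is.numeric(data$value) || !all(is.finite(data$value))) {
    abort("`value` must be finite numeric.", class = "emdcast_invalid_input")
  }
  expected <- month_seq(d[1], length(d))
  if (!identical(as.character(d), as.character(expected))) {
    bad <- which(as.character(d) != as.character(expected))[1]
    abort(sprintf("Months are not consecutive: expected %s at row %d, found %s.",
                  format(expected[bad], "%Y-%m"), bad, format(d[bad], "%Y-%m")),
          class = "emdcast_gap_error")
  }
  invisible(data)
}

#' Split a monthly series into training and test spans by calendar month
#'
#' @param data Monthly series tibble (see [monthly_series()]).
#' @param last_train_month Last month kept in the training span (`"YYYY-MM"`
#'   or `Date`); must lie strictly inside the series so that the test span is
#'   non-empty.
#' @return A list with tibbles `train` and `test`; row counts sum to
#'   `nrow(data)`.
#' @examples
#' x <- monthly_series(seq_len(24), start = "2005-01")
#' sp <- split_by_date(x, "2006-06")
#' nrow(sp$train); nrow(sp$test)
#' @export
split_by_date <- function(data, last_train_month) {
  data <- validate_monthly_series(data)
  cut <- parse_month(last_train_month)
  d <- as.Date(data$date)
  if (cut < d[1] || cut >= d[length(d)]) {
    abort(sprintf("`last_train_month` (%s) must lie inside the series and leave a test span.",
                  format(cut, "%Y-%m")), class = "emdcast_invalid_input")
  }
  if (!any(d == cut)) {
    abort(sprintf("`last_train_month` (%s) is not a month of the series.",
                  format(cut, "%Y-%m")), class = "emdcast_invalid_input")
  }
  list(train = data[d <= cut, , drop = FALSE],
       test  = data[d > cut, , drop = FALSE])
}

# "YYYY-MM" (or Date) -> Date at first of month
parse_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  if (is.character(x) && grepl("^\\d{4}-\\d{2}$", x)) {
    return(as.Date(paste0(x, "-01")))
  }
  d <- suppressWarnings(as.Date(x))
  if (length(d) == 1 && !is.na(d)) return(as.Date(format(d, "%Y-%m-01")))
  abort(sprintf("Cannot parse '%s' as a calendar month (expected YYYY-MM).", as.character(x)),
        class = "emdcast_invalid_input")
}

month_seq <- function(start, n) seq(start, by = "month", length.out = n)
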