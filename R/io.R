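#' Read a monthly series from CSV
#'
#' Expects a UTF-8 comma-separated file with header `date,value`, dates
#' formatted `YYYY-MM` and `.` as the decimal point. The file is validated,
#' not repaired: a missing month or an unparseable value is an error naming
#' the offending month or row.
#'
#' @param path Path to the CSV file.
#' @return A monthly series tibble (`date`, `value`).
#' @export
read_monthly_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "emdcast_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("date", "value") %in% names(raw))) {
    abort(sprintf("%s: expected header `date,value`, found `%s`.",
                  path, paste(names(raw), collapse = ",")),
          class = "emdcast_parse_error")
  }
  if (!all(grepl("^\\d{4}-\\d{2}$", raw$date))) {
    bad <- which(!grepl("^\\d{4}-\\d{2}$", raw$date))[1]
    abort(sprintf("%s: row %d has date '%s', expected YYYY-MM.", path, bad, raw$date[bad]),
          class = "emdcast_parse_error")
  }
  vals <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort(sprintf("%s: row %d has unparseable value '%s'.", path, bad, raw$value[bad]),
          class = "emdcast_parse_error")
  }
  out <- tibble::tibble(date = as.Date(paste0(raw$date, "-01")), value = vals)
  validate_monthly_series(out)
  out
}

#' Write a monthly series to CSV
#'
#' Inverse of [read_monthly_csv()]: dates written as `YYYY-MM`.
#'
#' @param data Monthly series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_csv <- function(data, path) {
  data <- validate_monthly_series(data)
  readr::write_csv(dplyr::mutate(data, date = format(.data$date, "%Y-%m")), path)
  invisible(path)
}

#' Read the supplementary outpatient-visit dataset
#'
#' Ingests a plain-text (CSV/TSV) conversion of the supplementary monthly
#' outpatient-count workbook, auto-detecting either of the two layouts such a
#' sheet commonly takes: a 108-row `date,value` (or `year,month,value`) list,
#' or a 12-by-9 grid of months by years. Legacy binary `.xls` files are not
#' parsed; convert the sheet to CSV first (any spreadsheet tool or
#' `ssconvert`/`in2csv` will do) and pass the conversion.
#'
#' @param path Path to the converted file.
#' @param expected_months Number of months the sheet must span (default 108,
#'   i.e. Jan 2005 - Dec 2013; set `NULL` to skip the check).
#' @param start First month of the series when the layout carries no dates
#'   (default "2005-01").
#' @return A monthly series tibble; a message reports which layout was
#'   detected.
#' @export
read_s1_dataset <- function(path, expected_months = 108L, start = "2005-01") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "emdcast_io_error")
  }
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    abort(paste0("Binary workbook files are not parsed directly; export the sheet ",
                 "to CSV and pass the conversion."), class = "emdcast_io_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  # drop a header row: either all label cells, or year labels of a grid layout
  first_numeric <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  numeric_cells <- first_numeric[!is.na(first_numeric)]
  is_header <- length(numeric_cells) == 0 ||
    all(numeric_cells == floor(numeric_cells) &
          numeric_cells >= 1900 & numeric_cells <= 2100)
  if (is_header) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) {
    abort(sprintf("%s: sheet is empty.", path), class = "emdcast_validation_error")
  }

  if (ncol(raw) >= 4) {                      # months-by-years grid
    grid <- raw
    # first column may label the months; keep numeric columns only
    numeric_cols <- vapply(grid, function(col) {
      !all(is.na(suppressWarnings(as.numeric(col))))
    }, logical(1))
    grid <- grid[, numeric_cols, drop = FALSE]
    if (nrow(grid) != 12) {
      abort(sprintf("%s: grid layout must have 12 month rows, found %d.", path, nrow(grid)),
            class = "emdcast_validation_error")
    }
    vals <- as.numeric(as.matrix(grid))      # column-major: year by year
    layout <- sprintf("12x%d months-by-years grid", ncol(grid))
  } else {                                   # row-per-month list
    value_col <- ncol(raw)
    vals <- suppressWarnings(as.numeric(raw[[value_col]]))
    layout <- sprintf("%d-row monthly list", nrow(raw))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort(sprintf("%s: non-numeric cell at position %d.", path, bad),
          class = "emdcast_parse_error")
  }
  if (!is.null(expected_months) && length(vals) != expected_months) {
    abort(sprintf("%s: expected %d months, found %d.", path, expected_months, length(vals)),
          class = "emdcast_validation_error")
  }
  message(sprintf("Detected layout: %s.", layout))
  monthly_series(vals, start = start)
}

#' Write a decomposition to CSV
#'
#' Columns `date,imf1..imfk,residue`, dates as `YYYY-MM`.
#'
#' @param decomposition An `emd_decomposition` from [emd()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomposition, path) {
  stopifnot(inherits(decomposition, "emd_decomposition"))
  out <- tibble::as_tibble(decomposition)
  out$date <- format(out$date, "%Y-%m")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a forecast report to a directory
#'
#' Writes `predictions.csv` (`date,observed,predicted,component columns`),
#' `metrics.csv` (one row: R, RMSE, MAPE, SSE, n) and `seasonality.csv`
#' (long format: `step,date,sfi2,re` over the horizon). Values survive a
#' write/read round trip to full double precision.
#'
#' @param report A `forecast_report` from [predict.hybrid_model()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "forecast_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pred <- report$predictions
  stopifnot(nrow(pred) > 0)
  files <- c(predictions = file.path(dir, "predictions.csv"),
             metrics = file.path(dir, "metrics.csv"),
             seasonality = file.path(dir, "seasonality.csv"))
  out <- pred
  out$date <- format(out$date, "%Y-%m")
  readr::write_csv(out, files["predictions"])
  readr::write_csv(report$metrics, files["metrics"])
  seas <- tibble::tibble(step = seq_len(nrow(pred)),
                         date = format(pred$date, "%Y-%m"),
                         sfi2 = sfi2(pred$observed),
                         re = relative_error(pred$predicted, pred$observed))
  readr::write_csv(seas, files["seasonality"])
  invisible(files)
}

#' Read a nested run configuration from YAML
#'
#' Sections `sift`, `train`, `pso` and `sim` mirror [sift_config()],
#' [train_config()], [pso_config()] and the [simulate_outpatient_series()]
#' arguments; top-level keys `seed` and `paths` are passed through. Unknown
#' sections or keys are rejected, and omitted keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `sift`, `train`, `pso`, `sim`, `seed`,
#'   `paths`; the first three are ready-made config objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "emdcast_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("sift", "train", "pso", "sim", "seed", "paths")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("%s: unknown config section(s): %s.", path, paste(extra, collapse = ", ")),
          class = "emdcast_validation_error")
  }
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(raw[[section]]), allowed)
    if (length(bad)) {
      abort(sprintf("%s: unknown key(s) in `%s`: %s.", path, section,
                    paste(bad, collapse = ", ")), class = "emdcast_validation_error")
    }
    raw[[section]] %||% list()
  }
  sift_args <- check_keys("sift", names(formals(sift_config)))
  train_args <- check_keys("train", names(formals(train_config)))
  pso_args <- check_keys("pso", names(formals(pso_config)))
  sim_args <- check_keys("sim", names(formals(simulate_outpatient_series)))
  seed <- raw$seed %||% 1L
  list(sift = do.call(sift_config, sift_args),
       train = do.call(train_config, c(train_args, if (!("seed" %in% names(train_args))) list(seed = seed))),
       pso = do.call(pso_config, c(pso_args, if (!("seed" %in% names(pso_args))) list(seed = seed))),
       sim = sim_args,
       seed = as.integer(seed),
       paths = raw$paths %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
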