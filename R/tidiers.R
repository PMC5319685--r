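#' Tidy a decomposition into long format
#'
#' @param x An `emd_decomposition`.
#' @param ... Unused.
#' @return A tibble with columns `date`, `component` (factor, extraction
#'   order, residue last) and `value`.
#' @exportS3Method generics::tidy
tidy.emd_decomposition <- function(x, ...) {
  comps <- component_names(x)
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(comps), names_to = "component",
                        values_to = "value") |>
    dplyr::mutate(component = factor(.data$component, levels = comps)) |>
    dplyr::arrange(.data$component, .data$date)
}

#' One-row summary of a decomposition
#'
#' @param x An `emd_decomposition`.
#' @param ... Unused.
#' @return A tibble with `n_imfs`, `n_obs`, `reconstruction_error` (maximum
#'   absolute gap between the source and the component sum, relative to the
#'   source magnitude).
#' @exportS3Method generics::glance
glance.emd_decomposition <- function(x, ...) {
  src <- attr(x, "source")
  recon <- rowSums(as.matrix(tibble::as_tibble(x)[component_names(x)]))
  tibble::tibble(n_imfs = n_imfs(x), n_obs = nrow(x),
                 reconstruction_error = max(abs(src - recon)) / max(abs(src)))
}

#' Tidy the per-component training summary of a hybrid model
#'
#' @param x A `hybrid_model`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `pso_fitness`
#'   (best swarm MSE, `NA` for plain training), `train_mse` (last epoch),
#'   `final_mse` (best epoch, the retained parameters), `epochs`, `seed`.
#' @exportS3Method generics::tidy
tidy.hybrid_model <- function(x, ...) {
  purrr::imap_dfr(x$components, function(cm, nm) {
    tibble::tibble(component = nm, pso_fitness = cm$pso_fitness,
                   train_mse = cm$train_mse, final_mse = cm$final_mse,
                   epochs = cm$epochs, seed = cm$seed)
  })
}

#' One-row summary of a hybrid model
#'
#' @param x A `hybrid_model`.
#' @param ... Unused.
#' @return A tibble with `mode`, `n_components`, `n_lags`, `n_hidden`,
#'   `n_train`, `seed`.
#' @exportS3Method generics::glance
glance.hybrid_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_components = length(x$components),
                 n_lags = x$n_lags, n_hidden = x$n_hidden,
                 n_train = x$n_train, seed = x$seed)
}

#' Tidy forecast-report predictions
#'
#' @param x A `forecast_report`.
#' @param ... Unused.
#' @return The predictions tibble (`date`, `observed`, `predicted`, one
#'   column per component).
#' @exportS3Method generics::tidy
tidy.forecast_report <- function(x, ...) x$predictions

#' One-row forecast-report summary
#'
#' @param x A `forecast_report`.
#' @param ... Unused.
#' @return A tibble with `R`, `RMSE`, `MAPE`, `SSE`, `n`, `scheme`, `mode`.
#' @exportS3Method generics::glance
glance.forecast_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(scheme = x$scheme, mode = x$mode))
}

#' Plot a decomposition, one panel per component
#'
#' @param object An `emd_decomposition`.
#' @param ... Unused.
#' @return A ggplot object: the source series on top, then each intrinsic
#'   mode function and the residue in extraction order.
#' @exportS3Method ggplot2::autoplot
autoplot.emd_decomposition <- function(object, ...) {
  long <- tidy(object)
  src <- tibble::tibble(date = object$date, component = "source",
                        value = attr(object, "source"))
  lv <- c("source", component_names(object))
  dat <- dplyr::bind_rows(src, dplyr::mutate(long, component = as.character(.data$component))) |>
    dplyr::mutate(component = factor(.data$component, levels = lv))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Empirical mode decomposition") +
    ggplot2::theme_minimal()
}

#' Plot observed and forecast values over the horizon
#'
#' @param object A `forecast_report`.
#' @param ... Unused.
#' @return A ggplot object with observed and predicted series.
#' @exportS3Method ggplot2::autoplot
autoplot.forecast_report <- function(object, ...) {
  dat <- object$predictions |>
    dplyr::select("date", "observed", "predicted") |>
    tidyr::pivot_longer(c("observed", "predicted"), names_to = "series",
                        values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "visits / month", colour = NULL,
                  title = sprintf("Forecast (%s, %s)", object$mode, object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot relative forecast error against the seasonal fluctuation index
#'
#' Bars show the per-step relative error of the forecast; the line shows the
#' seasonal fluctuation index of the observed horizon, making visible how
#' error concentrates in the strongly seasonal months.
#'
#' @param report A `forecast_report`.
#' @return A ggplot object.
#' @export
plot_seasonal_error <- function(report) {
  stopifnot(inherits(report, "forecast_report"))
  pred <- report$predictions
  dat <- tibble::tibble(date = pred$date,
                        re = relative_error(pred$predicted, pred$observed),
                        sfi2 = sfi2(pred$observed))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$re), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sfi2), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$sfi2), colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "relative error (bars), SFI2 (line)",
                  title = "Forecast error vs seasonal fluctuation") +
    ggplot2::theme_minimal()
}
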