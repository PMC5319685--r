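#' Fit the hybrid decomposition-network forecaster
#'
#' The six-stage pipeline: (1) decompose the series into intrinsic mode
#' functions plus a residue (`mode = "emd_pso_bpann"`), (2) min-max normalize
#' each component to \[-1, 1\], (3) encode each component network's weights
#' and thresholds as a particle and optimize them by particle swarm, (4)
#' refine each network by resilient backpropagation from the swarm optimum,
#' then (via [predict.hybrid_model()]) (5) forecast every component and (6)
#' superpose the component forecasts. `mode = "pso_bpann"` skips the
#' decomposition (one network on the raw series); `mode = "bpann"`
#' additionally skips the swarm and trains from random initial weights.
#'
#' By default the decomposition is computed on the full series before the
#' train/test split (the classical presentation of the method, which lets
#' test-period observations shape the components);
#' `decomposition_scope = "train"` restricts it to the training span for a
#' leakage-free fit, in which case only recursive forecasting is available
#' for the component series.
#'
#' @param data Monthly series tibble covering training and test spans.
#' @param last_train_month Last month of the training span (`"YYYY-MM"`).
#' @param mode `"emd_pso_bpann"` (default), `"pso_bpann"` or `"bpann"`.
#' @param n_lags Lagged inputs per network (default 3).
#' @param n_hidden Hidden nodes (default `hidden_node_count(n_lags, 1, 10)`,
#'   i.e. 14 for 3 lags).
#' @param scfg,tcfg,pcfg [sift_config()], [train_config()], [pso_config()].
#' @param decomposition_scope `"full"` (default) or `"train"`.
#' @param seed Master seed; per-component seeds are derived from it
#'   deterministically, so the whole fit is reproducible.
#' @return An object of class `hybrid_model` holding the decomposition (in
#'   decomposition mode), one `(params, normalizer)` pair per component, the
#'   per-component swarm fitness and training history, and the configuration.
#' @examples
#' \donttest{
#' x <- simulate_outpatient_series(seed = 1)
#' fit <- hybrid_fit(x, "2012-11", mode = "bpann",
#'                   tcfg = train_config(max_epochs = 50), seed = 1)
#' rep <- predict(fit)
#' glance(rep)
#' }
#' @export
hybrid_fit <- function(data, last_train_month,
                       mode = c("emd_pso_bpann", "pso_bpann", "bpann"),
                       n_lags = 3L, n_hidden = NULL,
                       scfg = sift_config(), tcfg = train_config(),
                       pcfg = pso_config(),
                       decomposition_scope = c("full", "train"),
                       seed = 1L) {
  mode <- match.arg(mode)
  decomposition_scope <- match.arg(decomposition_scope)
  data <- validate_monthly_series(data)
  sp <- split_by_date(data, last_train_month)
  n_train <- nrow(sp$train)
  if (n_train <= n_lags + 1L) {
    abort("Training span too short for lag embedding.", class = "emdcast_invalid_input")
  }
  if (is.null(n_hidden)) n_hidden <- hidden_node_count(n_lags, 1L, 10L)

  decomposition <- NULL
  if (mode == "emd_pso_bpann") {
    dec_input <- if (decomposition_scope == "full") data else sp$train
    decomposition <- emd(dec_input, scfg)
    comp_names <- component_names(decomposition)
    comp_train <- lapply(comp_names, function(nm) decomposition[[nm]][seq_len(n_train)])
    names(comp_train) <- comp_names
  } else {
    comp_train <- list(series = sp$train$value)
  }

  components <- vector("list", length(comp_train))
  names(components) <- names(comp_train)
  for (i in seq_along(comp_train)) {
    nm <- names(comp_train)[i]
    cseed <- derive_seed(seed, i)
    res <- tryCatch(
      fit_component(comp_train[[i]], mode, n_lags, n_hidden, tcfg, pcfg, cseed),
      error = function(e) {
        abort(sprintf("Fitting component '%s' failed: %s", nm, conditionMessage(e)),
              class = "emdcast_component_failure", parent = e)
      })
    components[[i]] <- res
  }

  structure(list(mode = mode, n_lags = as.integer(n_lags),
                 n_hidden = as.integer(n_hidden),
                 decomposition = decomposition,
                 decomposition_scope = decomposition_scope,
                 components = components,
                 data = data, last_train_month = parse_month(last_train_month),
                 n_train = n_train,
                 configs = list(sift = scfg, train = tcfg, pso = pcfg),
                 seed = as.integer(seed)),
            class = "hybrid_model")
}

# one component: normalize -> lag-embed -> (PSO ->) refine-train
fit_component <- function(series, mode, n_lags, n_hidden, tcfg, pcfg, cseed) {
  nrm <- normalize(series)
  le <- lag_embed(nrm$scaled, n_lags)
  if (mode == "bpann") {
    init <- mlp_init(n_lags, n_hidden, seed = cseed)
    pso_fitness <- NA_real_
  } else {
    D <- particle_dimension(n_lags, n_hidden, 1L)
    objective <- function(pos) mlp_fitness(pos, le$inputs, le$targets, n_lags, n_hidden)
    pcfg_c <- pcfg
    pcfg_c$seed <- cseed
    opt <- pso_optimize(objective, D, pcfg_c)
    init <- mlp_decode(opt$best_position, n_lags, n_hidden)
    pso_fitness <- opt$best_fitness
  }
  tr <- mlp_train(init, le$inputs, le$targets, tcfg)
  list(params = tr$params, normalizer = nrm$normalizer,
       pso_fitness = pso_fitness,
       train_mse = tr$history[length(tr$history)],
       final_mse = min(tr$history), epochs = tr$epochs, seed = cseed)
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 97 + 1009 * i) %% (2^31 - 1))
}

#' Forecast the test span with a fitted hybrid model
#'
#' Forecasts every month after `last_train_month` through the end of the
#' fitted data. With `scheme = "one_step_ahead"` each step is predicted from
#' *observed* lagged component values (teacher forcing); with
#' `scheme = "recursive"` the model's own predictions are fed back as lags.
#' Component predictions are denormalized and summed, so the reported
#' forecast is exactly the column sum of the per-component forecasts.
#'
#' @param object A `hybrid_model` from [hybrid_fit()].
#' @param scheme `"one_step_ahead"` (default) or `"recursive"`.
#' @param ... Unused.
#' @return An object of class `forecast_report`: list with `predictions` (a
#'   tibble `date`, `observed`, `predicted`, plus one column per component),
#'   `metrics` (one-row tibble: R, RMSE, MAPE, SSE, n), `scheme` and `mode`.
#' @export
predict.hybrid_model <- function(object,
                                 scheme = c("one_step_ahead", "recursive"),
                                 ...) {
  scheme <- match.arg(scheme)
  model <- object
  data <- model$data
  n <- nrow(data)
  n_train <- model$n_train
  horizon <- (n_train + 1L):n
  L <- model$n_lags

  if (model$mode == "emd_pso_bpann") {
    comp_obs <- lapply(component_names(model$decomposition),
                       function(nm) model$decomposition[[nm]])
    names(comp_obs) <- component_names(model$decomposition)
    if (scheme == "one_step_ahead" && nrow(model$decomposition) < n) {
      abort(paste0("One-step-ahead forecasting needs component observations over the ",
                   "horizon; a train-scope decomposition only supports scheme = 'recursive'."),
            class = "emdcast_invalid_input")
    }
  } else {
    comp_obs <- list(series = data$value)
  }

  per_comp <- matrix(NA_real_, nrow = length(horizon), ncol = length(model$components),
                     dimnames = list(NULL, names(model$components)))
  for (i in seq_along(model$components)) {
    cm <- model$components[[i]]
    obs <- comp_obs[[names(model$components)[i]]]
    z <- apply_normalizer(obs, cm$normalizer)
    if (scheme == "one_step_ahead") {
      preds_z <- vapply(horizon, function(t) {
        mlp_forward(cm$params, z[(t - L):(t - 1L)])
      }, numeric(1))
    } else {
      zbuf <- z[seq_len(n_train)]
      preds_z <- numeric(length(horizon))
      for (k in seq_along(horizon)) {
        preds_z[k] <- mlp_forward(cm$params, zbuf[(length(zbuf) - L + 1L):length(zbuf)])
        zbuf <- c(zbuf, preds_z[k])
      }
    }
    per_comp[, i] <- denormalize(preds_z, cm$normalizer)
  }

  predicted <- rowSums(per_comp)
  observed <- data$value[horizon]
  predictions <- tibble::tibble(date = data$date[horizon],
                                observed = observed, predicted = predicted)
  for (nm in colnames(per_comp)) predictions[[nm]] <- per_comp[, nm]
  structure(list(predictions = predictions,
                 metrics = metric_bundle(predicted, observed),
                 scheme = scheme, mode = model$mode,
                 seed = model$seed),
            class = "forecast_report")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("Hybrid forecaster (%s): %d component network(s), %d-%d-1, trained through %s\n",
              x$mode, length(x$components), x$n_lags, x$n_hidden,
              format(x$last_train_month, "%Y-%m")))
  invisible(x)
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf("Forecast report (%s, %s): %d months\n", x$mode, x$scheme,
              nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Compare forecasting modes across seeds
#'
#' Runs [hybrid_fit()] + [predict.hybrid_model()] for every combination of
#' mode and master seed on the same split, and collects the evaluation
#' criteria into one tidy table.
#'
#' @inheritParams hybrid_fit
#' @param methods Character vector of modes to run.
#' @param seeds Integer vector of master seeds.
#' @param scheme Forecast scheme passed to the predict step.
#' @return A tibble with one row per (method, seed): columns `method`,
#'   `seed`, `R`, `RMSE`, `MAPE`, `SSE`, `n`.
#' @export
compare_methods <- function(data, last_train_month,
                            methods = c("emd_pso_bpann", "bpann"),
                            seeds = 1L,
                            scheme = c("one_step_ahead", "recursive"),
                            n_lags = 3L, n_hidden = NULL,
                            scfg = sift_config(), tcfg = train_config(),
                            pcfg = pso_config(),
                            decomposition_scope = c("full", "train")) {
  scheme <- match.arg(scheme)
  decomposition_scope <- match.arg(decomposition_scope)
  if (length(methods) < 1) {
    abort("At least one method is required.", class = "emdcast_invalid_input")
  }
  grid <- tidyr::expand_grid(method = methods, seed = as.integer(seeds))
  purrr::pmap_dfr(grid, function(method, seed) {
    fit <- hybrid_fit(data, last_train_month, mode = method, n_lags = n_lags,
                      n_hidden = n_hidden, scfg = scfg, tcfg = tcfg, pcfg = pcfg,
                      decomposition_scope = decomposition_scope, seed = seed)
    rep <- predict(fit, scheme = scheme)
    dplyr::bind_cols(tibble::tibble(method = method, seed = seed), rep$metrics)
  })
}
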