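#' Empirical hidden-layer size rule
#'
#' The hidden node count of a three-layer network is chosen by the empirical
#' rule `n2 = n1 + n3 + m` with `m` an integer in 1..10. With 3 inputs, 1
#' output and `m = 10` this gives the 3-14-1 architecture used throughout the
#' default pipeline.
#'
#' @param n1 Number of input nodes (>= 1).
#' @param n3 Number of output nodes (>= 1).
#' @param m Integer adjustment, 1..10.
#' @return Integer hidden node count.
#' @examples
#' hidden_node_count(3, 1, 10)  # 14
#' @export
hidden_node_count <- function(n1, n3, m) {
  if (n1 < 1 || n3 < 1) abort("`n1` and `n3` must be >= 1.", class = "emdcast_invalid_input")
  if (m < 1 || m > 10) abort("`m` must lie in [1, 10].", class = "emdcast_invalid_input")
  as.integer(n1 + n3 + m)
}

#' Min-max normalization to [-1, 1]
#'
#' Maps the observed minimum to -1 and maximum to +1, the scaling applied to
#' every component series before network training (the classic
#' premnmx/postmnmx convention). [denormalize()] is the exact inverse.
#'
#' @param x Numeric vector with `min(x) < max(x)`.
#' @return A list with `scaled` (numeric vector in \[-1, 1\]) and `normalizer`
#'   (list with `observed_min`, `observed_max`).
#' @examples
#' normalize(c(0, 5, 10))$scaled  # -1 0 1
#' @export
normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("Constant (or non-finite) series cannot be min-max normalized.",
          class = "emdcast_degenerate_input")
  }
  list(scaled = 2 * (x - lo) / (hi - lo) - 1,
       normalizer = list(observed_min = lo, observed_max = hi))
}

#' @rdname normalize
#' @param scaled Numeric vector on the normalized scale.
#' @param normalizer The `normalizer` element returned by [normalize()].
#' @return For `denormalize()`: the vector mapped back to the original scale.
#' @export
denormalize <- function(scaled, normalizer) {
  (scaled + 1) / 2 * (normalizer$observed_max - normalizer$observed_min) +
    normalizer$observed_min
}

# apply an existing normalizer to new values (same affine map as normalize())
apply_normalizer <- function(x, normalizer) {
  2 * (x - normalizer$observed_min) /
    (normalizer$observed_max - normalizer$observed_min) - 1
}

#' Lag embedding of a sequence for autoregressive training
#'
#' Builds the supervised pairs used to train a network as a one-step-ahead
#' autoregression: row k of `inputs` holds `x[k], ..., x[k + n_lags - 1]` and
#' `targets[k]` is `x[k + n_lags]`.
#'
#' @param x Numeric vector, longer than `n_lags`.
#' @param n_lags Number of lagged inputs (>= 1; the pipeline default is 3).
#' @return A list with `inputs` (matrix, `length(x) - n_lags` rows) and
#'   `targets` (numeric vector).
#' @examples
#' lag_embed(1:4, 3)  # one pair: (1,2,3) -> 4
#' @export
lag_embed <- function(x, n_lags) {
  n_lags <- as.integer(n_lags)
  if (n_lags < 1) abort("`n_lags` must be >= 1.", class = "emdcast_invalid_input")
  n <- length(x)
  if (n <= n_lags) {
    abort(sprintf("Series of length %d too short for %d lags.", n, n_lags),
          class = "emdcast_invalid_input")
  }
  k <- n - n_lags
  inputs <- vapply(seq_len(n_lags), function(j) x[j:(j + k - 1L)], numeric(k))
  list(inputs = matrix(inputs, nrow = k), targets = x[(n_lags + 1L):n])
}

#' Three-layer network parameters
#'
#' A container for the weights and thresholds of a feed-forward network with
#' one hidden layer: hidden unit j computes
#' \eqn{H_j = \tanh(\sum_i \omega_{ij} x_i - b_j)} and the single linear
#' output is \eqn{\hat y = \sum_j w_j H_j - b_{out}}. Thresholds are
#' *subtracted*, matching the field's classical sign convention.
#'
#' @param input_hidden_weights Matrix `n_hidden x n_input`.
#' @param hidden_thresholds Numeric vector, length `n_hidden`.
#' @param hidden_output_weights Numeric vector, length `n_hidden`.
#' @param output_threshold Numeric scalar.
#' @return An object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(input_hidden_weights, hidden_thresholds,
                           hidden_output_weights, output_threshold) {
  W1 <- as.matrix(input_hidden_weights)
  nh <- nrow(W1)
  if (length(hidden_thresholds) != nh || length(hidden_output_weights) != nh ||
      length(output_threshold) != 1) {
    abort("Inconsistent parameter shapes for a three-layer network.",
          class = "emdcast_invalid_input")
  }
  p <- list(input_hidden_weights = W1,
            hidden_thresholds = as.numeric(hidden_thresholds),
            hidden_output_weights = as.numeric(hidden_output_weights),
            output_threshold = as.numeric(output_threshold),
            n_input = ncol(W1), n_hidden = nh, n_output = 1L)
  if (!all(vapply(p[1:4], function(v) all(is.finite(v)), logical(1)))) {
    abort("Network parameters must be finite.", class = "emdcast_invalid_input")
  }
  structure(p, class = "mlp_parameters")
}

#' Random initialization of network parameters
#'
#' Uniform on \[-1, 1\] (the same box the particle swarm searches), fully
#' determined by `seed`.
#'
#' @param n_input,n_hidden Layer sizes.
#' @param seed Integer seed.
#' @return An `mlp_parameters` object.
#' @export
mlp_init <- function(n_input, n_hidden, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  mlp_parameters(matrix(runif(n_hidden * n_input, -1, 1), n_hidden, n_input),
                 runif(n_hidden, -1, 1), runif(n_hidden, -1, 1), runif(1, -1, 1))
}

#' Forward pass of the three-layer network
#'
#' @param params An `mlp_parameters` object.
#' @param inputs Numeric vector of length `n_input`, or a matrix with
#'   `n_input` columns (one row per case).
#' @return Numeric vector of network outputs, one per input row.
#' @examples
#' p <- mlp_parameters(matrix(1), 0, 1, 0)
#' mlp_forward(p, 0.5)  # tanh(0.5)
#' @export
mlp_forward <- function(params, inputs) {
  X <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1)
  if (ncol(X) != params$n_input) {
    abort(sprintf("Expected %d inputs per case, got %d.", params$n_input, ncol(X)),
          class = "emdcast_invalid_input")
  }
  H <- tanh(sweep(X %*% t(params$input_hidden_weights), 2, params$hidden_thresholds))
  drop(H %*% params$hidden_output_weights) - params$output_threshold
}

# analytic gradient of mean squared error wrt all parameters
mlp_gradient <- function(params, inputs, targets) {
  X <- inputs
  Z <- sweep(X %*% t(params$input_hidden_weights), 2, params$hidden_thresholds)
  H <- tanh(Z)
  yhat <- drop(H %*% params$hidden_output_weights) - params$output_threshold
  e <- 2 * (yhat - targets) / length(targets)
  dZ <- (e %o% params$hidden_output_weights) * (1 - H^2)
  list(input_hidden_weights = crossprod(dZ, X),        # n_hidden x n_input
       hidden_thresholds = -colSums(dZ),
       hidden_output_weights = drop(crossprod(H, e)),
       output_threshold = -sum(e))
}

mlp_mse <- function(params, inputs, targets) {
  mean((mlp_forward(params, inputs) - targets)^2)
}

#' Training configuration for network refinement
#'
#' Defaults mirror the classical setup for this model family: goal MSE 0.01 on
#' the normalized scale, up to 1000 epochs, minimum gradient 1e-6, learning
#' rate 0.15 (used by the momentum method). `method = "rprop"` performs
#' resilient backpropagation (sign-of-gradient step adaptation, initial step
#' 0.07, increase 1.2, decrease 0.5, step bounds \[1e-6, 50\]);
#' `method = "gdm"` performs plain gradient descent with momentum 0.9.
#'
#' @param max_epochs Epoch cap (default 1000).
#' @param goal_mse Target mean squared error on the normalized scale
#'   (default 0.01).
#' @param learning_rate Step size for `"gdm"` (default 0.15).
#' @param min_gradient Stop when the gradient max-norm falls below this
#'   (default 1e-6).
#' @param method `"rprop"` (default) or `"gdm"`.
#' @param seed Integer seed used when training has to draw its own initial
#'   parameters.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 1000L, goal_mse = 0.01,
                         learning_rate = 0.15, min_gradient = 1e-6,
                         method = c("rprop", "gdm"), seed = 1L) {
  method <- match.arg(method)
  if (max_epochs < 1 || goal_mse <= 0 || learning_rate <= 0 || min_gradient <= 0) {
    abort("All training-config values must be positive.", class = "emdcast_invalid_input")
  }
  structure(list(max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
                 learning_rate = learning_rate, min_gradient = min_gradient,
                 method = method, seed = as.integer(seed)),
            class = "train_config")
}

flatten_params <- function(p) {
  c(t(p$input_hidden_weights), p$hidden_thresholds,
    p$hidden_output_weights, p$output_threshold)
}

unflatten_params <- function(v, n_input, n_hidden) {
  mlp_parameters(matrix(v[seq_len(n_input * n_hidden)], n_hidden, n_input, byrow = TRUE),
                 v[n_input * n_hidden + seq_len(n_hidden)],
                 v[n_input * n_hidden + n_hidden + seq_len(n_hidden)],
                 v[n_input * n_hidden + 2L * n_hidden + 1L])
}

#' Train a three-layer network on lag-embedded data
#'
#' Refines `params` against `(inputs, targets)` until the epoch MSE reaches
#' `goal_mse`, the gradient max-norm drops below `min_gradient`, or
#' `max_epochs` is hit. The parameters achieving the lowest epoch MSE seen
#' (including the starting point) are returned, so the final training MSE
#' never exceeds the initial one.
#'
#' @param params Starting `mlp_parameters` (e.g. the particle-swarm optimum).
#' @param inputs Matrix of lagged inputs on the normalized scale.
#' @param targets Numeric vector of normalized targets.
#' @param cfg A [train_config()].
#' @return A list with `params` (trained `mlp_parameters`), `history` (epoch
#'   MSE trace, first entry the starting MSE) and `epochs` run.
#' @export
mlp_train <- function(params, inputs, targets, cfg = train_config()) {
  if (!is.matrix(inputs) || nrow(inputs) != length(targets)) {
    abort("`inputs` must be a matrix with one row per target.",
          class = "emdcast_invalid_input")
  }
  ni <- params$n_input; nh <- params$n_hidden
  theta <- flatten_params(params)
  mse0 <- mlp_mse(params, inputs, targets)
  history <- mse0
  best <- theta; best_mse <- mse0
  if (mse0 <= cfg$goal_mse) {
    return(list(params = params, history = history, epochs = 0L))
  }
  step <- rep(0.07, length(theta))
  g_prev <- rep(0, length(theta))
  velocity <- rep(0, length(theta))
  epochs <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    epochs <- ep
    p <- unflatten_params(theta, ni, nh)
    g <- flatten_params(mlp_gradient(p, inputs, targets))
    if (!all(is.finite(g))) {
      abort(sprintf("Non-finite gradient at epoch %d.", ep),
            class = "emdcast_numeric_failure")
    }
    if (max(abs(g)) <= cfg$min_gradient) break
    if (cfg$method == "rprop") {
      agree <- sign(g) * sign(g_prev)
      step[agree > 0] <- pmin(step[agree > 0] * 1.2, 50)
      step[agree < 0] <- pmax(step[agree < 0] * 0.5, 1e-6)
      theta <- theta - sign(g) * step
      g_prev <- g
    } else {
      velocity <- 0.9 * velocity - cfg$learning_rate * g
      theta <- theta + velocity
    }
    m <- mlp_mse(unflatten_params(theta, ni, nh), inputs, targets)
    if (!is.finite(m)) {
      abort(sprintf("Non-finite training loss at epoch %d.", ep),
            class = "emdcast_numeric_failure")
    }
    history <- c(history, m)
    if (m < best_mse) { best_mse <- m; best <- theta }
    if (m <= cfg$goal_mse) break
  }
  list(params = unflatten_params(best, ni, nh), history = history, epochs = epochs)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
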