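# Shared fixtures, all generated in code.

sine_series <- function(n = 512, period = 64, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * (seq_len(n) - 1) / period + phase)
}

sine_plus_trend <- function() {
  t <- 0:127
  list(t = t, x = sin(2 * pi * t / 16) + 0.02 * t,
       sine = sin(2 * pi * t / 16), trend = 0.02 * t)
}

two_sine <- function() {
  t <- 0:127
  list(t = t, x = sin(2 * pi * t / 8) + sin(2 * pi * t / 64) + 5,
       fast = sin(2 * pi * t / 8), slow = sin(2 * pi * t / 64))
}

# small, fast settings for unit tests (defaults are the full study settings)
fast_pso <- function(seed = 1) pso_config(population = 15, iterations = 40, seed = seed)
fast_train <- function() train_config(max_epochs = 150)

# finite-difference MSE gradient: the independent oracle for the analytic one
numeric_gradient <- function(params, inputs, targets, eps = 1e-6) {
  theta <- mlp_encode(params)
  ni <- params$n_input; nh <- params$n_hidden
  vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    fu <- mean((mlp_forward(mlp_decode(up, ni, nh), inputs) - targets)^2)
    fd <- mean((mlp_forward(mlp_decode(dn, ni, nh), inputs) - targets)^2)
    (fu - fd) / (2 * eps)
  }, numeric(1))
}

random_mlp <- function(n_input, n_hidden, seed) mlp_init(n_input, n_hidden, seed = seed)
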