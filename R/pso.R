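#' Particle swarm configuration
#'
#' Defaults follow the standard setup for optimizing this network family:
#' population 40, 200 iterations, velocity clamped to \[-1, 1\], minimum
#' fitness 1e-30 as an early-stop, inertia decreasing linearly 0.9 to 0.3 and
#' time-varying acceleration coefficients with the cognitive factor falling
#' 2.5 to 0.5 while the social factor rises 0.5 to 2.5.
#'
#' @param population Number of particles (>= 2; default 40).
#' @param iterations Maximum iterations `t_max` (default 200).
#' @param inertia_start,inertia_end Inertia weight schedule endpoints
#'   (defaults 0.9, 0.3).
#' @param c1_start,c1_end Cognitive learning-factor endpoints (2.5 to 0.5).
#' @param c2_start,c2_end Social learning-factor endpoints (0.5 to 2.5).
#' @param v_max,v_min Velocity clamp (defaults 1, -1). Positions are not
#'   bounded.
#' @param min_fitness Early-stop fitness threshold (default 1e-30).
#' @param seed Integer seed driving initialization and the per-dimension
#'   uniforms.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(population = 40L, iterations = 200L,
                       inertia_start = 0.9, inertia_end = 0.3,
                       c1_start = 2.5, c1_end = 0.5,
                       c2_start = 0.5, c2_end = 2.5,
                       v_max = 1, v_min = -1,
                       min_fitness = 1e-30, seed = 1L) {
  if (population < 2) abort("`population` must be >= 2.", class = "emdcast_invalid_input")
  if (iterations < 1) abort("`iterations` must be >= 1.", class = "emdcast_invalid_input")
  if (inertia_start < inertia_end) {
    abort("`inertia_start` must be >= `inertia_end`.", class = "emdcast_invalid_input")
  }
  if (v_max <= v_min) abort("`v_max` must exceed `v_min`.", class = "emdcast_invalid_input")
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 c1_start = c1_start, c1_end = c1_end,
                 c2_start = c2_start, c2_end = c2_end,
                 v_max = v_max, v_min = v_min,
                 min_fitness = min_fitness, seed = as.integer(seed)),
            class = "pso_config")
}

#' Dimension of the particle encoding a three-layer network
#'
#' Every weight and threshold becomes one coordinate:
#' `n_h + n_0 + n_i * n_h + n_h * n_0`. The default 3-14-1 architecture gives
#' 71 dimensions.
#'
#' @param n_input,n_hidden,n_output Layer sizes (all >= 1).
#' @return Integer particle dimension.
#' @examples
#' particle_dimension(3, 14, 1)  # 71
#' @export
particle_dimension <- function(n_input, n_hidden, n_output = 1L) {
  if (n_input < 1 || n_hidden < 1 || n_output < 1) {
    abort("Layer sizes must be >= 1.", class = "emdcast_invalid_input")
  }
  as.integer(n_hidden + n_output + n_input * n_hidden + n_hidden * n_output)
}

#' Linearly decreasing inertia weight
#'
#' \eqn{\omega(t) = \omega_{start} - (\omega_{start} - \omega_{end}) \, t / t_{max}},
#' evaluated at the current iteration `t` in `0..t_max` so both endpoints are
#' attained.
#'
#' @param t Current iteration, `0 <= t <= cfg$iterations`.
#' @param cfg A [pso_config()].
#' @return The inertia weight at iteration `t`.
#' @export
inertia_weight <- function(t, cfg = pso_config()) {
  if (t < 0 || t > cfg$iterations) {
    abort("`t` must lie in [0, iterations].", class = "emdcast_invalid_input")
  }
  cfg$inertia_start - (cfg$inertia_start - cfg$inertia_end) * t / cfg$iterations
}

#' Time-varying learning factors
#'
#' Linear schedules between the configured endpoints: with defaults the
#' cognitive factor c1 decreases 2.5 to 0.5 while the social factor c2
#' increases 0.5 to 2.5, shifting the swarm from self-exploration to
#' consensus-seeking.
#'
#' @inheritParams inertia_weight
#' @return A named list with `c1` and `c2`.
#' @export
learning_factors <- function(t, cfg = pso_config()) {
  if (t < 0 || t > cfg$iterations) {
    abort("`t` must lie in [0, iterations].", class = "emdcast_invalid_input")
  }
  list(c1 = cfg$c1_start + (cfg$c1_end - cfg$c1_start) * t / cfg$iterations,
       c2 = cfg$c2_start + (cfg$c2_end - cfg$c2_start) * t / cfg$iterations)
}

#' Encode network parameters as a particle position
#'
#' Fixed layout: input-to-hidden weights row-major (hidden unit by hidden
#' unit), hidden thresholds, hidden-to-output weights, output threshold.
#' [mlp_decode()] is the exact inverse.
#'
#' @param params An `mlp_parameters` object.
#' @return Numeric vector of length
#'   `particle_dimension(n_input, n_hidden, 1)`.
#' @export
mlp_encode <- function(params) flatten_params(params)

#' @rdname mlp_encode
#' @param position Numeric vector in the [mlp_encode()] layout.
#' @param n_input,n_hidden,n_output Layer sizes the position encodes.
#' @return For `mlp_decode()`: the reconstructed `mlp_parameters`.
#' @export
mlp_decode <- function(position, n_input, n_hidden, n_output = 1L) {
  want <- particle_dimension(n_input, n_hidden, n_output)
  if (length(position) != want) {
    abort(sprintf("Position length %d does not match particle dimension %d.",
                  length(position), want), class = "emdcast_invalid_input")
  }
  unflatten_params(position, n_input, n_hidden)
}

#' Network fitness of a particle position
#'
#' Mean squared error of the decoded network's one-step predictions against
#' the targets — the objective the swarm minimizes.
#'
#' @param position Particle position encoding the network.
#' @param inputs Matrix of lagged inputs (normalized scale).
#' @param targets Numeric vector of targets.
#' @param n_input,n_hidden Layer sizes.
#' @return Non-negative mean squared error.
#' @export
mlp_fitness <- function(position, inputs, targets, n_input = ncol(inputs),
                        n_hidden = 14L) {
  p <- mlp_decode(position, n_input, n_hidden)
  mean((mlp_forward(p, inputs) - targets)^2)
}

#' Initialize a swarm
#'
#' Positions uniform on \[-1, 1\] per dimension; velocities uniform on one
#' tenth of the velocity clamp. Consumes the current RNG stream (seed it via
#' [pso_optimize()] or `set.seed()`).
#'
#' @param objective Function: position vector -> finite fitness.
#' @param dimension Particle dimension (>= 1).
#' @param cfg A [pso_config()].
#' @return A `swarm_state` list: `positions`, `velocities`, `personal_bests`,
#'   `personal_best_fitness`, `global_best`, `global_best_fitness`,
#'   `iteration`.
#' @export
pso_init <- function(objective, dimension, cfg = pso_config()) {
  pop <- cfg$population
  X <- matrix(runif(pop * dimension, -1, 1), pop, dimension)
  V <- matrix(runif(pop * dimension, cfg$v_min, cfg$v_max) * 0.1, pop, dimension)
  f <- apply(X, 1, objective)
  if (!all(is.finite(f))) {
    abort("Objective returned a non-finite value during initialization.",
          class = "emdcast_numeric_failure")
  }
  g <- which.min(f)
  structure(list(positions = X, velocities = V,
                 personal_bests = X, personal_best_fitness = f,
                 global_best = X[g, ], global_best_fitness = f[g],
                 iteration = 0L),
            class = "swarm_state")
}

#' Velocity update rule
#'
#' The core swarm recurrence applied to one iteration's matrices:
#' \eqn{V' = \omega V + c_1 r_1 (P - X) + c_2 r_2 (P_g - X)}, then clamped to
#' `[v_min, v_max]`. Exposed separately so the rule can be exercised with
#' chosen `r1`, `r2`.
#'
#' @param velocities,positions,personal_bests Matrices (population x D).
#' @param global_best Numeric vector of length D.
#' @param w Inertia weight.
#' @param c1,c2 Learning factors.
#' @param r1,r2 Uniform draws, matrices conformable with `positions` (or
#'   scalars, recycled).
#' @param v_min,v_max Velocity clamp.
#' @return The clamped velocity matrix.
#' @export
pso_velocity_update <- function(velocities, positions, personal_bests,
                                global_best, w, c1, c2, r1, r2,
                                v_min = -1, v_max = 1) {
  V <- w * velocities + c1 * r1 * (personal_bests - positions) +
    c2 * r2 * sweep(-positions, 2, global_best, `+`)
  V[V > v_max] <- v_max
  V[V < v_min] <- v_min
  V
}

#' Advance the swarm by one iteration
#'
#' Velocity update
#' \eqn{V \leftarrow \omega V + c_1 r_1 (P_i - X) + c_2 r_2 (P_g - X)} with
#' fresh independent uniforms `r1`, `r2` drawn per particle *and* per
#' dimension, velocities clamped to `[v_min, v_max]`, then `X <- X + V` and
#' personal/global bests updated. The global best fitness never increases.
#'
#' @param state A `swarm_state` from [pso_init()] or a previous step.
#' @param cfg A [pso_config()].
#' @param objective Function: position vector -> finite fitness.
#' @return The updated `swarm_state` with `iteration` advanced by one.
#' @export
pso_step <- function(state, cfg, objective) {
  t <- state$iteration + 1L
  w <- inertia_weight(t, cfg)
  lf <- learning_factors(t, cfg)
  X <- state$positions; V <- state$velocities
  pop <- nrow(X); D <- ncol(X)
  r1 <- matrix(runif(pop * D), pop, D)
  r2 <- matrix(runif(pop * D), pop, D)
  V <- pso_velocity_update(V, X, state$personal_bests, state$global_best,
                           w, lf$c1, lf$c2, r1, r2, cfg$v_min, cfg$v_max)
  X <- X + V
  f <- apply(X, 1, objective)
  if (!all(is.finite(f))) {
    abort(sprintf("Objective returned a non-finite fitness at iteration %d.", t),
          class = "emdcast_numeric_failure")
  }
  improved <- f < state$personal_best_fitness
  P <- state$personal_bests
  P[improved, ] <- X[improved, ]
  pf <- ifelse(improved, f, state$personal_best_fitness)
  g <- which.min(pf)
  gb <- state$global_best; gf <- state$global_best_fitness
  if (pf[g] < gf) { gb <- P[g, ]; gf <- pf[g] }
  structure(list(positions = X, velocities = V,
                 personal_bests = P, personal_best_fitness = pf,
                 global_best = gb, global_best_fitness = gf,
                 iteration = t),
            class = "swarm_state")
}

#' Minimize an objective by particle swarm optimization
#'
#' Runs `cfg$iterations` steps (or stops early once the global best falls to
#' `cfg$min_fitness`), entirely determined by `cfg$seed`.
#'
#' @param objective Function: position vector -> finite fitness to minimize.
#' @param dimension Length of a position vector (>= 1).
#' @param cfg A [pso_config()].
#' @param trace_file Optional path; when given, the per-iteration best
#'   fitness is written there as a two-column CSV (`iteration,best_fitness`).
#' @return A list with `best_position`, `best_fitness` and `history` (one
#'   best-fitness entry per iteration run, non-increasing).
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(sphere, 5, pso_config(iterations = 50, seed = 1))
#' res$best_fitness
#' @export
pso_optimize <- function(objective, dimension, cfg = pso_config(),
                         trace_file = NULL) {
  if (dimension < 1) abort("`dimension` must be >= 1.", class = "emdcast_invalid_input")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  state <- pso_init(objective, dimension, cfg)
  history <- numeric(0)
  for (t in seq_len(cfg$iterations)) {
    state <- pso_step(state, cfg, objective)
    history <- c(history, state$global_best_fitness)
    if (state$global_best_fitness <= cfg$min_fitness) break
  }
  if (!is.null(trace_file)) {
    readr::write_csv(tibble::tibble(iteration = seq_along(history),
                                    best_fitness = history), trace_file)
  }
  list(best_position = state$global_best,
       best_fitness = state$global_best_fitness,
       history = history)
}
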