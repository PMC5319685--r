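test_that("particle dimension counts every weight and threshold", {
  expect_identical(particle_dimension(3, 14, 1), 71L)
  expect_identical(particle_dimension(1, 1, 1), 4L)
  expect_identical(particle_dimension(2, 3, 1), 13L)
  expect_error(particle_dimension(0, 1, 1), class = "emdcast_invalid_input")
})

test_that("inertia weight decreases linearly between its endpoints", {
  cfg <- pso_config()
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(cfg$iterations, cfg), 0.3)
  expect_equal(inertia_weight(cfg$iterations / 2, cfg), 0.6)
  w <- vapply(0:cfg$iterations, inertia_weight, numeric(1), cfg = cfg)
  expect_true(all(diff(w) <= 0))
  expect_error(inertia_weight(-1, cfg), class = "emdcast_invalid_input")
  expect_error(inertia_weight(cfg$iterations + 1, cfg), class = "emdcast_invalid_input")
})

test_that("learning factors swap from cognitive to social over the run", {
  cfg <- pso_config()
  expect_equal(learning_factors(0, cfg), list(c1 = 2.5, c2 = 0.5))
  expect_equal(learning_factors(cfg$iterations, cfg), list(c1 = 0.5, c2 = 2.5))
  for (t in seq(0, cfg$iterations, by = 25)) {
    lf <- learning_factors(t, cfg)
    expect_equal(lf$c1 + lf$c2, 3.0)
  }
})

test_that("degenerate schedules are constant", {
  cfg <- pso_config(inertia_start = 0.7, inertia_end = 0.7,
                    c1_start = 1.5, c1_end = 1.5, c2_start = 1.5, c2_end = 1.5)
  expect_equal(inertia_weight(0, cfg), inertia_weight(cfg$iterations, cfg))
  expect_equal(learning_factors(3, cfg), learning_factors(cfg$iterations, cfg))
})

test_that("encode/decode is a bijection on fixed shapes", {
  for (k in 1:100) {
    ni <- (k %% 4) + 1; nh <- (k %% 7) + 2
    p <- random_mlp(ni, nh, seed = k)
    v <- mlp_encode(p)
    expect_length(v, particle_dimension(ni, nh, 1))
    expect_identical(mlp_decode(v, ni, nh), p)
  }
  p <- random_mlp(3, 14, seed = 1)
  expect_length(mlp_encode(p), 71)
  expect_error(mlp_decode(rep(0, 70), 3, 14), class = "emdcast_invalid_input")
})

test_that("fitness is the decoded network's mean squared error", {
  # zero network predicts 0 everywhere
  z <- rep(0, particle_dimension(2, 3, 1))
  X <- matrix(runif(10 * 2), 10)
  expect_equal(mlp_fitness(z, X, rep(0, 10), 2, 3), 0)
  expect_equal(mlp_fitness(z, matrix(runif(4), 2), c(1, -1), 2, 3), 1)
  p <- random_mlp(2, 3, seed = 4)
  y <- mlp_forward(p, X)
  expect_equal(mlp_fitness(mlp_encode(p), X, y, 2, 3), 0)
})

test_that("velocity update follows the swarm recurrence with clamping", {
  # hand-evaluated 1-D case: V' = 0.5*0 + 2*0.5*(1-0) + 2*0.5*(1-0) = 2 -> clamp 1
  V <- pso_velocity_update(velocities = matrix(0), positions = matrix(0),
                           personal_bests = matrix(1), global_best = 1,
                           w = 0.5, c1 = 2, c2 = 2, r1 = 0.5, r2 = 0.5)
  expect_equal(V, matrix(1))
  # degenerate: w = 1, c1 = c2 = 0 leaves the velocity unchanged
  V0 <- matrix(c(0.2, -0.4), 1)
  expect_equal(pso_velocity_update(V0, matrix(c(1, 1), 1), matrix(c(2, 2), 1),
                                   c(0, 0), 1, 0, 0, 0.3, 0.7), V0)
})

test_that("a particle resting on both bests stays fixed", {
  obj <- function(v) sum(v^2)
  cfg <- pso_config(population = 2, iterations = 3, seed = 1)
  set.seed(1)
  st <- pso_init(obj, 2, cfg)
  # plant particle 1 exactly at the global best with zero velocity
  st$positions[1, ] <- st$global_best
  st$personal_bests[1, ] <- st$global_best
  st$personal_best_fitness[1] <- st$global_best_fitness
  st$velocities[1, ] <- 0
  st2 <- pso_step(st, cfg, obj)
  expect_equal(st2$positions[1, ], st$global_best)
})

test_that("optimizer is seeded-deterministic with a non-increasing history", {
  sphere <- function(v) sum(v^2)
  a <- pso_optimize(sphere, 5, fast_pso(seed = 2))
  b <- pso_optimize(sphere, 5, fast_pso(seed = 2))
  expect_identical(a, b)
  expect_true(all(diff(a$history) <= 0))
  expect_false(identical(a$history, pso_optimize(sphere, 5, fast_pso(seed = 3))$history))
})

test_that("a constant objective yields a constant history", {
  res <- pso_optimize(function(v) 1, 3, fast_pso(seed = 1))
  expect_true(all(res$history == 1))
})

test_that("velocities stay inside the clamp after every step", {
  obj <- function(v) sum((v - 2)^2)
  cfg <- pso_config(population = 10, iterations = 1, seed = 5)
  set.seed(5)
  st <- pso_init(obj, 4, cfg)
  for (k in 1:25) {
    st <- pso_step(st, cfg, obj)
    st$iteration <- 0L  # keep the schedule in-range while re-stepping
    expect_true(all(st$velocities <= cfg$v_max + 1e-12))
    expect_true(all(st$velocities >= cfg$v_min - 1e-12))
    expect_equal(st$global_best_fitness, min(st$personal_best_fitness))
  }
})

test_that("optimizer writes a best-fitness trace when asked", {
  tf <- withr::local_tempfile(fileext = ".csv")
  res <- pso_optimize(function(v) sum(v^2), 2, fast_pso(seed = 1), trace_file = tf)
  tr <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(tr$best_fitness, res$history)
})
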