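# Unit tests use reduced swarm/epoch settings for speed; the full study
# settings are exercised in test-acceptance.R.

test_that("date split respects calendar boundaries", {
  x <- simulate_outpatient_series(n_years = 9, seed = 1)  # Jan 2005 - Dec 2013
  sp <- split_by_date(x, "2012-11")
  expect_equal(nrow(sp$train), 95)
  expect_equal(nrow(sp$test), 13)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(x))
  expect_equal(format(sp$test$date[1], "%Y-%m"), "2012-12")

  sp2 <- split_by_date(x, "2013-11")
  expect_equal(nrow(sp2$test), 1)
  expect_error(split_by_date(x, "2013-12"), class = "emdcast_invalid_input")
  expect_error(split_by_date(x, "2004-01"), class = "emdcast_invalid_input")
})

test_that("each mode builds the promised number of component models", {
  x <- simulate_outpatient_series(seed = 1)
  f_bp <- hybrid_fit(x, "2012-11", mode = "bpann", tcfg = fast_train(), seed = 1)
  expect_length(f_bp$components, 1)
  expect_true(is.na(f_bp$components$series$pso_fitness))

  f_ps <- hybrid_fit(x, "2012-11", mode = "pso_bpann", tcfg = fast_train(),
                     pcfg = fast_pso(), seed = 1)
  expect_length(f_ps$components, 1)
  expect_false(is.na(f_ps$components$series$pso_fitness))

  f_emd <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                      pcfg = fast_pso(), seed = 1)
  expect_length(f_emd$components, n_imfs(f_emd$decomposition) + 1)
  expect_equal(glance(f_emd)$n_components, length(f_emd$components))
})

test_that("refined training never worsens the swarm optimum", {
  x <- simulate_outpatient_series(seed = 2)
  fit <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                    pcfg = fast_pso(), seed = 2)
  tb <- tidy(fit)
  expect_true(all(tb$final_mse <= tb$pso_fitness + 1e-12))
})

test_that("superposition identity: forecast equals the component column sum", {
  x <- simulate_outpatient_series(seed = 3)
  fit <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                    pcfg = fast_pso(), seed = 3)
  for (scheme in c("one_step_ahead", "recursive")) {
    rep <- predict(fit, scheme = scheme)
    pred <- rep$predictions
    comp_cols <- setdiff(names(pred), c("date", "observed", "predicted"))
    expect_gt(length(comp_cols), 1)
    expect_equal(pred$predicted,
                 rowSums(as.matrix(pred[comp_cols])), tolerance = 1e-9)
  }
})

test_that("the full pipeline is deterministic under a fixed master seed", {
  x <- simulate_outpatient_series(seed = 4)
  run <- function() {
    fit <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                      pcfg = fast_pso(), seed = 11)
    predict(fit)
  }
  expect_identical(run(), run())
})

test_that("train-scope decomposition sees no test-period value and forbids teacher forcing", {
  x <- simulate_outpatient_series(seed = 5)
  # altering the test span must not change a train-scope fit
  x2 <- x
  x2$value[96:108] <- x2$value[96:108] * 1.5
  f1 <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                   pcfg = fast_pso(), decomposition_scope = "train", seed = 6)
  f2 <- hybrid_fit(x2, "2012-11", mode = "emd_pso_bpann", tcfg = fast_train(),
                   pcfg = fast_pso(), decomposition_scope = "train", seed = 6)
  expect_identical(f1$components, f2$components)
  expect_identical(tibble::as_tibble(f1$decomposition), tibble::as_tibble(f2$decomposition))
  expect_error(predict(f1, scheme = "one_step_ahead"), class = "emdcast_invalid_input")
  expect_s3_class(predict(f1, scheme = "recursive"), "forecast_report")
})

test_that("reported metrics are recomputable from the stored predictions", {
  x <- simulate_outpatient_series(seed = 6)
  fit <- hybrid_fit(x, "2012-11", mode = "bpann", tcfg = fast_train(), seed = 1)
  rep <- predict(fit)
  expect_equal(rep$metrics, metric_bundle(rep$predictions$predicted,
                                          rep$predictions$observed))
})

test_that("method comparison emits one tidy row per method and seed", {
  x <- simulate_outpatient_series(seed = 7)
  tab1 <- compare_methods(x, "2012-11", methods = "bpann", seeds = 1,
                          tcfg = fast_train())
  expect_equal(nrow(tab1), 1)
  expect_named(tab1, c("method", "seed", "R", "RMSE", "MAPE", "SSE", "n"))

  tab <- compare_methods(x, "2012-11", methods = c("bpann", "pso_bpann"),
                         seeds = c(1, 2), tcfg = fast_train(), pcfg = fast_pso())
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n, rep(13, 4))
  expect_error(compare_methods(x, "2012-11", methods = character(0)),
               class = "emdcast_invalid_input")
})

test_that("a noise-free seasonal series is forecast within a few percent", {
  x <- simulate_outpatient_series(noise_sd = 0, seed = 1)
  fit <- hybrid_fit(x, "2012-11", mode = "emd_pso_bpann", seed = 1)
  rep <- predict(fit, scheme = "one_step_ahead")
  expect_lt(rep$metrics$MAPE, 0.05)
})
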