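test_that("cross-fitted predictions are out-of-sample and finite", {
  sc <- sim_scenario(n = 300, teh_kind = "none", seed = 23)
  trial <- generate_trial(sc)
  plan <- make_split_plan(trial$data, seed = 4)
  cf <- crossfit_predictions(trial$data, plan,
                             glm_spec = predictor_spec("glm", seed = 4),
                             ml_spec = predictor_spec(
                               "random_forest", list(num_trees = 30),
                               seed = 4))
  expect_length(cf$z_glm, 300)
  expect_true(all(is.finite(cf$z_glm)) && all(is.finite(cf$z_ml)))
  # each subject's z_glm equals the opposite half's refit prediction
  refit_a <- fit_predictor(predictor_spec("glm", seed = 4),
                           tehsplit:::subset_trial(trial$data, plan$half_a))
  lp_b <- tehsplit:::predict_linear_predictor(
    refit_a, trial$data$X[plan$half_b, , drop = FALSE],
    trial$data$treatment[plan$half_b])
  expect_equal(cf$z_glm[plan$half_b], lp_b, tolerance = 1e-12)
})

test_that("GLM cross-predictions track the true linear predictor", {
  sc <- sim_scenario(n = 2000, teh_kind = "none", treat_main = -0.5,
                     seed = 29)
  trial <- generate_trial(sc)
  plan <- make_split_plan(trial$data, seed = 8)
  cf <- crossfit_predictions(trial$data, plan,
                             glm_spec = predictor_spec("glm"),
                             ml_spec = predictor_spec("glm"))
  truth_lp <- sc$intercept +
    as.matrix(trial$data$X) %*% sc$baseline_coefs +
    trial$data$treatment * sc$treat_main
  expect_gte(cor(cf$z_glm, drop(truth_lp)), 0.9)
})

test_that("clipped log-odds hit the hand-computed bound", {
  register_predictor("always_zero_prob",
                     fit = function(X, treatment, outcome, hyper) NULL,
                     predict = function(state, X, treatment) {
                       rep(0, nrow(X))
                     })
  td <- toy_trial(n = 40)
  plan <- make_split_plan(td, seed = 1)
  cf <- crossfit_predictions(td, plan,
                             glm_spec = predictor_spec("glm"),
                             ml_spec = predictor_spec("always_zero_prob"),
                             epsilon = 0.001)
  expect_equal(unique(cf$z_ml), log(0.001 / 0.999), tolerance = 1e-12)
})

test_that("a collinear ML channel yields a zero LRT and p = 1", {
  z <- rnorm(100)
  y <- rbinom(100, 1, plogis(z))
  cf <- list(z_glm = z, z_ml = z)
  sf <- stacked_lrt(cf, y)
  expect_equal(sf$lrt_statistic, 0)
  expect_equal(sf$p_value, 1)
})

test_that("the stacked LRT is invariant to affine rescaling of predictors", {
  withr::with_seed(55, {
    z1 <- rnorm(400); z2 <- rnorm(400)
    y <- rbinom(400, 1, plogis(0.5 * z1 + 0.3 * z2))
  })
  base <- stacked_lrt(list(z_glm = z1, z_ml = z2), y)
  resc <- stacked_lrt(list(z_glm = 3 * z1 - 2, z_ml = -0.5 * z2 + 1), y)
  expect_equal(base$lrt_statistic, resc$lrt_statistic, tolerance = 1e-6)
  expect_gte(base$lrt_statistic, 0)
})

test_that("stacked LRT p values are calibrated under a null ML channel", {
  # z_ml pure noise given z_glm: p should be approximately uniform
  rej <- withr::with_seed(606, {
    mean(replicate(500, {
      z1 <- rnorm(150)
      y <- rbinom(150, 1, plogis(z1))
      stacked_lrt(list(z_glm = z1, z_ml = rnorm(150)), y)$p_value <= 0.05
    }))
  })
  expect_lte(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("an informative ML channel is detected with high power", {
  hits <- withr::with_seed(707, {
    mean(replicate(40, {
      x1 <- rnorm(1000); x2 <- rnorm(1000)
      signal <- 1.5 * x1 * x2          # invisible to a linear predictor
      y <- rbinom(1000, 1, plogis(signal))
      z_glm <- 0.1 * x1 + 0.1 * x2     # a weak linear stand-in
      stacked_lrt(list(z_glm = z_glm, z_ml = signal), y)$p_value < 0.001
    }))
  })
  expect_gte(hits, 0.95)
})

test_that("perfect separation falls back to the ridge fit with a flag", {
  # z_ml separates the outcome exactly
  y <- rep(c(0, 1), each = 30)
  z_ml <- ifelse(y == 1, 5, -5) + rnorm(60, sd = 0.01)
  z_glm <- rnorm(60)
  sf <- stacked_lrt(list(z_glm = z_glm, z_ml = z_ml), y)
  expect_true(sf$separation)
  expect_gte(sf$lrt_statistic, 0)
  expect_lte(sf$p_value, 0.001)   # the signal is real and overwhelming
})

test_that("the omnibus added-benefit test honours its contract", {
  sc <- sim_scenario(n = 200, teh_kind = "none", seed = 37)
  trial <- generate_trial(sc)
  res <- run_added_benefit_test(trial$data,
                                ml_spec = predictor_spec(
                                  "random_forest", list(num_trees = 25)),
                                K = 8, alpha = 0.05, master_seed = 41)
  expect_s3_class(res, "added_benefit_test")
  expect_length(res$aggregate$p_values, 8)
  expect_equal(res$p_aggregate, res$aggregate$trace[8])
  # same seed, same result
  res2 <- run_added_benefit_test(trial$data,
                                 ml_spec = predictor_spec(
                                   "random_forest", list(num_trees = 25)),
                                 K = 8, alpha = 0.05, master_seed = 41)
  expect_identical(res$aggregate$p_values, res2$aggregate$p_values)
  # K = 1 closed form
  res1 <- run_added_benefit_test(trial$data,
                                 ml_spec = predictor_spec("glm"),
                                 K = 1, alpha = 0.05, master_seed = 41)
  expect_equal(res1$p_aggregate,
               min(1, (1 - log(0.05)) * res1$aggregate$p_values[1]),
               tolerance = 1e-12)
})

test_that("intercept-free replication mode is available", {
  withr::with_seed(81, {
    z1 <- rnorm(200); z2 <- z1 + rnorm(200)
    y <- rbinom(200, 1, plogis(z1))
  })
  with_i <- stacked_lrt(list(z_glm = z1, z_ml = z2), y, intercept = TRUE)
  without_i <- stacked_lrt(list(z_glm = z1, z_ml = z2), y,
                           intercept = FALSE)
  expect_false(identical(with_i$lrt_statistic, without_i$lrt_statistic))
  expect_true(without_i$p_value >= 0 && without_i$p_value <= 1)
})
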