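test_that("a predictor that never predicts benefit gives a degenerate p = 1", {
  td <- toy_trial(n = 60)
  plan <- make_split_plan(td, seed = 1)
  register_predictor("null_glm_fixture",
                     fit = function(X, treatment, outcome, hyper) NULL,
                     predict = function(state, X, treatment) {
                       rep(0.5, nrow(X))
                     })
  sr <- split_pvalue(td, plan, predictor_spec("null_glm_fixture"))
  expect_s3_class(sr, "split_result")
  expect_equal(sr$n_s, 0L)
  expect_true(sr$degenerate)
  expect_equal(sr$p_value, 1)
})

test_that("the one-sided Fisher statistic matches exhaustive enumeration", {
  fisher_fun <- get("fisher_one_sided", envir = tehsplit:::.stat_registry)
  # the 1/20 vs 8/20 subgroup table
  y_exp <- c(rep(1, 1), rep(0, 19))
  y_soc <- c(rep(1, 8), rep(0, 12))
  expect_equal(fisher_fun(y_exp, y_soc),
               fisher_enum_oracle(1, 19, 8, 12), tolerance = 1e-12)
  # random 2x2 tables
  withr::with_seed(77, {
    for (i in 1:20) {
      n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
      a <- sample(0:n1, 1); c_ <- sample(0:n0, 1)
      p_pkg <- fisher_fun(c(rep(1, a), rep(0, n1 - a)),
                          c(rep(1, c_), rep(0, n0 - c_)))
      p_orc <- fisher_enum_oracle(a, n1 - a, c_, n0 - c_)
      expect_equal(p_pkg, p_orc, tolerance = 1e-12)
    }
  })
})

test_that("every subject is scored out-of-sample exactly once", {
  sc <- sim_scenario(n = 200, teh_kind = "crossover", seed = 5)
  trial <- generate_trial(sc)
  plan <- make_split_plan(trial$data, seed = 9)
  sr <- split_pvalue(trial$data, plan, predictor_spec("glm", seed = 9))
  expect_true(all(is.finite(sr$ite)))
  # rescoring each half with a model refitted on the opposite half alone
  # reproduces the stored ITEs: proof the stored score never saw its subject
  for (side in 1:2) {
    train_idx <- if (side == 1) plan$half_a else plan$half_b
    test_idx <- if (side == 1) plan$half_b else plan$half_a
    refit <- fit_predictor(predictor_spec("glm", seed = 9),
                           tehsplit:::subset_trial(trial$data, train_idx))
    ite_ref <- estimate_ite(refit, trial$data$X[test_idx, , drop = FALSE])
    expect_equal(sr$ite[test_idx], as.numeric(ite_ref), tolerance = 1e-12)
  }
  # subgroup bookkeeping
  expect_equal(sr$n_s, sum(sr$ite < 0))
  expect_equal(sum(sr$arm_counts), sr$n_s)
})

test_that("degenerate training halves are flagged, not fatal", {
  # outcome almost constant: after splitting, a half can lose all events
  X <- data.frame(x = rnorm(24))
  td <- trial_data(X, treatment = rep(0:1, 12),
                   outcome = c(1, rep(0, 23)))
  plan <- make_split_plan(td, seed = 2)
  expect_warning(sr <- split_pvalue(td, plan, predictor_spec("glm")),
                 "degenerate training half")
  expect_true(sr$degenerate)
  expect_equal(sr$p_value, 1)
})

test_that("the omnibus crossover test honours its aggregate contract", {
  sc <- sim_scenario(n = 200, teh_kind = "crossover", seed = 17)
  trial <- generate_trial(sc)
  res <- run_crossover_test(trial$data, predictor = predictor_spec("glm"),
                            K = 12, alpha = 0.05, master_seed = 21)
  expect_s3_class(res, "crossover_test")
  expect_length(res$aggregate$p_values, 12)
  expect_gte(res$p_aggregate, 0)
  expect_lte(res$p_aggregate, 1)
  expect_equal(res$p_aggregate, res$aggregate$trace[12])
  expect_equal(res$prevalence_estimate,
               mean(vapply(res$splits, `[[`, numeric(1), "n_s") / 200))
  # reproducibility from the master seed alone
  res2 <- run_crossover_test(trial$data, predictor = predictor_spec("glm"),
                             K = 12, alpha = 0.05, master_seed = 21)
  expect_identical(res$aggregate$p_values, res2$aggregate$p_values)

  # K = 1 adaptive closed form
  res1 <- run_crossover_test(trial$data, predictor = predictor_spec("glm"),
                             K = 1, alpha = 0.05, master_seed = 21)
  expect_equal(res1$p_aggregate,
               min(1, (1 - log(0.05)) * res1$aggregate$p_values[1]),
               tolerance = 1e-12)
})

test_that("split p values are superuniform when outcomes carry no signal", {
  # permuting Y within arms breaks any covariate-effect link; the resulting
  # p values should be stochastically >= uniform (degenerate p = 1 splits
  # only add conservatism)
  sc <- sim_scenario(n = 150, teh_kind = "crossover", seed = 3)
  trial <- generate_trial(sc)
  y <- trial$data$outcome
  perm <- withr::with_seed(404, {
    for (arm in 0:1) {
      idx <- which(trial$data$treatment == arm)
      y[idx] <- sample(y[idx])
    }
    y
  })
  td <- trial_data(trial$data$X, trial$data$treatment, perm)
  ps <- vapply(1:400, function(s) {
    plan <- make_split_plan(td, seed = s)
    split_pvalue(td, plan, predictor_spec("glm", seed = s))$p_value
  }, numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(ps, "punif", alternative = "greater"))
  # alternative "greater" tests ECDF above uniform, i.e. anti-conservatism
  expect_gt(ks$p.value, 0.01)
  expect_gte(mean(ps), 0.45)
})

test_that("a strong crossover signal with an oracle predictor is detected", {
  sc <- sim_scenario(n = 2000, teh_kind = "crossover", seed = 13)
  trial <- generate_trial(sc)
  osp <- oracle_predictor(sc, name = "oracle_strong")
  ps <- vapply(1:25, function(s) {
    plan <- make_split_plan(trial$data, seed = s)
    split_pvalue(trial$data, plan, osp)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.9)
})
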