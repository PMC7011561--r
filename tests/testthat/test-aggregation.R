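test_that("quantile_scaled matches hand-evaluated cases", {
  expect_equal(quantile_scaled(0.4, gamma = 0.5), 0.8)
  expect_equal(quantile_scaled(c(1, 1, 1), gamma = 0.3), 1)
  # median of {0.02, 0.04, 0.06}
  expect_equal(quantile_scaled(c(0.01, 0.02, 0.03), gamma = 0.5), 0.04)
  expect_error(quantile_scaled(numeric(0), 0.5), "empty")
  expect_error(quantile_scaled(c(0.2, 1.2), 0.5), "\\[0, 1\\]")
  expect_error(quantile_scaled(0.5, gamma = 1), "gamma")
})

test_that("fixed-gamma aggregation at 0.5 is the twice-the-median rule", {
  expect_equal(aggregate_fixed_gamma(c(0.01, 0.02, 0.03), 0.5)$p_aggregate,
               0.04)
  expect_equal(aggregate_fixed_gamma(rep(1, 7), 0.5)$p_aggregate, 1)
  expect_equal(aggregate_fixed_gamma(rep(0.001, 10), 0.5)$p_aggregate,
               0.002)
  # closed form against an independent median computation, many random sets
  for (s in 1:1000) {
    p <- random_pvalue_set(K = sample(c(1, 2, 3, 10, 101), 1), seed = s)
    got <- aggregate_fixed_gamma(p, 0.5, trace = FALSE)$p_aggregate
    # type-1 median of an even-length set is the lower of the two middle
    # order statistics; for odd length it is the middle one
    med <- sort(2 * p)[ceiling(length(p) / 2)]
    expect_identical(got, min(1, med))
  }
})

test_that("adaptive aggregation has the constant-set closed form", {
  # constant sets: Q_gamma = p / gamma, minimised at gamma = 1
  expect_equal(aggregate_adaptive(rep(0.001, 100), alpha = 0.05)$p_aggregate,
               (1 - log(0.05)) * 0.001, tolerance = 1e-9)
  expect_equal(aggregate_adaptive(rep(1, 5), alpha = 0.05)$p_aggregate, 1)
  for (p0 in c(0.0004, 0.01, 0.2)) {
    for (K in c(1, 7, 50)) {
      expect_equal(aggregate_adaptive(rep(p0, K), 0.05)$p_aggregate,
                   min(1, (1 - log(0.05)) * p0), tolerance = 1e-9)
    }
  }
})

test_that("aggregation results satisfy their structural contract", {
  p <- random_pvalue_set(40, seed = 9)
  for (res in list(aggregate_adaptive(p, 0.05),
                   aggregate_fixed_gamma(p, 0.5))) {
    expect_s3_class(res, "aggregate_result")
    expect_true(res$p_aggregate >= 0 && res$p_aggregate <= 1)
    expect_length(res$trace, 40)
    expect_equal(res$trace[40], res$p_aggregate)
    expect_true(all(res$trace >= 0 & res$trace <= 1))
  }
})

test_that("both rules are monotone and permutation invariant", {
  for (s in 1:50) {
    p <- random_pvalue_set(K = sample(2:30, 1), seed = 100 + s)
    agg_a <- aggregate_adaptive(p, 0.05, trace = FALSE)$p_aggregate
    agg_f <- aggregate_fixed_gamma(p, 0.5, trace = FALSE)$p_aggregate
    # permutation invariance
    q <- withr::with_seed(s, sample(p))
    expect_equal(aggregate_adaptive(q, 0.05, trace = FALSE)$p_aggregate,
                 agg_a)
    expect_equal(aggregate_fixed_gamma(q, 0.5, trace = FALSE)$p_aggregate,
                 agg_f)
    # raising one p value never lowers the aggregate
    i <- withr::with_seed(s, sample(length(p), 1))
    p2 <- p
    p2[i] <- min(1, p[i] + withr::with_seed(s + 1, runif(1, 0, 1 - p[i])))
    expect_gte(aggregate_adaptive(p2, 0.05, trace = FALSE)$p_aggregate,
               agg_a)
    expect_gte(aggregate_fixed_gamma(p2, 0.5, trace = FALSE)$p_aggregate,
               agg_f)
  }
})

test_that("adaptive aggregation controls the level on iid uniform p values", {
  # simulation oracle for the validity guarantee, desk scale
  n_sets <- 300
  K <- 400
  rej <- withr::with_seed(2024, {
    sum(replicate(n_sets, {
      aggregate_adaptive(runif(K), 0.05, trace = FALSE)$p_aggregate <= 0.05
    }))
  })
  expect_lte(rej / n_sets, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sets))
})

test_that("boundary curve matches its closed form and the adaptive rule", {
  bc <- boundary_curve(0.05, grid = 11)
  expect_equal(bc$y[1], 0.05)
  expect_equal(bc$y[11], 1)
  expect_equal(bc$x[11], 0.05 / (1 - log(0.05)), tolerance = 1e-12)
  # straight segment: x / y constant = alpha / (1 - log alpha)
  expect_equal(bc$x / bc$y, rep(0.05 / (1 - log(0.05)), 11),
               tolerance = 1e-12)

  # ECDF-crossing criterion is exactly equivalent to adaptive rejection
  for (s in 1:200) {
    alpha <- c(0.01, 0.05, 0.1)[1 + s %% 3]
    p <- random_pvalue_set(K = sample(c(1, 5, 20, 150), 1), seed = 5000 + s)
    reject <- aggregate_adaptive(p, alpha,
                                 trace = FALSE)$p_aggregate <= alpha
    expect_identical(ecdf_crosses_boundary(p, alpha), reject)
  }

  # p values all at alpha^2 / (2 (1 - log alpha)) sit below the boundary at
  # gamma = alpha/2 < alpha... at gamma = alpha they already reject
  alpha <- 0.05
  p_on <- rep(alpha^2 / (2 * (1 - log(alpha))), 50)
  expect_true(ecdf_crosses_boundary(p_on, alpha))
  expect_lte(aggregate_adaptive(p_on, alpha, trace = FALSE)$p_aggregate,
             alpha)
})

test_that("degenerate p-value sets hit the caps", {
  expect_equal(aggregate_adaptive(rep(1, 20), 0.05)$p_aggregate, 1)
  expect_equal(aggregate_fixed_gamma(rep(1, 20), 0.5)$p_aggregate, 1)
  # singleton under the adaptive rule: min(1, (1 - log alpha) p_1)
  for (p1 in c(0.001, 0.3, 0.9)) {
    expect_equal(aggregate_adaptive(p1, 0.05)$p_aggregate,
                 min(1, (1 - log(0.05)) * p1), tolerance = 1e-12)
  }
})
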