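# Shared fixtures and independent oracles for the test suite.
# Everything is built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A tiny deterministic two-arm trial with alternating treatment.
toy_trial <- function(n = 40, d = 2, seed = 42) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * d), n, d,
                              dimnames = list(NULL, paste0("x", 1:d))))
    trt <- rep(c(0L, 1L), length.out = n)
    y <- rbinom(n, 1, plogis(-0.5 + X[[1]] - 0.5 * trt))
  })
  trial_data(X, treatment = trt, outcome = y)
}

# Write a small CSV trial file with labelled treatments; returns the path.
write_toy_csv <- function(path = tempfile(fileext = ".csv"),
                          drug = c("A", "B", "A", "B", "A", "B"),
                          died = c(0, 1, 0, 0, 1, 1),
                          age = c(30, 40, 50, 60, 70, 80)) {
  utils::write.csv(data.frame(id = seq_along(drug), drug = drug,
                              died = died, age = age),
                   path, row.names = FALSE, quote = FALSE)
  path
}

toy_schema <- function() {
  column_schema(outcome = "died", treatment = "drug", covariates = "age",
                soc_label = "A", id = "id")
}

# Independent oracle: logistic regression by hand-coded Newton-Raphson on
# the design matrix [1, X, T]. Deliberately shares no code with the
# package's GLM adapter.
newton_logistic <- function(X, trt, y, max_iter = 50, tol = 1e-12) {
  M <- cbind(1, as.matrix(X), trt)
  beta <- rep(0, ncol(M))
  for (i in seq_len(max_iter)) {
    eta <- drop(M %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(M) %*% (M * W), t(M) %*% (y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, linear_predictor = drop(M %*% beta))
}

# Independent oracle: one-sided Fisher p value by exhaustive hypergeometric
# enumeration over all tables with the observed margins. Sums the exact
# conditional probabilities of all tables with at most the observed number
# of events in the experimental arm ("less" direction).
fisher_enum_oracle <- function(a, b, c, d) {
  # a = events among experimental, b = non-events among experimental,
  # c = events among soc, d = non-events among soc
  m1 <- a + b           # experimental receivers
  k <- a + c            # total events
  n <- a + b + c + d
  support <- max(0, k - (n - m1)):min(m1, k)
  logp <- lchoose(m1, support) + lchoose(n - m1, k - support) - lchoose(n, k)
  sum(exp(logp[support <= a]))
}

# Random p-value sets with a mix of distributions, for property tests.
random_pvalue_set <- function(K, seed) {
  withr::with_seed(seed, {
    mode <- sample(3, 1)
    switch(mode,
           runif(K),
           rbeta(K, 0.3, 1),            # small-p heavy
           pmin(1, runif(K) * 1.5))     # mass at 1
  })
}
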