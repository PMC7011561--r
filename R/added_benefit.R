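#' Cross-fitted out-of-sample predictions from the baseline GLM and the ML
#' model
#'
#' For one arm-balanced split, fits the baseline GLM and the ML model to
#' each half separately (both models share the same partition) and records,
#' for every subject, the out-of-sample predictions produced by the models
#' trained on the *opposite* half:
#' \itemize{
#'   \item `z_glm`: the GLM linear predictor
#'     \eqn{\hat Z^{GLM}_i = X_i\hat\beta + T_i\hat\alpha_{treat}};
#'   \item `z_ml`: the ML log-odds
#'     \eqn{\hat Z^{ML}_i = \log(\hat P_i / (1-\hat P_i))}, with
#'     \eqn{\hat P_i} clipped into \eqn{[\epsilon, 1-\epsilon]} first.
#' }
#' Predictions use each subject's *actual* randomised treatment — this is a
#' risk-prediction stack, not a counterfactual contrast.
#'
#' @param data a `trial_data` object.
#' @param plan a [make_split_plan()] partition.
#' @param glm_spec [predictor_spec()] for the baseline model (must expose a
#'   linear predictor; the built-in `"glm"` does).
#' @param ml_spec [predictor_spec()] for the ML model.
#' @param epsilon probability clamp before the log-odds transform.
#' @return An object of class `crossfit_predictions`: list with numeric
#'   vectors `z_glm`, `z_ml` (length n, finite) and `split_index`.
#' @export
crossfit_predictions <- function(data, plan, glm_spec, ml_spec,
                                 epsilon = 0.001) {
  validate_trial_data(data)
  stopifnot(inherits(plan, "split_plan"))
  z_glm <- rep(NA_real_, data$n)
  z_ml <- rep(NA_real_, data$n)
  scored_by <- rep(NA_integer_, data$n)
  for (side in 1:2) {
    train_idx <- if (side == 1L) plan$half_a else plan$half_b
    test_idx <- if (side == 1L) plan$half_b else plan$half_a
    train <- subset_trial(data, train_idx)
    if (length(unique(train$treatment)) < 2L ||
        length(unique(train$outcome)) < 2L) {
      stop("degenerate training half (single arm or constant outcome)")
    }
    glm_fit <- fit_predictor(glm_spec, train)
    ml_fit <- fit_predictor(ml_spec, train)
    Xtest <- data$X[test_idx, , drop = FALSE]
    Ttest <- data$treatment[test_idx]
    z_glm[test_idx] <- predict_linear_predictor(glm_fit, Xtest, Ttest)
    p_ml <- predict_event_probability(ml_fit, Xtest, Ttest)
    z_ml[test_idx] <- stats::qlogis(clip_probability(p_ml, epsilon))
    scored_by[test_idx] <- side
  }
  stopifnot(!anyNA(scored_by), all(is.finite(z_glm)), all(is.finite(z_ml)),
            all(scored_by[plan$half_a] == 2L),
            all(scored_by[plan$half_b] == 1L))
  structure(list(z_glm = z_glm, z_ml = z_ml, split_index = NA_integer_),
            class = "crossfit_predictions")
}

#' Stacked logistic likelihood-ratio test of the ML model's added benefit
#'
#' Fits the stacked logistic model
#' \deqn{\mathrm{logit}\,\Pr(Y_i=1) = \theta_0 + \hat Z^{GLM}_i \theta_{GLM}
#'   + \hat Z^{ML}_i \theta_{ML}}
#' on the full data and compares it with the nested model with
#' \eqn{\theta_{ML} = 0} by the deviance (likelihood-ratio) test on 1 degree
#' of freedom — the standard analysis-of-deviance comparison for nested
#' GLMs. A small p value says the ML predictions carry information about the
#' outcome beyond the baseline GLM's.
#'
#' An intercept \eqn{\theta_0} is included by default: out-of-sample
#' predictors can be miscalibrated in level, and omitting the intercept can
#' manufacture spurious significance. Set `intercept = FALSE` for the
#' intercept-free variant.
#'
#' If the stacked fit separates perfectly (or fails to converge), both
#' nested models are refitted with the same small ridge penalty and the
#' penalised deviance difference is used, with `separation = TRUE` flagged.
#' If `z_ml` is exactly collinear with `z_glm` the statistic is 0 and p = 1.
#'
#' @param predictions a [crossfit_predictions()] object (or any list with
#'   finite `z_glm`, `z_ml`).
#' @param outcome binary outcome vector of the same length.
#' @param intercept include an intercept in both nested models?
#' @param ridge_lambda penalty used only by the separation fallback.
#' @return An object of class `stacked_fit`: list with `theta_glm`,
#'   `theta_ml`, `lrt_statistic`, `df` (= 1), `p_value`, `separation`.
#' @export
stacked_lrt <- function(predictions, outcome, intercept = TRUE,
                        ridge_lambda = 1e-3) {
  z_glm <- predictions$z_glm
  z_ml <- predictions$z_ml
  n <- length(outcome)
  stopifnot(length(z_glm) == n, length(z_ml) == n,
            all(is.finite(z_glm)), all(is.finite(z_ml)),
            all(outcome %in% c(0, 1)))

  # exact collinearity: the ML channel cannot add information
  if (isTRUE(all.equal(unname(z_ml), unname(z_glm), tolerance = 1e-12)) ||
      stats::sd(z_ml) == 0 ||
      (stats::sd(z_glm) > 0 && stats::sd(z_ml) > 0 &&
       abs(stats::cor(z_glm, z_ml)) > 1 - 1e-12)) {
    return(structure(list(theta_glm = NA_real_, theta_ml = 0,
                          lrt_statistic = 0, df = 1L, p_value = 1,
                          separation = FALSE),
                     class = "stacked_fit"))
  }

  fmla_full <- if (intercept) outcome ~ z_glm + z_ml else
    outcome ~ 0 + z_glm + z_ml
  fmla_null <- if (intercept) outcome ~ z_glm else outcome ~ 0 + z_glm
  df <- data.frame(outcome = outcome, z_glm = z_glm, z_ml = z_ml)

  separated <- FALSE
  handler <- function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      separated <<- TRUE
    invokeRestart("muffleWarning")
  }
  full <- withCallingHandlers(
    stats::glm(fmla_full, data = df, family = stats::binomial()),
    warning = handler)
  null <- withCallingHandlers(
    stats::glm(fmla_null, data = df, family = stats::binomial()),
    warning = handler)

  # glm can "converge" under complete separation with huge finite
  # coefficients and silently pinned fitted probabilities; treat those as
  # separation too
  pinned <- any(stats::fitted(full) < 1e-10 | stats::fitted(full) > 1 - 1e-10)
  if (separated || pinned || !full$converged || !null$converged) {
    Xf <- cbind(z_glm, z_ml)
    full_r <- ridge_logistic(Xf, outcome, lambda = ridge_lambda,
                             intercept = intercept)
    null_r <- ridge_logistic(Xf[, 1, drop = FALSE], outcome,
                             lambda = ridge_lambda, intercept = intercept)
    lrt <- max(0, null_r$deviance - full_r$deviance)
    return(structure(list(theta_glm = full_r$coef[["z_glm"]],
                          theta_ml = full_r$coef[["z_ml"]],
                          lrt_statistic = lrt, df = 1L,
                          p_value = stats::pchisq(lrt, df = 1,
                                                  lower.tail = FALSE),
                          separation = TRUE),
                     class = "stacked_fit"))
  }

  co <- stats::coef(full)
  lrt <- max(0, null$deviance - full$deviance)
  structure(list(theta_glm = unname(co["z_glm"]),
                 theta_ml = unname(co["z_ml"]),
                 lrt_statistic = lrt, df = 1L,
                 p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 separation = FALSE),
            class = "stacked_fit")
}

# Ridge-penalised logistic regression by Newton iterations; penalty on the
# slope coefficients only. Used solely as the perfect-separation fallback.
ridge_logistic <- function(X, y, lambda, intercept = TRUE,
                           max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  M <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  pen <- rep(lambda, ncol(M))
  if (intercept) pen[1] <- 0
  beta <- rep(0, ncol(M))
  for (it in seq_len(max_iter)) {
    eta <- drop(M %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(M, y - mu) - pen * beta
    H <- crossprod(M * w, M) + diag(pen, ncol(M))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(M %*% beta)
  dev <- -2 * sum(y * eta - log1p(exp(eta)))
  names(beta) <- colnames(M)
  list(coef = beta, deviance = dev, iterations = it)
}

#' Omnibus test of the added predictive benefit of an ML model
#'
#' Runs K arm-balanced random 50/50 splits; in each, cross-fits the baseline
#' GLM and the ML model ([crossfit_predictions()]), stacks their
#' out-of-sample predictions in a logistic model on the full data, and
#' records the 1-df likelihood-ratio p value for the ML coefficient
#' ([stacked_lrt()]). The K p values are aggregated exactly as in
#' [run_crossover_test()], with the same split seeds `master_seed + k`.
#' Under the null — the ML model adds nothing beyond the baseline GLM — the
#' rejection probability at level `alpha` is at most `alpha`.
#'
#' Degenerate splits (a training half with one arm or constant outcome) are
#' conservatively assigned p = 1 and flagged.
#'
#' @inheritParams run_crossover_test
#' @param glm_spec baseline [predictor_spec()] (default the built-in GLM on
#'   all covariates; restrict via the `covariates` hyperparameter to use a
#'   prespecified risk score).
#' @param ml_spec ML [predictor_spec()] (default a 500-tree random forest).
#' @param epsilon probability clamp before the log-odds transform.
#' @param intercept include an intercept in the stacked model (see
#'   [stacked_lrt()]).
#' @return An object of class `c("added_benefit_test", "teh_test")`; the
#'   `splits` element holds per-split lists with the `stacked_fit`, its
#'   `p_value` and a `degenerate` flag.
#' @export
run_added_benefit_test <- function(data,
                                   glm_spec = predictor_spec("glm"),
                                   ml_spec = predictor_spec("random_forest"),
                                   K = 1000, alpha = 0.05, gamma = NULL,
                                   epsilon = 0.001, intercept = TRUE,
                                   master_seed = 1L) {
  validate_trial_data(data)
  stopifnot(K >= 1)
  splits <- vector("list", K)
  for (k in seq_len(K)) {
    seed_k <- as.integer(master_seed) + k
    plan <- make_split_plan(data, seed = seed_k)
    gspec <- glm_spec; gspec$seed <- seed_k
    mspec <- ml_spec; mspec$seed <- seed_k
    sr <- tryCatch({
      cf <- crossfit_predictions(data, plan, gspec, mspec, epsilon = epsilon)
      cf$split_index <- k
      sf <- stacked_lrt(cf, data$outcome, intercept = intercept)
      list(split_index = k, plan = plan, stacked = sf,
           p_value = sf$p_value, n_s = NA_real_,
           degenerate = FALSE)
    }, error = function(e) {
      warning("split ", k, " degenerate (", conditionMessage(e),
              "); assigned p = 1")
      list(split_index = k, plan = plan, stacked = NULL, p_value = 1,
           n_s = NA_real_, degenerate = TRUE)
    })
    splits[[k]] <- sr
  }
  finalize_teh_test(data, splits, K, alpha, gamma, master_seed,
                    test = "added_benefit",
                    config = list(glm_predictor = glm_spec$name,
                                  ml_predictor = ml_spec$name,
                                  epsilon = epsilon, intercept = intercept))
}
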