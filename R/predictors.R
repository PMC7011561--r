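#' @importFrom stats glm binomial predict plogis qlogis pchisq pnorm rbinom
#'   rnorm fisher.test na.omit sd quantile wilcox.test
NULL

.predictor_registry <- new.env(parent = emptyenv())

#' Register an outcome-prediction learner under a name
#'
#' The pluggable contract for discovery models: a registered predictor is a
#' pair of functions
#' \describe{
#'   \item{fit}{`function(X, treatment, outcome, hyperparameters)` returning
#'     an opaque fitted state. Called inside a seeded RNG scope, so
#'     stochastic learners are reproducible for free.}
#'   \item{predict}{`function(state, X, treatment)` returning event
#'     probabilities `Pr(Y = 1)` in \[0,1\] for covariate rows `X` under the
#'     supplied (possibly counterfactual) treatment vector.}
#' }
#' Nothing else is assumed about the learner. Built-ins are `"glm"`
#' (logistic regression with linear main effects) and `"random_forest"`
#' (classification forest via the randomForest package).
#'
#' @param name identifier used in [predictor_spec()].
#' @param fit,predict the two contract functions.
#' @param linear_predictor optional `function(state, X, treatment)` returning
#'   the linear predictor on the log-odds scale (used by the stacking test
#'   for GLM-family learners).
#' @return `name`, invisibly.
#' @export
register_predictor <- function(name, fit, predict, linear_predictor = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict,
                    linear_predictor = linear_predictor),
         envir = .predictor_registry)
  invisible(name)
}

#' List the registered predictor names
#' @return Character vector.
#' @export
list_predictors <- function() sort(ls(.predictor_registry))

get_predictor <- function(name) {
  if (!exists(name, envir = .predictor_registry, inherits = FALSE)) {
    stop("unknown predictor '", name, "'; registered: ",
         paste(list_predictors(), collapse = ", "))
  }
  get(name, envir = .predictor_registry, inherits = FALSE)
}

#' Specify a predictor and its hyperparameters
#'
#' @param name a registered predictor name (see [register_predictor()]).
#' @param hyperparameters named list. For `"random_forest"`: `num_trees`
#'   (default 500), `mtry` (default `floor(sqrt(d))`), `min_node_size`
#'   (default 1) — the package defaults of classification forests. For
#'   `"glm"`: `covariates`, an optional character vector restricting the
#'   baseline model to a prespecified covariate list (default: all
#'   covariates as linear main effects, categoricals dummy-coded).
#' @param seed integer seed for stochastic learners.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(name, hyperparameters = list(), seed = 1L) {
  get_predictor(name)   # fail early on unknown names
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "predictor_spec")
}

#' Fit a predictor to (a subset of) a trial
#'
#' Fits the learner named in `spec` to the given data. The training data
#' must contain both treatment arms and both outcome values; a constant
#' outcome is a "degenerate training outcome" error (downstream, the split
#' machinery converts this into a conservative p = 1 split rather than
#' aborting a long run).
#'
#' @param spec a [predictor_spec()].
#' @param data a `trial_data` object (typically one half of a split).
#' @return An object of class `fitted_predictor`.
#' @export
fit_predictor <- function(spec, data) {
  stopifnot(inherits(spec, "predictor_spec"))
  validate_trial_data(data)
  if (length(unique(data$outcome)) < 2L) {
    stop("degenerate training outcome: outcome is constant in the training ",
         "data")
  }
  eng <- get_predictor(spec$name)
  state <- withr::with_seed(spec$seed,
    eng$fit(data$X, data$treatment, data$outcome, spec$hyperparameters))
  structure(list(spec = spec,
                 training_info = list(n = data$n,
                                      n_experimental = sum(data$treatment),
                                      n_soc = sum(data$treatment == 0L),
                                      covariates = names(data$X)),
                 state = state,
                 engine = eng),
            class = "fitted_predictor")
}

#' Predict event probabilities under a forced treatment
#'
#' Returns \eqn{\Pr(Y=1 \mid X, T=t)} for each covariate row, with the
#' treatment forced to `treatment` for all rows (counterfactual toggling);
#' `treatment` may also be a vector to score subjects under their actual
#' assignment.
#'
#' @param model a `fitted_predictor`.
#' @param X covariate data frame with the training schema.
#' @param treatment scalar 0/1 or vector of length `nrow(X)`.
#' @return Numeric vector of probabilities in \[0,1\].
#' @export
predict_event_probability <- function(model, X, treatment) {
  stopifnot(inherits(model, "fitted_predictor"))
  X <- check_schema(model, X)
  if (length(treatment) == 1L) treatment <- rep(treatment, nrow(X))
  stopifnot(length(treatment) == nrow(X), all(treatment %in% c(0, 1)))
  p <- model$engine$predict(model$state, X, as.integer(treatment))
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1))
  p
}

# the stacking test needs the GLM's linear predictor, not just probabilities
predict_linear_predictor <- function(model, X, treatment) {
  stopifnot(inherits(model, "fitted_predictor"))
  if (is.null(model$engine$linear_predictor)) {
    stop("predictor '", model$spec$name, "' does not expose a linear ",
         "predictor")
  }
  X <- check_schema(model, X)
  if (length(treatment) == 1L) treatment <- rep(treatment, nrow(X))
  model$engine$linear_predictor(model$state, X, as.integer(treatment))
}

check_schema <- function(model, X) {
  if (is.matrix(X)) X <- as.data.frame(X)
  miss <- setdiff(model$training_info$covariates, names(X))
  if (length(miss) > 0L) {
    stop("schema mismatch: prediction rows lack training covariate(s): ",
         paste(miss, collapse = ", "))
  }
  X[, model$training_info$covariates, drop = FALSE]
}

#' Individual treatment effects from a fitted predictor
#'
#' The individual treatment effect (ITE) of subject i is the difference in
#' predicted event probability under the two arms,
#' \deqn{\Delta_i = \Pr(Y=1 \mid X_i, T=1) - \Pr(Y=1 \mid X_i, T=0).}
#' Since outcome 1 is the adverse event, \eqn{\Delta_i < 0} means the
#' experimental arm is predicted beneficial for subject i. The predicted
#' optimal treatment is the experimental arm iff \eqn{\Delta_i < 0}; exact
#' ties go to the standard of care (never move a patient off standard of
#' care without predicted strict benefit).
#'
#' @inheritParams predict_event_probability
#' @return Numeric vector \eqn{\Delta_i} with attribute `optimal_treatment`
#'   (integer 0/1 per row).
#' @export
estimate_ite <- function(model, X) {
  p1 <- predict_event_probability(model, X, 1L)
  p0 <- predict_event_probability(model, X, 0L)
  ite <- p1 - p0
  attr(ite, "optimal_treatment") <- ifelse(ite < 0, 1L, 0L)
  ite
}

#' Clamp probabilities away from 0 and 1
#'
#' Ensemble learners can emit exact 0/1 probabilities, whose log-odds are
#' infinite; the stacking test therefore clips probabilities into
#' \eqn{[\epsilon, 1-\epsilon]} before the log-odds transform.
#'
#' @param p probabilities in \[0,1\].
#' @param epsilon clamp width in (0, 0.5), default 0.001.
#' @return Probabilities in \eqn{[\epsilon, 1-\epsilon]}.
#' @export
clip_probability <- function(p, epsilon = 0.001) {
  stopifnot(epsilon > 0, epsilon < 0.5, all(p >= 0), all(p <= 1))
  pmin(1 - epsilon, pmax(epsilon, p))
}

# ---------------------------------------------------------------------------
# built-in adapters

glm_fit_engine <- function(X, treatment, outcome, hyper) {
  covs <- hyper$covariates
  if (!is.null(covs)) {
    miss <- setdiff(covs, names(X))
    if (length(miss) > 0L) stop("glm covariates not in data: ",
                                paste(miss, collapse = ", "))
    X <- X[, covs, drop = FALSE]
  }
  df <- cbind(X, .treat = treatment, .y = outcome)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0   # rank-deficient columns contribute nothing
  list(fit = fit, covariates = names(X),
       intercept = unname(co["(Intercept)"]),
       alpha_treat = unname(co[".treat"]),
       beta = co[setdiff(names(co), c("(Intercept)", ".treat"))])
}

glm_newdata <- function(state, X, treatment) {
  cbind(X[, state$covariates, drop = FALSE], .treat = treatment)
}

register_predictor(
  "glm",
  fit = glm_fit_engine,
  predict = function(state, X, treatment) {
    unname(stats::predict(state$fit, newdata = glm_newdata(state, X, treatment),
                          type = "response"))
  },
  linear_predictor = function(state, X, treatment) {
    unname(stats::predict(state$fit, newdata = glm_newdata(state, X, treatment),
                          type = "link"))
  })

register_predictor(
  "random_forest",
  fit = function(X, treatment, outcome, hyper) {
    ntree <- hyper$num_trees %||% 500
    mtry <- hyper$mtry %||% max(1, floor(sqrt(ncol(X) + 1)))
    nodesize <- hyper$min_node_size %||% 1
    df <- cbind(X, .treat = treatment)
    randomForest::randomForest(x = df,
                               y = factor(outcome, levels = c(0, 1)),
                               ntree = ntree, mtry = mtry,
                               nodesize = nodesize)
  },
  predict = function(state, X, treatment) {
    nd <- cbind(X, .treat = treatment)
    unname(stats::predict(state, newdata = nd, type = "prob")[, "1"])
  })

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A logistic-model predictor with fixed, known coefficients
#'
#' Builds a `fitted_predictor` whose event probability is
#' \eqn{\mathrm{logit}^{-1}(b_0 + X\beta + T\,\alpha_{\mathrm{treat}})} with
#' the supplied coefficients — no fitting involved. Useful as a ground-truth
#' "oracle" discovery model in simulations and as a fixed reference in
#' tests.
#'
#' @param intercept scalar intercept \eqn{b_0}.
#' @param beta named numeric vector of covariate coefficients (names must
#'   match covariate columns; missing covariates contribute zero).
#' @param alpha_treat treatment coefficient (negative = experimental arm
#'   beneficial). Named to avoid a clash with the significance level alpha.
#' @param covariates character vector of the covariate schema.
#' @return A `fitted_predictor`.
#' @export
glm_predictor_from_coefficients <- function(intercept, beta, alpha_treat,
                                            covariates = names(beta)) {
  stopifnot(is.numeric(intercept), is.numeric(alpha_treat))
  eng <- list(
    fit = NULL,
    predict = function(state, X, treatment) {
      stats::plogis(linpred_fixed(state, X, treatment))
    },
    linear_predictor = function(state, X, treatment) {
      linpred_fixed(state, X, treatment)
    })
  state <- list(intercept = intercept, beta = beta,
                alpha_treat = alpha_treat)
  structure(list(spec = structure(list(name = "fixed_glm",
                                       hyperparameters = list(), seed = 0L),
                                  class = "predictor_spec"),
                 training_info = list(n = NA_integer_,
                                      n_experimental = NA_integer_,
                                      n_soc = NA_integer_,
                                      covariates = covariates),
                 state = state, engine = eng),
            class = "fitted_predictor")
}

linpred_fixed <- function(state, X, treatment) {
  lp <- rep(state$intercept, nrow(X)) + treatment * state$alpha_treat
  for (nm in names(state$beta)) {
    if (nm %in% names(X)) lp <- lp + state$beta[[nm]] * X[[nm]]
  }
  lp
}
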