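.stat_registry <- new.env(parent = emptyenv())

#' Register a two-sample test statistic for the held-out subgroup
#'
#' The contract: a function `function(y_experimental, y_soc)` receiving the
#' outcome vectors of the held-out subgroup members split by the treatment
#' they *actually received*, returning a one-sided p value in \[0,1\] where
#' small values are evidence that the experimental arm produced better
#' outcomes (fewer adverse events) within the subgroup. The direction is
#' fixed by construction — the subgroup is the set of subjects predicted to
#' benefit from switching off the standard of care.
#'
#' Built-ins: `"fisher_one_sided"` (default, exact for binary outcomes),
#' `"prop_z_one_sided"` (one-sided difference-in-proportions z test),
#' `"wilcoxon_one_sided"` (rank test, usable for ordinal/continuous
#' endpoints where higher is worse).
#'
#' @param name identifier used in [test_statistic_spec()].
#' @param fun the test function.
#' @return `name`, invisibly.
#' @export
register_test_statistic <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .stat_registry)
  invisible(name)
}

#' List registered test statistics
#' @return Character vector.
#' @export
list_test_statistics <- function() sort(ls(.stat_registry))

#' Choose the subgroup test statistic
#'
#' @param name a registered statistic name; see [register_test_statistic()].
#' @return An object of class `test_statistic_spec`. Its `direction` field
#'   records that evidence means better outcomes in the experimental arm
#'   within the predicted-to-benefit subgroup.
#' @export
test_statistic_spec <- function(name = "fisher_one_sided") {
  if (!exists(name, envir = .stat_registry, inherits = FALSE)) {
    stop("unknown test statistic '", name, "'; registered: ",
         paste(list_test_statistics(), collapse = ", "))
  }
  structure(list(name = name, direction = "experimental_benefit"),
            class = "test_statistic_spec")
}

register_test_statistic("fisher_one_sided", function(y_exp, y_soc) {
  tab <- rbind(c(sum(y_exp), length(y_exp) - sum(y_exp)),
               c(sum(y_soc), length(y_soc) - sum(y_soc)))
  # alternative "less": odds of an event lower in the experimental arm
  stats::fisher.test(tab, alternative = "less")$p.value
})

register_test_statistic("prop_z_one_sided", function(y_exp, y_soc) {
  n1 <- length(y_exp); n0 <- length(y_soc)
  pbar <- (sum(y_exp) + sum(y_soc)) / (n1 + n0)
  if (pbar <= 0 || pbar >= 1) return(1)
  z <- (mean(y_exp) - mean(y_soc)) /
    sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  stats::pnorm(z)
})

register_test_statistic("wilcoxon_one_sided", function(y_exp, y_soc) {
  suppressWarnings(
    stats::wilcox.test(y_exp, y_soc, alternative = "less")$p.value)
})

#' One split of the crossover (benefitting subgroup) test
#'
#' Implements one iteration of the cross-prediction procedure: the predictor
#' is fitted to half A and scores half B, and vice versa, so that every
#' subject's individual treatment effect is estimated exactly once and
#' always out-of-sample. Subjects whose predicted optimal treatment is the
#' experimental arm (strictly negative ITE) form the held-out subgroup of
#' size `n_s`. Within that subgroup, the outcomes of those who actually
#' received the experimental treatment are compared with those who actually
#' received the standard of care by the one-sided two-sample statistic.
#'
#' Degenerate splits — a training half with a single arm or constant
#' outcome, an empty subgroup, a subgroup confined to one received arm, or a
#' subgroup with no outcome variation — conservatively yield p = 1 and are
#' flagged rather than discarded (discarding would bias the aggregate
#' towards small p values).
#'
#' @param data a `trial_data` object.
#' @param plan a [make_split_plan()] partition of `data`.
#' @param predictor a [predictor_spec()].
#' @param stat a [test_statistic_spec()].
#' @return An object of class `split_result`: list with `split_index`
#'   (filled by the driver), `plan`, `subgroup_ids`, `n_s`, `arm_counts`
#'   (received arm x event 2x2 table), `p_value`, `degenerate`, `ite`
#'   (per-subject out-of-sample ITE, in subject order).
#' @export
split_pvalue <- function(data, plan, predictor,
                         stat = test_statistic_spec()) {
  validate_trial_data(data)
  stopifnot(inherits(plan, "split_plan"),
            inherits(predictor, "predictor_spec"),
            inherits(stat, "test_statistic_spec"))
  idx <- sort(c(plan$half_a, plan$half_b))
  if (!identical(idx, seq_len(data$n))) {
    stop("split plan does not partition the trial's subjects")
  }

  ite <- rep(NA_real_, data$n)
  scored_by <- rep(NA_integer_, data$n)
  for (side in 1:2) {
    train_idx <- if (side == 1L) plan$half_a else plan$half_b
    test_idx <- if (side == 1L) plan$half_b else plan$half_a
    train <- subset_trial(data, train_idx)
    if (length(unique(train$treatment)) < 2L ||
        length(unique(train$outcome)) < 2L) {
      warning("degenerate training half (single arm or constant outcome); ",
              "split recorded as degenerate with p = 1")
      return(degenerate_split(data, plan, reason = "degenerate_training"))
    }
    fit <- fit_predictor(predictor, train)
    ite[test_idx] <- estimate_ite(fit, data$X[test_idx, , drop = FALSE])
    scored_by[test_idx] <- side
  }
  # out-of-sample bookkeeping: every subject scored exactly once, by the
  # model trained on the opposite half
  stopifnot(!anyNA(scored_by),
            all(scored_by[plan$half_a] == 2L),
            all(scored_by[plan$half_b] == 1L))

  in_subgroup <- ite < 0
  subgroup_test(data, plan, ite, in_subgroup, stat)
}

subgroup_test <- function(data, plan, ite, in_subgroup, stat) {
  ids <- data$subject_id[in_subgroup]
  n_s <- sum(in_subgroup)
  y <- data$outcome[in_subgroup]
  tr <- data$treatment[in_subgroup]
  arm_counts <- matrix(
    c(sum(y[tr == 1L]), sum(tr == 1L) - sum(y[tr == 1L]),
      sum(y[tr == 0L]), sum(tr == 0L) - sum(y[tr == 0L])),
    nrow = 2, byrow = TRUE,
    dimnames = list(received = c("experimental", "standard_of_care"),
                    outcome = c("event", "no_event")))
  degenerate <- n_s == 0L || length(unique(tr)) < 2L ||
    length(unique(y)) < 2L
  p <- if (degenerate) 1 else {
    fun <- get(stat$name, envir = .stat_registry, inherits = FALSE)
    min(1, max(0, fun(y[tr == 1L], y[tr == 0L])))
  }
  structure(list(split_index = NA_integer_, plan = plan,
                 subgroup_ids = ids, n_s = n_s, arm_counts = arm_counts,
                 p_value = p, degenerate = degenerate, ite = ite),
            class = "split_result")
}

degenerate_split <- function(data, plan, reason) {
  structure(list(split_index = NA_integer_, plan = plan,
                 subgroup_ids = data$subject_id[0], n_s = 0L,
                 arm_counts = matrix(0L, 2, 2,
                                     dimnames = list(
                                       received = c("experimental",
                                                    "standard_of_care"),
                                       outcome = c("event", "no_event"))),
                 p_value = 1, degenerate = TRUE, reason = reason,
                 ite = rep(NA_real_, data$n)),
            class = "split_result")
}

#' Omnibus test for a benefitting subgroup (crossover heterogeneity)
#'
#' Runs K arm-balanced random 50/50 splits, computes one out-of-sample
#' subgroup p value per split with [split_pvalue()], and merges the K
#' dependent p values into a single valid aggregate p value — adaptively
#' over quantile levels by default, or with a prespecified fixed `gamma`.
#' The null hypothesis is "no subgroup benefits from switching off the
#' standard of care"; under it the aggregate p value is stochastically at
#' least uniform, so rejection at level `alpha` has type I error at most
#' `alpha`.
#'
#' Split k uses seed `master_seed + k` for both the partition draw and the
#' predictor fit, so the whole run is reproducible from `master_seed` alone.
#' The mean of `n_s / n` across splits estimates the prevalence of the
#' predicted-to-benefit subgroup in the study population.
#'
#' @param data a `trial_data` object.
#' @param predictor a [predictor_spec()]; default a 500-tree random forest.
#' @param stat a [test_statistic_spec()].
#' @param K number of random splits (1000 is ample; the stabilisation trace
#'   lets you check convergence, typically reached by ~200).
#' @param alpha significance level for the adaptive aggregation.
#' @param gamma optional fixed quantile level; if supplied, the fixed-gamma
#'   rule replaces the adaptive sweep.
#' @param master_seed integer master seed.
#' @return An object of class `c("crossover_test", "teh_test")`: list with
#'   `aggregate` (an `aggregate_result`), `splits` (list of `split_result`),
#'   `p_aggregate`, `prevalence_estimate`, `config`.
#' @examples
#' \donttest{
#' sc <- sim_scenario(n = 300, teh_kind = "crossover", seed = 1)
#' trial <- generate_trial(sc)
#' res <- run_crossover_test(trial$data,
#'                           predictor = predictor_spec("glm"),
#'                           K = 25, master_seed = 1)
#' res$p_aggregate
#' }
#' @export
run_crossover_test <- function(data,
                               predictor = predictor_spec("random_forest"),
                               stat = test_statistic_spec(),
                               K = 1000, alpha = 0.05, gamma = NULL,
                               master_seed = 1L) {
  validate_trial_data(data)
  stopifnot(K >= 1)
  splits <- vector("list", K)
  for (k in seq_len(K)) {
    seed_k <- as.integer(master_seed) + k
    plan <- make_split_plan(data, seed = seed_k)
    pred_k <- predictor
    pred_k$seed <- seed_k
    sr <- split_pvalue(data, plan, pred_k, stat)
    sr$split_index <- k
    splits[[k]] <- sr
  }
  finalize_teh_test(data, splits, K, alpha, gamma, master_seed,
                    test = "crossover",
                    config = list(predictor = predictor$name,
                                  hyperparameters = predictor$hyperparameters,
                                  statistic = stat$name))
}

finalize_teh_test <- function(data, splits, K, alpha, gamma, master_seed,
                              test, config) {
  p_values <- vapply(splits, `[[`, numeric(1), "p_value")
  degenerate <- vapply(splits, `[[`, logical(1), "degenerate")
  if (all(degenerate)) {
    warning("all ", K, " splits were degenerate; aggregate p = 1")
  }
  agg <- if (is.null(gamma)) {
    aggregate_adaptive(p_values, alpha = alpha)
  } else {
    aggregate_fixed_gamma(p_values, gamma = gamma)
  }
  n_s <- vapply(splits, `[[`, numeric(1), "n_s")
  structure(list(
    aggregate = agg,
    splits = splits,
    p_aggregate = agg$p_aggregate,
    prevalence_estimate = if (test == "crossover") mean(n_s / data$n) else NULL,
    config = c(list(test = test, K = K, alpha = alpha, gamma = gamma,
                    master_seed = as.integer(master_seed), n = data$n),
               config)),
    class = c(paste0(test, "_test"), "teh_test"))
}

#' @export
print.teh_test <- function(x, ...) {
  lab <- if (inherits(x, "crossover_test")) {
    "Crossover heterogeneity (benefitting subgroup) test"
  } else {
    "Added predictive benefit (stacking) test"
  }
  cat(lab, "\n")
  cat(sprintf("  K = %d random 50/50 splits, predictor: %s\n",
              x$config$K, x$config$predictor %||% x$config$ml_predictor))
  cat(sprintf("  aggregate p value: %.6g (%s rule)\n",
              x$p_aggregate, x$aggregate$method))
  if (!is.null(x$prevalence_estimate)) {
    cat(sprintf("  estimated subgroup prevalence (mean n_s/n): %.1f%%\n",
                100 * x$prevalence_estimate))
  }
  ndeg <- sum(vapply(x$splits, `[[`, logical(1), "degenerate"))
  if (ndeg > 0) cat(sprintf("  %d degenerate split(s) set to p = 1\n", ndeg))
  invisible(x)
}
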