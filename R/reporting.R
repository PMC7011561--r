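REPORT_SCHEMA_VERSION <- "1.0"

#' ECDF of per-split p values against the adaptive rejection boundary
#'
#' The visual significance read-out: the empirical CDF of the K per-split p
#' values (black step) together with the rejection boundary of the adaptive
#' aggregation rule at level `alpha` (red segment, see [boundary_curve()]).
#' The test rejects at level `alpha` exactly when the black line touches or
#' crosses above the red boundary.
#'
#' @param p_values per-split p values.
#' @param alpha significance level for the boundary.
#' @param xlim upper x-axis limit (default 1; a small value zooms into the
#'   decision region near the origin).
#' @return A ggplot object (deterministic given the inputs).
#' @export
plot_pvalue_ecdf <- function(p_values, alpha = 0.05, xlim = 1) {
  check_pvalues(p_values)
  df <- data.frame(p = p_values)
  bc <- boundary_curve(alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::stat_ecdf(geom = "step", colour = "black") +
    ggplot2::geom_line(data = bc,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red", linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, xlim), ylim = c(0, 1)) +
    ggplot2::labs(x = "per-split p value",
                  y = "empirical CDF",
                  title = sprintf(
                    "p-value ECDF vs rejection boundary (alpha = %g)",
                    alpha),
                  subtitle =
                    "rejection iff the ECDF touches/crosses above the red boundary") +
    ggplot2::theme_minimal()
}

#' Stabilisation traceplot of the aggregate p value
#'
#' Plots the running aggregate p value computed on the first k per-split p
#' values, for k = 1..K. A flat right-hand tail indicates that K was large
#' enough for the aggregate to have stabilised (typically by a few hundred
#' splits); a drifting trace calls for more splits.
#'
#' @param trace numeric vector of running aggregate p values (e.g. the
#'   `trace` field of an `aggregate_result`).
#' @param alpha reference significance level drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, alpha = 0.05) {
  stopifnot(length(trace) >= 1, all(trace >= 0), all(trace <= 1))
  df <- data.frame(k = seq_along(trace), p = trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::geom_hline(yintercept = alpha, colour = "red",
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of splits k",
                  y = "aggregate p value on first k splits",
                  title = "Stabilisation of the aggregate p value") +
    ggplot2::theme_minimal()
}

#' @export
plot.teh_test <- function(x, type = c("ecdf", "trace"), ...) {
  type <- match.arg(type)
  alpha <- x$config$alpha
  if (type == "ecdf") plot_pvalue_ecdf(x$aggregate$p_values, alpha = alpha)
  else plot_trace(x$aggregate$trace, alpha = alpha)
}

#' Write a versioned JSON report of a test run
#'
#' Serialises everything needed to audit and reproduce a run: a schema
#' version, the configuration echo (including the master seed and every
#' per-split seed), all per-split p values, subgroup sizes and degeneracy
#' flags, the aggregate p value, the prevalence estimate and the
#' stabilisation trace. Reloading the report and re-aggregating the stored
#' p values reproduces the stored aggregate exactly.
#'
#' @param result a `teh_test` object from [run_crossover_test()] or
#'   [run_added_benefit_test()].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "teh_test"))
  splits <- result$splits
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    test = result$config$test,
    config = result$config,
    master_seed = result$config$master_seed,
    split_seeds = result$config$master_seed + seq_len(result$config$K),
    p_values = result$aggregate$p_values,
    n_s = vapply(splits, `[[`, numeric(1), "n_s"),
    degenerate = vapply(splits, `[[`, logical(1), "degenerate"),
    aggregation = list(method = result$aggregate$method,
                       gamma = result$aggregate$gamma,
                       alpha = result$aggregate$alpha),
    p_aggregate = result$p_aggregate,
    prevalence_estimate = result$prevalence_estimate,
    trace = result$aggregate$trace)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report back
#' @param path path written by [write_report()].
#' @return The report as a validated list.
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_report(report)
  report
}

#' Validate a report against the schema
#'
#' Checks that the fields required for reproducibility are present — in
#' particular the master seed: a report that cannot be reproduced is
#' rejected.
#'
#' @param report a list as produced by [write_report()].
#' @return `report`, invisibly; errors on missing fields.
#' @export
validate_report <- function(report) {
  required <- c("schema_version", "test", "master_seed", "p_values",
                "aggregation", "p_aggregate")
  missing <- setdiff(required, names(report))
  missing <- c(missing,
               if ("master_seed" %in% names(report) &&
                   is.null(report$master_seed)) "master_seed")
  if (length(missing) > 0L) {
    stop("invalid report: missing required field(s): ",
         paste(unique(missing), collapse = ", "))
  }
  invisible(report)
}

#' Assemble a reproducible run configuration
#'
#' The configuration object doubles as the machine-readable analysis plan:
#' fixing it (together with the input data file) before looking at the data
#' pins down every choice the analysis will make — models, statistic, K,
#' alpha, seeds — so a run is reproducible from `(data, config)` alone.
#'
#' @param schema a [column_schema()].
#' @param predictor name of the discovery/ML predictor.
#' @param hyperparameters named list for the predictor.
#' @param glm_covariates optional prespecified covariate list for the
#'   baseline GLM of the added-benefit test.
#' @param statistic subgroup test statistic name.
#' @param K number of splits.
#' @param alpha significance level.
#' @param gamma optional fixed quantile level (NULL = adaptive).
#' @param epsilon probability clamp.
#' @param intercept intercept in the stacked model (set `FALSE` for the
#'   intercept-free replication mode).
#' @param master_seed master seed; split k uses `master_seed + k`.
#' @param delim input field delimiter.
#' @return An object of class `run_config`.
#' @export
run_config <- function(schema, predictor = "random_forest",
                       hyperparameters = list(), glm_covariates = NULL,
                       statistic = "fisher_one_sided",
                       K = 1000, alpha = 0.05, gamma = NULL,
                       epsilon = 0.001, intercept = TRUE,
                       master_seed = 1L, delim = ",") {
  stopifnot(inherits(schema, "column_schema"))
  structure(list(schema = schema, predictor = predictor,
                 hyperparameters = hyperparameters,
                 glm_covariates = glm_covariates, statistic = statistic,
                 K = K, alpha = alpha, gamma = gamma, epsilon = epsilon,
                 intercept = intercept,
                 master_seed = as.integer(master_seed), delim = delim),
            class = "run_config")
}

#' Read a run configuration from a YAML analysis-plan file
#'
#' Expected keys: `columns` (with `outcome`, `treatment`, `covariates`,
#' `soc_label`, optional `id`), and optionally `predictor`,
#' `hyperparameters`, `glm_covariates`, `statistic`, `k`, `alpha`, `gamma`,
#' `epsilon`, `intercept`, `seed`, `delim`.
#'
#' @param path path to the YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$columns)) stop("config error: missing 'columns' section")
  cols <- y$columns
  for (f in c("outcome", "treatment", "covariates", "soc_label")) {
    if (is.null(cols[[f]])) stop("config error: columns section lacks '",
                                 f, "'")
  }
  schema <- column_schema(outcome = cols$outcome,
                          treatment = cols$treatment,
                          covariates = unlist(cols$covariates),
                          soc_label = cols$soc_label, id = cols$id)
  run_config(schema,
             predictor = y$predictor %||% "random_forest",
             hyperparameters = y$hyperparameters %||% list(),
             glm_covariates = unlist(y$glm_covariates),
             statistic = y$statistic %||% "fisher_one_sided",
             K = y$k %||% 1000, alpha = y$alpha %||% 0.05,
             gamma = y$gamma, epsilon = y$epsilon %||% 0.001,
             intercept = y$intercept %||% TRUE,
             master_seed = y$seed %||% 1L, delim = y$delim %||% ",")
}

#' @importFrom ggplot2 .data
NULL
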