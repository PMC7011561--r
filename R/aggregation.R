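#' Quantile of scaled p values
#'
#' The building block of the aggregation rule: for a set of p values
#' \eqn{p_1, \dots, p_K} and a quantile level \eqn{\gamma \in (0,1)},
#' computes
#' \deqn{Q_\gamma = \min\left(1,\ \mathrm{Quantile}_\gamma\{p_i/\gamma\}\right).}
#' The empirical quantile is the inverse-ECDF convention: the smallest order
#' statistic whose ECDF is at least \eqn{\gamma} (type-1 quantile). This
#' convention is fixed because different conventions shift results
#' noticeably at small K.
#'
#' @param p_values numeric vector of p values in \[0,1\].
#' @param gamma quantile level in (0,1).
#' @return A single value in \[0,1\].
#' @examples
#' quantile_scaled(c(0.01, 0.02, 0.03), gamma = 0.5) # median of doubled ps
#' @export
quantile_scaled <- function(p_values, gamma) {
  check_pvalues(p_values)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1) {
    stop("gamma must be a single value strictly inside (0, 1)")
  }
  min(1, type1_quantile(p_values / gamma, gamma))
}

# smallest order statistic with ECDF >= gamma; the 1e-9 slack keeps
# gamma * n that is an integer up to floating point from rounding up
type1_quantile <- function(x, gamma) {
  n <- length(x)
  k <- min(n, max(1L, as.integer(ceiling(gamma * n - 1e-9))))
  sort(x, partial = k)[k]
}

check_pvalues <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value set")
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1] with no missing values")
  }
  invisible(p_values)
}

#' Merge dependent p values with a prespecified quantile level
#'
#' Aggregates K per-split p values into one p value using a fixed
#' \eqn{\gamma}:
#' \deqn{p_{\mathrm{agg}} = \min\left(1,\ \mathrm{Quantile}_\gamma\{p_i/\gamma\}\right).}
#' With \eqn{\gamma = 0.5} this is exactly \eqn{\min(1, \mathrm{Median}(2p_1,
#' \dots, 2p_K))}, the "twice the median" rule. The merged value is a valid
#' p value even though the \eqn{p_i} are dependent (they share the data
#' across random splits).
#'
#' @inheritParams quantile_scaled
#' @param trace logical: also compute the running aggregate over prefixes
#'   \eqn{p_{1..k}} for the K-stabilisation diagnostic (default `TRUE`).
#' @return An object of class `aggregate_result`; see [aggregate_adaptive()].
#' @examples
#' aggregate_fixed_gamma(c(0.01, 0.02, 0.03), gamma = 0.5)$p_aggregate # 0.04
#' @export
aggregate_fixed_gamma <- function(p_values, gamma, trace = TRUE) {
  check_pvalues(p_values)
  if (gamma <= 0 || gamma >= 1) stop("gamma must be inside (0, 1)")
  p_agg <- quantile_scaled(p_values, gamma)
  tr <- if (trace) {
    vapply(seq_along(p_values),
           function(k) quantile_scaled(p_values[seq_len(k)], gamma),
           numeric(1))
  } else NULL
  new_aggregate_result(p_values, p_agg, method = "fixed_gamma",
                       gamma = gamma, alpha = NULL, trace = tr)
}

#' Merge dependent p values with an adaptive quantile sweep
#'
#' Aggregates K p values by minimising the scaled quantile over
#' \eqn{\gamma \in [\alpha, 1]}, paying a \eqn{(1-\log\alpha)} penalty
#' (natural logarithm) for the search:
#' \deqn{p_{\mathrm{agg}} = \min_{\gamma \in [\alpha,1]} \min\left(1,\
#'   (1-\log\alpha)\, Q_\gamma\{p_i\}\right).}
#' \eqn{Q_\gamma} is piecewise in \eqn{\gamma} through the order statistics,
#' so the minimisation is exact on the grid \eqn{\{\alpha\} \cup \{j/K : j =
#' \lceil \alpha K\rceil, \dots, K\}} (each piece of \eqn{Q_\gamma} is
#' decreasing in \eqn{\gamma}, so its minimum sits at the right endpoint
#' \eqn{j/K}).
#'
#' @inheritParams quantile_scaled
#' @param alpha significance level in (0,1) at which the aggregate will be
#'   compared; also the lower end of the \eqn{\gamma} sweep.
#' @param trace logical: compute the running aggregate over prefixes.
#' @return An object of class `aggregate_result`: list with `p_values`,
#'   `p_aggregate`, `method`, `gamma` (NULL for adaptive), `alpha`, `trace`.
#' @examples
#' # constant p values: minimum at gamma = 1, closed form (1 - log(alpha)) * p
#' aggregate_adaptive(rep(0.001, 100), alpha = 0.05)$p_aggregate
#' @export
aggregate_adaptive <- function(p_values, alpha = 0.05, trace = TRUE) {
  check_pvalues(p_values)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be inside (0, 1)")
  p_agg <- adaptive_value(p_values, alpha)
  tr <- if (trace) {
    vapply(seq_along(p_values),
           function(k) adaptive_value(p_values[seq_len(k)], alpha),
           numeric(1))
  } else NULL
  new_aggregate_result(p_values, p_agg, method = "adaptive",
                       gamma = NULL, alpha = alpha, trace = tr)
}

adaptive_value <- function(p_values, alpha) {
  K <- length(p_values)
  sp <- sort(p_values)
  penalty <- 1 - log(alpha)
  grid <- unique(c(alpha, seq.int(ceiling(alpha * K - 1e-9), K) / K, 1))
  grid <- grid[grid >= alpha & grid <= 1]
  vals <- vapply(grid, function(g) {
    k <- min(K, max(1L, as.integer(ceiling(g * K - 1e-9))))
    min(1, penalty * min(1, sp[k] / g))
  }, numeric(1))
  min(vals)
}

new_aggregate_result <- function(p_values, p_aggregate, method, gamma, alpha,
                                 trace) {
  structure(list(p_values = as.numeric(p_values),
                 p_aggregate = p_aggregate,
                 method = method, gamma = gamma, alpha = alpha,
                 trace = trace),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  par_txt <- if (x$method == "fixed_gamma") {
    sprintf("gamma = %g", x$gamma)
  } else {
    sprintf("gamma swept over [%g, 1], penalty 1 - log(alpha)", x$alpha)
  }
  cat(sprintf("Aggregate of %d split p values (%s, %s)\n",
              length(x$p_values), x$method, par_txt))
  cat(sprintf("  p_aggregate = %.6g\n", x$p_aggregate))
  invisible(x)
}

#' Rejection boundary of the adaptive aggregation rule in the ECDF plane
#'
#' The adaptive rule rejects at level \eqn{\alpha} if and only if the
#' empirical CDF of the per-split p values touches or crosses above the
#' parametric curve
#' \deqn{\left(x, y\right) = \left(\frac{\gamma\,\alpha}{1-\log\alpha},\ \gamma\right),
#'   \quad \gamma \in [\alpha, 1],}
#' a straight segment of slope \eqn{(1-\log\alpha)/\alpha} through the
#' origin direction. Plotting the p-value ECDF against this boundary gives a
#' visual significance read-out; the equivalence with
#' [aggregate_adaptive()] `<= alpha` is exact and is exercised in the test
#' suite.
#'
#' @param alpha significance level in (0,1).
#' @param grid number of points on the curve.
#' @return A data frame with columns `x` (p-value axis) and `y` (ECDF axis).
#' @export
boundary_curve <- function(alpha, grid = 200) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be inside (0, 1)")
  g <- seq(alpha, 1, length.out = grid)
  data.frame(x = g * alpha / (1 - log(alpha)), y = g)
}

#' Does the p-value ECDF touch or cross the adaptive rejection boundary?
#'
#' Exact discrete check of the boundary criterion: rejection occurs iff some
#' order statistic \eqn{p_{(j)}} with \eqn{j \ge \lceil\alpha K\rceil}
#' satisfies \eqn{p_{(j)} \le (j/K)\,\alpha/(1-\log\alpha)}.
#'
#' @inheritParams aggregate_adaptive
#' @return Logical scalar.
#' @export
ecdf_crosses_boundary <- function(p_values, alpha = 0.05) {
  check_pvalues(p_values)
  K <- length(p_values)
  sp <- sort(p_values)
  js <- seq.int(max(1L, as.integer(ceiling(alpha * K - 1e-9))), K)
  any(sp[js] <= (js / K) * alpha / (1 - log(alpha)))
}
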