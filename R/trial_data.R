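#' Construct and validate a two-arm randomised trial dataset
#'
#' A `trial_data` object holds the ingredients of a two-arm randomised
#' controlled trial with a binary endpoint: a matrix (data frame) of
#' baseline covariates `X`, a randomised treatment indicator `treatment`
#' (0 = standard of care, 1 = experimental) and a binary outcome `outcome`
#' (1 = adverse event such as death, 0 = no event). The convention that a
#' larger event probability is worse is recorded in the object so that
#' downstream tests orient "benefit" consistently.
#'
#' Covariates may be numeric or categorical (factors / character columns are
#' stored as factors). The pipeline is complete-case: any missing value in
#' the outcome, the treatment, or a covariate is an error that names the
#' offending columns, rather than a silently imputed value.
#'
#' @param X data frame (or matrix) of baseline covariates, one row per
#'   subject.
#' @param treatment integer/numeric vector of 0/1 treatment indicators
#'   (0 = standard of care).
#' @param outcome integer/numeric vector of 0/1 outcomes (1 = adverse event).
#' @param subject_id optional vector of subject labels; defaults to
#'   `seq_len(n)`.
#' @return An object of class `trial_data`: a list with elements
#'   `subject_id`, `X` (data frame), `treatment`, `outcome`, `n` and
#'   `outcome_orientation` (always `"higher_is_worse"`).
#' @examples
#' td <- trial_data(data.frame(age = c(30, 40, 50, 60)),
#'                  treatment = c(0, 1, 0, 1),
#'                  outcome   = c(0, 0, 1, 1))
#' td$n
#' @export
trial_data <- function(X, treatment, outcome, subject_id = NULL) {
  if (is.matrix(X)) X <- as.data.frame(X)
  stopifnot(is.data.frame(X))
  X <- as.data.frame(lapply(X, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }), stringsAsFactors = FALSE)
  n <- nrow(X)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  obj <- structure(
    list(subject_id = subject_id,
         X = X,
         treatment = as.integer(treatment),
         outcome = as.integer(outcome),
         n = n,
         outcome_orientation = "higher_is_worse"),
    class = "trial_data")
  validate_trial_data(obj)
  obj
}

#' Validate a trial_data object
#'
#' Checks the structural invariants: treatment and outcome are binary with
#' no missing values, both arms are non-empty, all vectors share the common
#' length `n`, and covariates are complete cases.
#'
#' @param data a `trial_data` object.
#' @return `data`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_trial_data <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  n <- data$n
  if (length(data$subject_id) != n || length(data$treatment) != n ||
      length(data$outcome) != n || nrow(data$X) != n) {
    stop("trial_data: subject_id, treatment, outcome and X must all have ",
         "length/row count n = ", n)
  }
  if (anyNA(data$treatment) || anyNA(data$outcome)) {
    stop("trial_data: missing values in treatment or outcome are not allowed")
  }
  if (!all(data$treatment %in% c(0L, 1L))) {
    stop("trial_data: treatment must be coded 0 (standard of care) / 1 ",
         "(experimental)")
  }
  if (!all(data$outcome %in% c(0L, 1L))) {
    stop("trial_data: outcome must be binary 0/1")
  }
  n1 <- sum(data$treatment)
  if (n1 == 0L || n1 == n) {
    stop("trial_data: single-arm data; both treatment arms must be non-empty")
  }
  bad <- names(data$X)[vapply(data$X, anyNA, logical(1))]
  if (length(bad) > 0L) {
    stop("trial_data: missing covariate values (complete cases required) in ",
         "column(s): ", paste(bad, collapse = ", "))
  }
  invisible(data)
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "Two-arm randomised trial: n = %d (%d standard of care, %d experimental)\n",
    x$n, sum(x$treatment == 0L), sum(x$treatment == 1L)))
  cat(sprintf("Binary outcome: %d events (%.1f%%); %d covariates: %s\n",
              sum(x$outcome), 100 * mean(x$outcome), ncol(x$X),
              paste(utils::head(names(x$X), 8), collapse = ", ")))
  invisible(x)
}

#' Describe the columns of a trial CSV file
#'
#' The column roles are declared explicitly (never inferred from the data):
#' which column is the binary outcome, which is the treatment, which label in
#' the treatment column denotes the standard of care, and which columns are
#' baseline covariates.
#'
#' @param outcome name of the binary outcome column (1 = adverse event).
#' @param treatment name of the treatment column.
#' @param covariates character vector of covariate column names.
#' @param soc_label the value in the treatment column that denotes the
#'   standard of care (recoded to 0 on read).
#' @param id optional name of a subject identifier column.
#' @return An object of class `column_schema`.
#' @export
column_schema <- function(outcome, treatment, covariates, soc_label,
                          id = NULL) {
  structure(list(outcome = outcome, treatment = treatment,
                 covariates = covariates, soc_label = soc_label, id = id),
            class = "column_schema")
}

#' Read a two-arm trial from a delimited text file
#'
#' Reads a headed CSV (or other delimiter) and returns a validated
#' [trial_data()] object. The treatment column is recoded so that the
#' standard-of-care label maps to 0 and the single other label maps to 1;
#' character covariates become factors.
#'
#' @param path path to the delimited file (header row required).
#' @param schema a [column_schema()] naming the outcome, treatment and
#'   covariate columns and the standard-of-care label.
#' @param delim field delimiter, default `","`.
#' @return A validated `trial_data` object.
#' @export
read_trial_csv <- function(path, schema, delim = ",") {
  stopifnot(inherits(schema, "column_schema"))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(schema$outcome, schema$treatment, schema$covariates, schema$id)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: column(s) not present in file: ",
         paste(missing_cols, collapse = ", "))
  }
  tr_raw <- raw[[schema$treatment]]
  labels <- unique(tr_raw[!is.na(tr_raw)])
  if (!(schema$soc_label %in% labels)) {
    stop("schema error: standard-of-care label '", schema$soc_label,
         "' does not occur in treatment column '", schema$treatment, "'")
  }
  if (length(labels) == 1L) {
    stop("validation error: single-arm data (every subject received '",
         labels, "')")
  }
  if (length(labels) > 2L) {
    stop("validation error: more than two treatment labels: ",
         paste(labels, collapse = ", "))
  }
  treatment <- ifelse(tr_raw == schema$soc_label, 0L, 1L)
  outcome <- raw[[schema$outcome]]
  if (!all(stats::na.omit(outcome) %in% c(0, 1))) {
    stop("validation error: outcome column '", schema$outcome,
         "' is not binary 0/1")
  }
  subject_id <- if (is.null(schema$id)) seq_len(nrow(raw)) else raw[[schema$id]]
  trial_data(raw[, schema$covariates, drop = FALSE],
             treatment = treatment, outcome = outcome,
             subject_id = subject_id)
}

#' Write a trial back to CSV
#'
#' Serialises a `trial_data` object to a comma-separated file with the
#' recoded 0/1 treatment, so a round trip through [read_trial_csv()] with
#' `soc_label = 0` reproduces the object.
#'
#' @param data a `trial_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  validate_trial_data(data)
  out <- cbind(data.frame(subject_id = data$subject_id,
                          treatment = data$treatment,
                          outcome = data$outcome),
               data$X)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw one arm-balanced random 50/50 partition of a trial
#'
#' Splits the subjects into two halves of (near-)equal size such that within
#' each treatment arm the counts in the two halves differ by at most one.
#' Subjects are permuted uniformly at random within each arm, so given the
#' seed the partition is reproducible and distinct seeds give (with
#' overwhelming probability) distinct partitions. The global RNG state is
#' left untouched.
#'
#' @param data a `trial_data` object; each arm must contain at least two
#'   subjects.
#' @param seed integer seed for the partition draw.
#' @return An object of class `split_plan`: list with integer index vectors
#'   `half_a` and `half_b` and the `seed` used.
#' @examples
#' td <- trial_data(data.frame(x = rnorm(10)),
#'                  treatment = rep(c(0, 1), 5),
#'                  outcome   = rep(c(0, 1), each = 5))
#' plan <- make_split_plan(td, seed = 1)
#' sort(c(plan$half_a, plan$half_b))
#' @export
make_split_plan <- function(data, seed) {
  validate_trial_data(data)
  arm1 <- which(data$treatment == 1L)
  arm0 <- which(data$treatment == 0L)
  if (length(arm1) < 2L || length(arm0) < 2L) {
    stop("cannot balance split: each arm needs at least 2 subjects")
  }
  withr::with_seed(as.integer(seed), {
    arm1 <- sample(arm1)
    arm0 <- sample(arm0)
  })
  # arm 1's odd subject (if any) goes to half A, arm 0's to half B, so the
  # overall half sizes also differ by at most one
  k1 <- ceiling(length(arm1) / 2)
  k0 <- if (length(arm1) %% 2 == 1L) floor(length(arm0) / 2) else
    ceiling(length(arm0) / 2)
  half_a <- sort(c(arm1[seq_len(k1)], arm0[seq_len(k0)]))
  half_b <- sort(setdiff(seq_len(data$n), half_a))
  structure(list(half_a = half_a, half_b = half_b, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: |half_a| = %d, |half_b| = %d (seed %d)\n",
              length(x$half_a), length(x$half_b), x$seed))
  invisible(x)
}

# Internal: arm-stratified split at an arbitrary ratio (used only by the
# split-ratio experiment; the headline tests always split 50/50).
split_at_ratio <- function(data, seed, ratio) {
  stopifnot(ratio > 0, ratio < 1)
  arm1 <- which(data$treatment == 1L)
  arm0 <- which(data$treatment == 0L)
  withr::with_seed(as.integer(seed), {
    arm1 <- sample(arm1)
    arm0 <- sample(arm0)
  })
  k1 <- round(length(arm1) * ratio)
  k0 <- round(length(arm0) * ratio)
  half_a <- sort(c(arm1[seq_len(k1)], arm0[seq_len(k0)]))
  half_b <- sort(setdiff(seq_len(data$n), half_a))
  structure(list(half_a = half_a, half_b = half_b, seed = as.integer(seed)),
            class = "split_plan")
}

# Internal: subset a trial_data by row indices.
subset_trial <- function(data, idx) {
  structure(list(subject_id = data$subject_id[idx],
                 X = data$X[idx, , drop = FALSE],
                 treatment = data$treatment[idx],
                 outcome = data$outcome[idx],
                 n = length(idx),
                 outcome_orientation = data$outcome_orientation),
            class = "trial_data")
}
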