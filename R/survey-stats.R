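# Corpus-level meta-analysis of diagnostics records: parameter
# correlation matrices, PCA, multiple regression.

#' Mean within-chain parameter correlation matrix
#'
#' For every pair of sampled quantities, computes the Pearson
#' correlation of their traces within each chain and averages the
#' per-chain coefficients across all chains of all analyses. This is
#' the machinery behind parameter-interaction heatmaps such as the
#' strong negative correlation between LnPr and tree length induced by
#' the tree-length prior.
#'
#' @param runsets A [run_set()], a list of them, or a list of
#'   [parameter_trace()] objects.
#' @return Symmetric correlation matrix with unit diagonal; an
#'   attribute `n_chains` gives the per-cell number of chains
#'   averaged. Chains in which either parameter has zero variance are
#'   skipped for that pair (with a message).
#' @export
parameter_correlation_matrix <- function(runsets) {
  traces <- collect_param_traces(runsets)
  params <- Reduce(union, lapply(traces, function(tr) names(tr$columns)))
  p <- length(params)
  acc <- cnt <- matrix(0, p, p, dimnames = list(params, params))
  skipped <- 0L
  for (tr in traces) {
    if (tr$n_samples < 3L) stop("need at least 3 samples per chain")
    present <- intersect(params, names(tr$columns))
    X <- as.matrix(tr$columns[present])
    v <- apply(X, 2L, stats::var)
    ok <- present[v > 0]
    skipped <- skipped + sum(v == 0)
    if (length(ok) >= 1L) {
      cc <- stats::cor(X[, ok, drop = FALSE])
      acc[ok, ok] <- acc[ok, ok] + cc
      cnt[ok, ok] <- cnt[ok, ok] + 1
    }
  }
  if (skipped) message(skipped, " zero-variance parameter/chain pairs skipped")
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  diag(out) <- 1
  attr(out, "n_chains") <- cnt
  out
}

collect_param_traces <- function(runsets) {
  if (inherits(runsets, "run_set")) return(runsets$param_traces)
  if (inherits(runsets, "parameter_trace")) return(list(runsets))
  stopifnot(is.list(runsets), length(runsets) >= 1L)
  unlist(lapply(runsets, function(x) {
    if (inherits(x, "run_set")) x$param_traces
    else if (inherits(x, "parameter_trace")) list(x)
    else stop("expected run_set or parameter_trace objects")
  }), recursive = FALSE)
}

#' Principal component analysis of survey columns
#'
#' PCA on the correlation matrix of the selected columns: rows with
#' missing values are dropped (complete-case deletion), the data are
#' centered and scaled to unit variance, and components are
#' eigenvectors of the resulting correlation matrix. Loading signs
#' follow a deterministic convention (the largest-magnitude loading of
#' each component is positive).
#'
#' @param table Data frame of survey rows (see [gen_survey_cohort()]).
#' @param columns Character vector of columns to analyse; default all
#'   numeric columns.
#' @return An object of class `pca_result`: `loadings` (variables x
#'   components, orthonormal), `scores` (rows x components),
#'   `variance_fraction` (nonincreasing, summing to 1 over all
#'   components), `sdev`, `columns`, `n_used`.
#' @export
pca <- function(table, columns = NULL) {
  table <- as.data.frame(table)
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1L))]
  if (length(columns) < 2L) stop("need at least 2 columns")
  X <- table[columns]
  cc <- stats::complete.cases(X)
  X <- as.matrix(X[cc, , drop = FALSE])
  if (nrow(X) < 2L) stop("need at least 2 complete rows")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0))
    stop("constant column: ", paste(columns[v == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(loadings = pc$rotation, scores = pc$x,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, columns = columns, n_used = nrow(X),
                 center = pc$center, scale = pc$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d variables on %d rows\n", length(x$columns), x$n_used))
  vf <- round(100 * x$variance_fraction[seq_len(min(5L, length(x$variance_fraction)))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "),
      if (length(x$variance_fraction) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Multiple regression of a diagnostic on data-set features
#'
#' Ordinary least squares with intercept, the machinery for regressing
#' ESS values (or PCA scores) on the number of taxa, number of
#' characters, and average branch length. Predictors are raw-scale by
#' default; `scale_predictors = TRUE` z-scores them so coefficient
#' magnitudes are comparable, and `log_response = TRUE` fits the log of
#' the response.
#'
#' @param table Data frame of survey rows.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param scale_predictors Z-score predictors before fitting?
#' @param log_response Fit `log(response)`?
#' @return An object of class `regression_result`: `coefficients`
#'   (data frame: term, estimate, std_error, t, p_value),
#'   `adj_r_squared`, `n_used`, and the underlying `lm` fit.
#' @export
regress <- function(table, response, predictors,
                    scale_predictors = FALSE, log_response = FALSE) {
  table <- as.data.frame(table)
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  dat <- table[c(response, predictors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L)
    stop("need at least p + 2 complete rows")
  if (log_response) dat[[response]] <- log(dat[[response]])
  if (scale_predictors) dat[predictors] <- lapply(dat[predictors], scale)
  mm <- stats::model.matrix(
    stats::reformulate(predictors, response = NULL), dat)
  kap <- kappa(mm, exact = TRUE)
  if (kap > 1e10)
    stop(sprintf("collinear predictors (condition number %.3g)", kap))
  fit <- stats::lm(stats::reformulate(predictors, response = sprintf("`%s`", response)),
                   data = dat)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_error", "t", "p_value")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  structure(list(coefficients = co, adj_r_squared = sm$adj.r.squared,
                 n_used = nrow(dat), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS on %d rows, adjusted R^2 = %.3f\n", x$n_used, x$adj_r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Evaluate pass flags for every row of a survey table
#'
#' Applies [evaluate()] row-wise to a survey cohort table: `ess_<p>`
#' columns feed the ESS flag (LnL/LnPr excluded as non-parameters),
#' `psrf_<p>` columns the PSRF flag, and `topo_ess`, `asdsf`,
#' `split_corr` their own flags.
#'
#' @param table A survey data frame, e.g. from [gen_survey_cohort()].
#' @param th A [thresholds()] object.
#' @param include_lnl Count LnL/LnPr among ESS-flagged parameters?
#' @return Data frame of logical flags, one row per analysis.
#' @export
evaluate_survey <- function(table, th = thresholds(), include_lnl = FALSE) {
  table <- as.data.frame(table)
  ess_cols <- grep("^ess_", names(table), value = TRUE)
  psrf_cols <- grep("^psrf_", names(table), value = TRUE)
  out <- lapply(seq_len(nrow(table)), function(i) {
    rec <- list(
      ess = stats::setNames(as.numeric(table[i, ess_cols]),
                            sub("^ess_", "", ess_cols)),
      psrf = if (length(psrf_cols))
        as.numeric(table[i, psrf_cols]) else NULL,
      topo_ess = table[["topo_ess"]][i] %||% NULL,
      asdsf = table[["asdsf"]][i] %||% NULL,
      split_corr = table[["split_corr"]][i] %||% NULL)
    as.list(evaluate(rec, th, include_lnl = include_lnl))
  })
  out <- do.call(rbind, lapply(out, as.data.frame))
  rownames(out) <- NULL
  out
}
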