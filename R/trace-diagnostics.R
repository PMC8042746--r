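# Single- and multi-chain diagnostics on continuous parameter traces.

#' Lag-k sample autocorrelation
#'
#' Standard biased (divisor n) sample autocorrelation at a given lag.
#' The divisor-n convention keeps the implied autocovariance sequence
#' positive definite, the usual spectral practice.
#'
#' @param x Numeric sample vector.
#' @param lag Nonnegative lag, strictly less than `length(x)`.
#' @return Autocorrelation in \eqn{[-1, 1]}; 1 at lag 0.
#' @export
autocorrelation <- function(x, lag) {
  stopifnot(is.numeric(x), is_count(lag), lag >= 0)
  n <- length(x)
  if (lag >= n) stop("lag must be smaller than the sample size")
  m <- mean(x)
  c0 <- sum((x - m)^2) / n
  if (c0 == 0) stop("zero variance: autocorrelation undefined")
  if (lag == 0L) return(1)
  ck <- sum((x[seq_len(n - lag)] - m) * (x[(lag + 1L):n] - m)) / n
  ck / c0
}

# Empirical autocorrelations rho_1..rho_K computed lazily in growing
# windows until a truncation point is found (first nonpositive rho, or
# first nonpositive Geyer pair sum).
acf_prefix <- function(x, need_pairs = FALSE) {
  n <- length(x)
  L <- min(n - 1L, 128L)
  repeat {
    rho <- as.vector(stats::acf(x, lag.max = L, plot = FALSE,
                                demean = TRUE)$acf)[-1L]
    if (need_pairs) {
      g <- c(1 + rho[1L], rho[seq(2L, length(rho) - 1L, by = 2L)] +
               rho[seq(3L, length(rho), by = 2L)])
      if (any(g <= 0) || L >= n - 1L) return(rho)
    } else {
      if (any(rho <= 0) || L >= n - 1L) return(rho)
    }
    L <- min(n - 1L, 2L * L)
  }
}

#' Effective sample size of a scalar trace
#'
#' Estimates the autocorrelation time \eqn{\tau = 1 + 2 \sum_k \rho_k}
#' and returns ESS = n / \eqn{\tau}. The default truncation is the
#' initial positive sequence: the sum runs up to the lag before the
#' first nonpositive empirical autocorrelation, the estimator used by
#' the Tracer family of tools. `method = "monotone"` applies Geyer's
#' initial monotone sequence on pair sums instead. No upper cap is
#' applied, so estimator noise can push ESS slightly above n; reports
#' flag such values rather than truncating them.
#'
#' @param x Numeric sample vector, length at least 10, nonconstant.
#' @param method Truncation rule: `"ips"` (initial positive sequence,
#'   default) or `"monotone"` (Geyer initial monotone).
#' @param parameter Optional parameter name carried into the result.
#' @return An object of class `ess_result`: list with `parameter`,
#'   `ess`, `act` and `n`, satisfying `ess == n / act`.
#' @export
ess <- function(x, method = c("ips", "monotone"), parameter = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::var(x) == 0) stop("zero variance: ESS undefined")
  rho <- acf_prefix(x, need_pairs = method == "monotone")
  if (method == "ips") {
    cut <- which(rho <= 0)
    K <- if (length(cut)) cut[[1L]] - 1L else length(rho)
    act <- 1 + 2 * sum(rho[seq_len(K)])
  } else {
    # Geyer: Gamma_m = rho_{2m} + rho_{2m+1} (rho_0 = 1); truncate at the
    # first nonpositive pair sum, then enforce monotone nonincreasing.
    rho2 <- c(1, rho)
    m_max <- floor(length(rho2) / 2L)
    g <- vapply(seq_len(m_max), function(m) rho2[[2L * m - 1L]] + rho2[[2L * m]],
                numeric(1L))
    cut <- which(g <= 0)
    M <- if (length(cut)) cut[[1L]] - 1L else length(g)
    g <- g[seq_len(M)]
    if (length(g) > 1L) g <- cummin(g)
    act <- -1 + 2 * sum(g)
  }
  act <- max(act, .Machine$double.eps)
  structure(list(parameter = parameter, ess = n / act, act = act, n = n),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("ESS %s= %.1f (ACT %.2f, n = %d)%s\n",
              if (is.na(x$parameter)) "" else paste0("[", x$parameter, "] "),
              x$ess, x$act, x$n,
              if (x$ess > x$n) " [exceeds n: estimator noise]" else ""))
  invisible(x)
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Compares among-chain to within-chain variance for one scalar
#' quantity sampled by two or more chains of equal length:
#' \deqn{PSRF = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}}
#' with W the mean within-chain variance (divisor n - 1) and B/n the
#' variance of the chain means (divisor m - 1). Values near 1 indicate
#' the chains share a distribution; values well above 1 indicate
#' disagreement. The classical variant with the additional B/(mn)
#' sampling-variability term is available via `between_chain_term`.
#'
#' @param chains Numeric matrix (n samples x m chains) or list of
#'   equal-length numeric vectors, m >= 2.
#' @param parameter Optional parameter name carried into the result.
#' @param between_chain_term Include the B/(mn) term in the pooled
#'   variance estimate?
#' @return An object of class `psrf_result`: list with `parameter`,
#'   `psrf`, `within_variance`, `between_over_n`, `n`, `m`.
#' @export
psrf <- function(chains, parameter = NA_character_, between_chain_term = FALSE) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("chains must have equal lengths")
    chains <- do.call(cbind, chains)
  }
  stopifnot(is.matrix(chains))
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 2L) stop("need at least 2 samples per chain")
  W <- mean(apply(chains, 2L, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0)
    stop("constant chains: within-chain variance is zero, PSRF undefined")
  V <- (n - 1) / n * W + B_over_n
  if (between_chain_term) V <- V + B_over_n / m
  structure(list(parameter = parameter, psrf = sqrt(V / W),
                 within_variance = W, between_over_n = B_over_n,
                 n = n, m = m),
            class = "psrf_result")
}

#' @export
print.psrf_result <- function(x, ...) {
  cat(sprintf("PSRF %s= %.4f (W = %.4g, B/n = %.4g, n = %d, m = %d)\n",
              if (is.na(x$parameter)) "" else paste0("[", x$parameter, "] "),
              x$psrf, x$within_variance, x$between_over_n, x$n, x$m))
  invisible(x)
}

#' Per-parameter ESS and PSRF table for a run set
#'
#' Batch entry point: computes ESS and autocorrelation time per
#' parameter per chain, and PSRF per parameter across chains, for all
#' parameter-trace columns of a run set.
#'
#' @param runset A [run_set()].
#' @param method ESS truncation rule, see [ess()].
#' @return A data frame with one row per parameter x chain (ESS, ACT)
#'   and the across-chain PSRF repeated on each of the parameter's
#'   rows.
#' @export
trace_diagnostics_table <- function(runset, method = "ips") {
  params <- names(runset$param_traces[[1L]]$columns)
  chains <- vapply(runset$param_traces, `[[`, character(1L), "chain_id")
  rows <- list()
  for (p in params) {
    cols <- lapply(runset$param_traces, function(tr) tr$columns[[p]])
    r <- vapply(cols, function(x) {
      e <- ess(x, method = method, parameter = p)
      c(e$ess, e$act)
    }, numeric(2L))
    ps <- if (length(cols) >= 2L) psrf(cols, parameter = p)$psrf else NA_real_
    rows[[p]] <- data.frame(parameter = p, chain_id = chains,
                            ess = r[1L, ], act = r[2L, ],
                            n = length(cols[[1L]]), psrf = ps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
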