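# Multi-chain and single-chain diagnostics on tree samples.

#' Average standard deviation of split frequencies (ASDSF)
#'
#' For every bipartition reaching `min_freq` in at least one chain,
#' takes the standard deviation of its per-chain frequencies and
#' averages these SDs. Values near 0 indicate the chains sample the
#' same tree distribution; the conventional pass threshold is 0.01 with
#' `min_freq = 0.1`.
#'
#' @param table A [split_frequencies()] table over at least two chains.
#' @param min_freq Minimum within-chain frequency a split must reach in
#'   at least one chain to be included, in \eqn{[0, 1)}.
#' @param sd_divisor `"sample"` (divisor m - 1, the MrBayes across-run
#'   convention, default) or `"population"` (divisor m).
#' @param include `"any"` (default: split included when it reaches
#'   `min_freq` in at least one chain) or `"all"` (must reach it in
#'   every chain).
#' @return An object of class `asdsf_result`: list with `asdsf`,
#'   `n_splits_included`, `min_freq`, `per_split_sd` (named), and
#'   `no_splits` flag. With zero included splits the ASDSF is defined
#'   as 0 and a warning is raised.
#' @export
asdsf <- function(table, min_freq = 0.1,
                  sd_divisor = c("sample", "population"),
                  include = c("any", "all")) {
  sd_divisor <- match.arg(sd_divisor)
  include <- match.arg(include)
  stopifnot(inherits(table, "split_freq_table"))
  if (table$n_chains < 2L) stop("ASDSF requires at least two chains")
  if (!is.numeric(min_freq) || min_freq < 0 || min_freq >= 1)
    stop("min_freq must lie in [0, 1)")
  sel <- if (include == "any") {
    apply(table$freq >= min_freq, 1L, any)
  } else {
    apply(table$freq >= min_freq, 1L, all)
  }
  f <- table$freq[sel, , drop = FALSE]
  if (!nrow(f)) {
    warning("no splits reach min_freq; ASDSF defined as 0")
    return(structure(list(asdsf = 0, n_splits_included = 0L,
                          min_freq = min_freq,
                          per_split_sd = stats::setNames(numeric(0), character(0)),
                          no_splits = TRUE),
                     class = "asdsf_result"))
  }
  m <- ncol(f)
  sds <- apply(f, 1L, stats::sd)
  if (sd_divisor == "population") sds <- sds * sqrt((m - 1) / m)
  structure(list(asdsf = mean(sds), n_splits_included = nrow(f),
                 min_freq = min_freq,
                 per_split_sd = stats::setNames(sds, rownames(f)),
                 no_splits = FALSE),
            class = "asdsf_result")
}

#' @export
print.asdsf_result <- function(x, ...) {
  cat(sprintf("ASDSF = %.5f over %d splits (min freq %.2f)\n",
              x$asdsf, x$n_splits_included, x$min_freq))
  invisible(x)
}

#' Split-frequency correlation among chains
#'
#' Pearson correlation of the per-chain frequency vectors of the
#' included splits (inclusion rule as in [asdsf()]); with more than two
#' chains, the mean over all chain pairs. High values (conventionally
#' at least 0.9) indicate chains agree on which splits are common.
#'
#' @inheritParams asdsf
#' @return The (mean pairwise) Pearson correlation.
#' @export
split_freq_correlation <- function(table, min_freq = 0.1,
                                   include = c("any", "all")) {
  include <- match.arg(include)
  stopifnot(inherits(table, "split_freq_table"))
  if (table$n_chains < 2L) stop("requires at least two chains")
  sel <- if (include == "any") {
    apply(table$freq >= min_freq, 1L, any)
  } else {
    apply(table$freq >= min_freq, 1L, all)
  }
  f <- table$freq[sel, , drop = FALSE]
  if (nrow(f) < 2L)
    stop("correlation undefined: fewer than 2 included splits")
  if (any(apply(f, 2L, stats::var) == 0))
    stop("correlation undefined: a chain has zero variance over included splits")
  prs <- utils::combn(ncol(f), 2L)
  mean(apply(prs, 2L, function(p) stats::cor(f[, p[1L]], f[, p[2L]])))
}

#' Topological effective sample size
#'
#' ESS adapted to tree topology through tree distances.
#'
#' `method = "pseudo"`: draws `n_refs` reference trees uniformly
#' (seeded) from the sample, converts the trace into scalar traces of
#' Robinson-Foulds distances to each reference, computes [ess()] on
#' each, and reports the median (the per-reference values are
#' retained). `method = "approx"`: estimates a topological
#' autocorrelation function from lagged mean squared RF distances,
#' \eqn{\rho(k) = 1 - D(k)/D_\infty} with \eqn{D_\infty} the all-pairs
#' mean squared distance, truncates at the first nonpositive value and
#' reports \eqn{n/\tau}.
#'
#' @param trace A [topology_trace()] with at least 10 samples.
#' @param method `"pseudo"` (default) or `"approx"`.
#' @param n_refs Number of reference trees for the pseudo method.
#' @param seed Seed for reference-tree choice (pseudo method).
#' @return An object of class `topo_ess_result`: list with `ess`,
#'   `method`, `n`, and for the pseudo method `n_reference_trees` and
#'   `per_reference_ess`.
#' @export
topological_ess <- function(trace, method = c("pseudo", "approx"),
                            n_refs = 10L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "topology_trace"))
  n <- trace$n_samples
  if (n < 10L) stop("need at least 10 tree samples")
  tid <- trace_topo_ids(trace)
  u <- length(tid$keysets)
  if (u == 1L) stop("zero topological variance: all sampled trees identical")
  dmat <- matrix(0, u, u)
  for (i in seq_len(u - 1L)) for (j in (i + 1L):u) {
    dmat[i, j] <- dmat[j, i] <- rf_from_keys(tid$keysets[[i]], tid$keysets[[j]])
  }
  ids <- tid$ids
  if (method == "pseudo") {
    refs <- with_seed_internal(seed,
      sample.int(n, min(n_refs, n), replace = FALSE))
    per_ref <- vapply(refs, function(r) {
      dtrace <- dmat[ids[[r]], ids]
      if (stats::var(dtrace) == 0) return(NA_real_)
      ess(dtrace)$ess
    }, numeric(1L))
    if (all(is.na(per_ref)))
      stop("zero topological variance: distance traces constant")
    structure(list(ess = stats::median(per_ref, na.rm = TRUE),
                   method = "pseudo", n = n,
                   n_reference_trees = length(refs),
                   per_reference_ess = per_ref),
              class = "topo_ess_result")
  } else {
    counts <- tabulate(ids, nbins = u)
    d2 <- dmat^2
    num <- as.numeric(counts %*% d2 %*% counts)  # includes zero self-pairs
    d_inf <- num / (n * (n - 1))
    if (d_inf == 0) stop("zero topological variance")
    rho_at <- function(k) {
      a <- ids[seq_len(n - k)]; b <- ids[(k + 1L):n]
      1 - mean(d2[cbind(a, b)]) / d_inf
    }
    tau <- 1; k <- 1L
    while (k < n) {
      r <- rho_at(k)
      if (r <= 0) break
      tau <- tau + 2 * r
      k <- k + 1L
    }
    structure(list(ess = n / tau, method = "approx", n = n, act = tau),
              class = "topo_ess_result")
  }
}

#' @export
print.topo_ess_result <- function(x, ...) {
  cat(sprintf("topological ESS (%s) = %.1f (n = %d)\n", x$method, x$ess, x$n))
  invisible(x)
}

#' One-row topology diagnostics for a run set
#'
#' Batch entry point: ASDSF, split-frequency correlation (both over the
#' cold chains of all runs) and per-chain topological ESS.
#'
#' @param runset A [run_set()].
#' @param min_freq Split inclusion threshold, see [asdsf()].
#' @param topo_method Topological ESS method, see [topological_ess()].
#' @param seed Seed for pseudo-ESS reference trees.
#' @return A one-row data frame: `asdsf`, `split_corr`, and one
#'   `topo_ess_<chain>` column per chain.
#' @export
topology_diagnostics_table <- function(runset, min_freq = 0.1,
                                       topo_method = "pseudo", seed = NULL) {
  tab <- split_frequencies(runset$topo_traces)
  a <- asdsf(tab, min_freq = min_freq)
  sc <- tryCatch(split_freq_correlation(tab, min_freq = min_freq),
                 error = function(e) NA_real_)
  te <- vapply(seq_along(runset$topo_traces), function(k) {
    tryCatch(topological_ess(runset$topo_traces[[k]], method = topo_method,
                             seed = if (is.null(seed)) NULL else child_seed(seed, k))$ess,
             error = function(e) NA_real_)
  }, numeric(1L))
  out <- data.frame(asdsf = a$asdsf, split_corr = sc)
  for (k in seq_along(te))
    out[[paste0("topo_ess_", runset$topo_traces[[k]]$chain_id)]] <- te[[k]]
  out
}
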