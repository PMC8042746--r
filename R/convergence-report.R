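# Threshold classification, failure binning, diagnostic congruence,
# heating recommendation and before/after re-analysis comparison.

#' Convergence thresholds
#'
#' The conventional pass thresholds: per-parameter ESS and topological
#' ESS of at least 200, ASDSF strictly below 0.01, PSRF strictly below
#' 1.02, split-frequency correlation of at least 0.9; a fixed 25%
#' burn-in and a 0.1 split inclusion frequency. Boundary semantics are
#' fixed and documented: ESS, topological ESS and split correlation
#' pass at the threshold (>=), ASDSF and PSRF fail at it (strict <).
#'
#' @param ess_min,topo_ess_min Minimum (topological) ESS.
#' @param asdsf_max Maximum ASDSF (exclusive).
#' @param psrf_max Maximum PSRF (exclusive).
#' @param splitcorr_min Minimum split-frequency correlation.
#' @param burnin_fraction Burn-in fraction removed before diagnostics.
#' @param split_min_freq Split inclusion threshold for ASDSF and the
#'   split correlation.
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(ess_min = 200, topo_ess_min = 200, asdsf_max = 0.01,
                       psrf_max = 1.02, splitcorr_min = 0.9,
                       burnin_fraction = 0.25, split_min_freq = 0.1) {
  th <- list(ess_min = ess_min, topo_ess_min = topo_ess_min,
             asdsf_max = asdsf_max, psrf_max = psrf_max,
             splitcorr_min = splitcorr_min,
             burnin_fraction = burnin_fraction,
             split_min_freq = split_min_freq)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (burnin_fraction >= 1) stop("burnin_fraction must be < 1")
  structure(th, class = "thresholds")
}

#' Read thresholds from a YAML config file
#'
#' @param path YAML file whose top-level keys are [thresholds()]
#'   arguments; missing keys take the defaults.
#' @return A `thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(thresholds)))
  do.call(thresholds, cfg[keep])
}

#' Diagnose a run set
#'
#' Applies burn-in (and optional thinning), computes every diagnostic
#' for one analysis and assembles the unit row of the survey: ESS and
#' autocorrelation time per parameter per chain, PSRF per parameter,
#' ASDSF, split-frequency correlation, per-chain topological ESS, move
#' acceptance rates, and data-set features (number of taxa and
#' characters, average branch length of the majority-rule consensus).
#'
#' @param runset A [run_set()].
#' @param th A [thresholds()] object.
#' @param thin_to Optional number of samples to retain after burn-in.
#' @param topo_method Topological ESS method, see [topological_ess()].
#' @param ess_method ESS truncation rule, see [ess()].
#' @param seed Seed for pseudo-ESS reference trees.
#' @return An object of class `diagnostics_record`.
#' @export
diagnose_runset <- function(runset, th = thresholds(), thin_to = NULL,
                            topo_method = "pseudo", ess_method = "ips",
                            seed = NULL) {
  prep <- function(tr) {
    tr <- apply_burnin(tr, th$burnin_fraction)
    if (!is.null(thin_to)) tr <- thin_trace(tr, thin_to)
    tr
  }
  pts <- lapply(runset$param_traces, prep)
  tts <- lapply(runset$topo_traces, prep)
  params <- names(pts[[1L]]$columns)
  chains <- vapply(pts, `[[`, character(1L), "chain_id")
  ess_mat <- act_mat <- matrix(NA_real_, length(params), length(pts),
                               dimnames = list(params, chains))
  for (p in params) for (k in seq_along(pts)) {
    e <- tryCatch(ess(pts[[k]]$columns[[p]], method = ess_method),
                  error = function(e) NULL)
    if (!is.null(e)) { ess_mat[p, k] <- e$ess; act_mat[p, k] <- e$act }
  }
  psrf_vec <- vapply(params, function(p) {
    tryCatch(psrf(lapply(pts, function(tr) tr$columns[[p]]))$psrf,
             error = function(e) NA_real_)
  }, numeric(1L))
  tab <- split_frequencies(tts)
  asdsf_val <- if (length(tts) >= 2L)
    suppressWarnings(asdsf(tab, min_freq = th$split_min_freq)$asdsf) else NA_real_
  split_corr <- if (length(tts) >= 2L)
    tryCatch(split_freq_correlation(tab, min_freq = th$split_min_freq),
             error = function(e) NA_real_) else NA_real_
  topo_ess_vec <- vapply(seq_along(tts), function(k) {
    tryCatch(topological_ess(tts[[k]], method = topo_method,
                             seed = if (is.null(seed)) NULL else child_seed(seed, k))$ess,
             error = function(e) NA_real_)
  }, numeric(1L))
  names(topo_ess_vec) <- chains
  tlb <- tryCatch(tl_per_branch(mean_branch_tree(tts)),
                  error = function(e) NA_real_)
  rec <- structure(
    list(analysis_id = runset$analysis_id,
         parameters = params,
         ess = ess_mat, act = act_mat,
         psrf = psrf_vec,
         asdsf = asdsf_val, split_corr = split_corr,
         topo_ess = topo_ess_vec,
         acceptance = runset$acceptance,
         n_taxa = runset$n_taxa,
         n_characters = runset$n_characters,
         tl_per_branch = tlb,
         n_samples = pts[[1L]]$n_samples),
    class = "diagnostics_record")
  rec$pass <- evaluate(rec, th)
  rec$failure_bins <- bin_failures(rec, th)
  rec
}

# Mean TL/branch feature: average branch length over the pooled sample.
mean_branch_tree <- function(tts) {
  if (inherits(tts, "topology_trace")) tts <- list(tts)
  lens <- unlist(lapply(tts, function(tr)
    lapply(tr$trees, function(t) t$edge.length)))
  if (is.null(lens)) stop("trees have no branch lengths")
  tr0 <- tts[[1L]]$trees[[1L]]
  tr0$edge.length <- rep(mean(lens), nrow(tr0$edge))
  tr0
}

# Names treated as trace summaries rather than model parameters.
non_parameter_columns <- c("LnL", "LnPr")

#' Evaluate pass/fail flags for one analysis
#'
#' Applies the thresholds to a diagnostics record (or any list with
#' fields `ess`, `topo_ess`, `asdsf`, `psrf`, `split_corr`). The ESS
#' flag requires every non-topology model parameter, in every chain, to
#' reach the ESS threshold; LnL and LnPr are trace summaries rather
#' than model parameters and are excluded unless `include_lnl = TRUE`.
#' The PSRF flag requires every parameter's PSRF to fall strictly below
#' its threshold. A missing diagnostic yields an `NA` (indeterminate)
#' flag, never a pass.
#'
#' @param record A `diagnostics_record` or compatible list.
#' @param th A [thresholds()] object.
#' @param include_lnl Count LnL/LnPr among the ESS-flagged parameters?
#' @return Named logical vector with elements `ess`, `topo_ess`,
#'   `asdsf`, `psrf`, `split_corr` (`NA` = indeterminate).
#' @export
evaluate <- function(record, th = thresholds(), include_lnl = FALSE) {
  ess_vals <- record$ess
  if (!is.null(dim(ess_vals)) || !is.null(names(ess_vals))) {
    keep <- if (include_lnl) rep(TRUE, NROW(ess_vals))
            else !(ess_names(ess_vals) %in% non_parameter_columns)
    ess_vals <- if (is.matrix(ess_vals)) ess_vals[keep, , drop = FALSE]
                else ess_vals[keep]
  }
  flag_ge <- function(v, thr) {
    if (is.null(v) || !length(v) || all(is.na(v))) return(NA)
    if (anyNA(v)) return(NA)
    all(v >= thr)
  }
  flag_lt <- function(v, thr) {
    if (is.null(v) || !length(v) || all(is.na(v))) return(NA)
    if (anyNA(v)) return(NA)
    all(v < thr)
  }
  c(ess = flag_ge(ess_vals, th$ess_min),
    topo_ess = flag_ge(record$topo_ess, th$topo_ess_min),
    asdsf = flag_lt(record$asdsf, th$asdsf_max),
    psrf = flag_lt(record$psrf, th$psrf_max),
    split_corr = flag_ge(record$split_corr, th$splitcorr_min))
}

ess_names <- function(v) {
  if (is.matrix(v)) rownames(v) %||% character(NROW(v)) else names(v) %||% character(length(v))
}

#' Bin a poorly performing analysis by failure mode
#'
#' Assigns an analysis to failure bins: (1) ESS below threshold for at
#' least one continuous parameter (LnL and LnPr count as continuous
#' trace columns here); (2) topological ESS below threshold with LnL
#' ESS also below it; (3) topological ESS below threshold but LnL ESS
#' above it; (4) ASDSF above its threshold. The empty set means no
#' binned failure. For multi-chain records the worst (minimum) chain
#' value is binned.
#'
#' @param record A `diagnostics_record` or compatible list.
#' @param th A [thresholds()] object.
#' @return Integer vector, a subset of `1:4`.
#' @export
bin_failures <- function(record, th = thresholds()) {
  worst <- function(v) if (is.null(v) || !length(v) || all(is.na(v))) NA_real_
                       else min(v, na.rm = TRUE)
  ess_all <- record$ess
  min_ess <- worst(ess_all)
  lnl <- if (is.matrix(ess_all) && "LnL" %in% rownames(ess_all))
    worst(ess_all["LnL", ]) else if ("LnL" %in% names(ess_all))
    ess_all[["LnL"]] else NA_real_
  topo <- worst(record$topo_ess)
  bins <- integer()
  if (!is.na(min_ess) && min_ess < th$ess_min) bins <- c(bins, 1L)
  if (!is.na(topo) && topo < th$topo_ess_min && !is.na(lnl)) {
    if (lnl < th$ess_min) bins <- c(bins, 2L)
    if (lnl > th$ess_min) bins <- c(bins, 3L)
  }
  if (!is.na(record$asdsf %||% NA_real_) && record$asdsf > th$asdsf_max)
    bins <- c(bins, 4L)
  bins
}

#' Congruence counts for a pair of diagnostics
#'
#' Cross-tabulates failures of two diagnostics over a cohort, the
#' counts behind a two-set Venn diagram: how many analyses fail only
#' the first, only the second, both, or neither. Indeterminate (`NA`)
#' flags count as failures of neither.
#'
#' @param records List of `diagnostics_record` objects, or a data frame
#'   of logical pass flags with one row per analysis.
#' @param diagA,diagB Diagnostic names among `ess`, `topo_ess`,
#'   `asdsf`, `psrf`, `split_corr`.
#' @param th A [thresholds()] object (used when records need
#'   evaluating).
#' @return Named integer vector `fail_A_only`, `fail_B_only`,
#'   `fail_both`, `fail_neither`; cells sum to the number of records.
#' @export
congruence_counts <- function(records, diagA, diagB, th = thresholds()) {
  flags <- flag_frame(records, th)
  for (d in c(diagA, diagB)) {
    if (!d %in% names(flags)) stop("unknown diagnostic: ", d)
  }
  fa <- !flags[[diagA]] & !is.na(flags[[diagA]])
  fb <- !flags[[diagB]] & !is.na(flags[[diagB]])
  c(fail_A_only = sum(fa & !fb),
    fail_B_only = sum(fb & !fa),
    fail_both = sum(fa & fb),
    fail_neither = sum(!fa & !fb))
}

flag_frame <- function(records, th) {
  if (is.data.frame(records)) {
    if (all(vapply(records, is.logical, logical(1L)))) return(records)
    return(evaluate_survey(records, th))
  }
  as.data.frame(do.call(rbind, lapply(records, function(r) {
    f <- if (!is.null(r$pass)) r$pass else evaluate(r, th)
    as.list(f)
  })))
}

#' Recommend a Metropolis-coupling temperature
#'
#' Doubles the heating temperature when the cold/heated swap acceptance
#' exceeds 0.5 (chains too similar: bolder proposals wanted) and halves
#' it below 0.5 (heated chains wandering unproductively); exactly 0.5
#' leaves the temperature unchanged.
#'
#' @param current_temp Current heating temperature (> 0).
#' @param swap_acceptance Cold/first-heated swap acceptance in
#'   \eqn{[0, 1]}.
#' @return The recommended temperature.
#' @export
recommend_heating <- function(current_temp, swap_acceptance) {
  if (!is.numeric(current_temp) || current_temp <= 0)
    stop("temperature must be positive")
  if (swap_acceptance < 0 || swap_acceptance > 1)
    stop("swap acceptance must lie in [0, 1]")
  if (swap_acceptance > 0.5) current_temp * 2
  else if (swap_acceptance < 0.5) current_temp / 2
  else current_temp
}

# Total failed-threshold count for one analysis: single-chain
# diagnostics (per-parameter ESS, topological ESS) counted per chain,
# multi-chain diagnostics (ASDSF, PSRF, split correlation) once.
count_failures <- function(record, th = thresholds(), include_lnl = FALSE) {
  n_fail <- 0L
  ess_mat <- record$ess
  if (is.matrix(ess_mat)) {
    keep <- if (include_lnl) rep(TRUE, nrow(ess_mat))
            else !(rownames(ess_mat) %in% non_parameter_columns)
    sub <- ess_mat[keep, , drop = FALSE]
    n_fail <- n_fail + sum(apply(sub, 2L, function(v) any(v < th$ess_min, na.rm = TRUE)))
  } else if (!is.null(ess_mat)) {
    n_fail <- n_fail + sum(ess_mat < th$ess_min, na.rm = TRUE)
  }
  n_fail <- n_fail + sum(record$topo_ess < th$topo_ess_min, na.rm = TRUE)
  if (!is.na(record$asdsf %||% NA_real_) && record$asdsf >= th$asdsf_max)
    n_fail <- n_fail + 1L
  if (any(record$psrf >= th$psrf_max, na.rm = TRUE))
    n_fail <- n_fail + 1L
  if (!is.na(record$split_corr %||% NA_real_) &&
      record$split_corr < th$splitcorr_min)
    n_fail <- n_fail + 1L
  n_fail
}

#' Compare an analysis before and after re-analysis
#'
#' Quantifies the effect of a re-run with changed settings (heating,
#' substitution model, chain length): the change in the total number of
#' failed diagnostic thresholds (single-chain failures summed across
#' chains), and normalized Robinson-Foulds distances between the
#' before/after 50% and 95% majority-rule consensus trees and MCC
#' trees.
#'
#' @param before,after Each a [run_set()], or a list with elements
#'   `runset` and (optionally) `record`; records are computed with
#'   [diagnose_runset()] when absent.
#' @param th A [thresholds()] object.
#' @param ... Passed to [diagnose_runset()] when records are computed.
#' @return An object of class `reanalysis_comparison`: list with
#'   `delta_failures`, `failures_before`, `failures_after` and `rf`
#'   (named vector: `consensus50`, `consensus95`, `mcc`).
#' @export
compare_reanalysis <- function(before, after, th = thresholds(), ...) {
  unpack <- function(x) {
    if (inherits(x, "run_set"))
      list(runset = x, record = diagnose_runset(x, th, ...))
    else {
      if (is.null(x$record)) x$record <- diagnose_runset(x$runset, th, ...)
      x
    }
  }
  before <- unpack(before); after <- unpack(after)
  taxa_b <- before$runset$topo_traces[[1L]]$taxa
  taxa_a <- after$runset$topo_traces[[1L]]$taxa
  if (!setequal(taxa_b, taxa_a)) stop("before/after analyses must share taxa")
  prep <- function(rs) lapply(rs$topo_traces, apply_burnin, th$burnin_fraction)
  tb <- prep(before$runset); ta <- prep(after$runset)
  rf <- c(
    consensus50 = rf_distance(consensus_tree(tb, 0.5), consensus_tree(ta, 0.5),
                              normalized = TRUE),
    consensus95 = rf_distance(consensus_tree(tb, 0.95), consensus_tree(ta, 0.95),
                              normalized = TRUE),
    mcc = rf_distance(mcc_tree(tb), mcc_tree(ta), normalized = TRUE))
  fb <- count_failures(before$record, th)
  fa <- count_failures(after$record, th)
  structure(list(delta_failures = fa - fb,
                 failures_before = fb, failures_after = fa, rf = rf),
            class = "reanalysis_comparison")
}

#' @export
print.reanalysis_comparison <- function(x, ...) {
  cat(sprintf("failed thresholds: %d -> %d (delta %+d)\n",
              x$failures_before, x$failures_after, x$delta_failures))
  cat(sprintf("normalized RF: 50%% consensus %.3f, 95%% consensus %.3f, MCC %.3f\n",
              x$rf[["consensus50"]], x$rf[["consensus95"]], x$rf[["mcc"]]))
  invisible(x)
}

#' @export
print.diagnostics_record <- function(x, ...) {
  cat(sprintf("diagnostics_record '%s' (%d chains, %d samples post burn-in)\n",
              x$analysis_id, ncol(x$ess), x$n_samples))
  cat(sprintf("  min ESS %.0f | topo ESS %s | ASDSF %s | max PSRF %s | split corr %s\n",
              min(x$ess, na.rm = TRUE),
              paste(sprintf("%.0f", x$topo_ess), collapse = "/"),
              format(x$asdsf, digits = 3),
              format(suppressWarnings(max(x$psrf, na.rm = TRUE)), digits = 4),
              format(x$split_corr, digits = 3)))
  p <- x$pass
  cat("  pass:", paste(sprintf("%s=%s", names(p), ifelse(is.na(p), "NA", p)),
                       collapse = " "), "\n")
  if (length(x$failure_bins))
    cat("  failure bins:", paste(x$failure_bins, collapse = ", "), "\n")
  invisible(x)
}
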