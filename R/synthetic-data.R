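# Synthetic multi-chain posteriors with analytically known convergence
# properties: stationary AR(1) parameter traces (optionally correlated
# through a Gaussian copula and perturbed by offsets, trends or mode
# switches) and topology samples from sticky tree-island models. These
# stand in for empirical MrBayes output in calibration and testing.

#' Stationary Gaussian AR(1) trace
#'
#' Generates x_t = mean + sd * u_t with u_t = rho u_(t-1) +
#' sqrt(1 - rho^2) z_t and u_1 drawn from the stationary distribution,
#' so the trace is stationary from the first sample with lag-1
#' autocorrelation rho. Its true effective sample size is
#' n (1 - rho) / (1 + rho).
#'
#' @param n Number of samples.
#' @param mean,variance Stationary mean and variance (variance > 0).
#' @param rho Lag-1 autocorrelation in \eqn{[0, 1)}.
#' @param seed RNG seed (required: synthetic traces must be
#'   reproducible).
#' @return Numeric vector of length `n` with attribute `true_ess`.
#' @export
gen_ar1_trace <- function(n, mean = 0, variance = 1, rho = 0, seed) {
  stopifnot(is_count(n), n >= 1, variance > 0)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (missing(seed)) stop("seed is required")
  z <- with_seed_internal(seed, stats::rnorm(n))
  x <- mean + sqrt(variance) * ar1_filter(z, rho)
  attr(x, "true_ess") <- n * (1 - rho) / (1 + rho)
  x
}

# Unit-variance stationary AR(1) filter of iid N(0,1) innovations.
ar1_filter <- function(z, rho) {
  if (rho == 0) return(z)
  innov <- z * sqrt(1 - rho^2)
  innov[1L] <- z[1L]
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Random island topologies
#'
#' Draws distinct unrooted binary topologies on a common taxon set, the
#' "islands" of a tree-island model, with exponential branch lengths.
#'
#' @param n_taxa Number of taxa (labels `t1..tN`).
#' @param n_islands Number of distinct topologies.
#' @param seed RNG seed.
#' @param mean_branch_length Mean of the exponential branch lengths.
#' @return List of `phylo` objects.
#' @export
random_islands <- function(n_taxa, n_islands = 2L, seed,
                           mean_branch_length = 0.05) {
  stopifnot(is_count(n_taxa), n_taxa >= 4L, is_count(n_islands))
  with_seed_internal(seed, {
    islands <- list()
    sigs <- character()
    tries <- 0L
    while (length(islands) < n_islands) {
      tries <- tries + 1L
      if (tries > 100L * n_islands) stop("cannot find enough distinct topologies")
      tr <- ape::rtopology(n_taxa, rooted = FALSE,
                           tip.label = paste0("t", seq_len(n_taxa)))
      tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_branch_length)
      sig <- paste(sort(decompose_splits(tr)), collapse = ";")
      if (!sig %in% sigs) {
        islands[[length(islands) + 1L]] <- tr
        sigs <- c(sigs, sig)
      }
    }
    islands
  })
}

#' Markov tree-island topology chain
#'
#' Samples a topology trace from a sticky island model: with
#' probability `stickiness` the chain repeats the previous topology,
#' otherwise it draws an island independently with probabilities
#' `probs`. The stationary frequency of a split equals the total
#' probability of the islands containing it, and the island-indicator
#' process has lag-1 autocorrelation `stickiness`, giving an effective
#' topological sample size of about n (1 - s) / (1 + s).
#'
#' @param taxa Taxon labels (must match the islands' leaf sets).
#' @param islands List of `phylo` topologies (the islands).
#' @param probs Island probabilities (default uniform; must sum to 1).
#' @param stickiness Stay probability s in \eqn{[0, 1)}.
#' @param n Number of samples.
#' @param seed RNG seed (required).
#' @param chain_id Chain identifier.
#' @param branch_jitter Lognormal sdlog jitter applied to branch
#'   lengths per sample (0 = islands keep fixed branch lengths).
#' @param switch_at Optional fraction in (0, 1): a deterministic mode
#'   switch pathology. Before that point the chain samples only island
#'   1, after it only island 2.
#' @return A [topology_trace()] with attribute `island_index`.
#' @export
gen_tree_chain <- function(taxa, islands, probs = NULL, stickiness = 0,
                           n, seed, chain_id = "chain1",
                           branch_jitter = 0, switch_at = NULL) {
  stopifnot(length(islands) >= 1L, is_count(n), n >= 1)
  if (missing(seed)) stop("seed is required")
  if (stickiness < 0 || stickiness >= 1) stop("stickiness must lie in [0, 1)")
  k <- length(islands)
  probs <- probs %||% rep(1 / k, k)
  if (length(probs) != k || abs(sum(probs) - 1) > 1e-8)
    stop("island probabilities must sum to 1")
  for (isl in islands) {
    if (!setequal(isl$tip.label, taxa)) stop("islands on mismatched taxa")
  }
  idx <- with_seed_internal(seed, {
    if (!is.null(switch_at)) {
      stopifnot(switch_at > 0, switch_at < 1, k >= 2L)
      cut <- ceiling(switch_at * n)
      c(rep(1L, cut), rep(2L, n - cut))
    } else {
      i <- integer(n)
      i[1L] <- sample.int(k, 1L, prob = probs)
      if (n > 1L) {
        stay <- stats::runif(n) < stickiness
        redraw <- sample.int(k, n, replace = TRUE, prob = probs)
        for (t in 2:n) i[t] <- if (stay[t]) i[t - 1L] else redraw[t]
      }
      i
    }
  })
  trees <- islands[idx]
  if (branch_jitter > 0) {
    trees <- with_seed_internal(child_seed(seed, 1L), lapply(trees, function(tr) {
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, branch_jitter)
      tr
    }))
  }
  attr(trees, "phyloconv_index") <- list(ids = idx, unique_trees = islands)
  out <- topology_trace(chain_id, taxa, trees)
  attr(out, "island_index") <- idx
  out
}

#' Specification for a synthetic multi-chain posterior
#'
#' Defaults emulate the chain structure of a typical thinned MrBayes
#' analysis: four independent cold chains of 1,000 retained samples
#' over a two-island topology distribution on 25 taxa, with a standard
#' set of correlated parameter traces (LnL, LnPr, TL, alpha, pinvar)
#' whose built-in cross-correlations mirror the strong LnPr-TL
#' anticorrelation induced by the tree-length prior and the familiar
#' positive alpha-pinvar correlation of the I+Gamma model.
#'
#' @param n_chains Number of cold chains (2-4 typical).
#' @param n_samples Retained samples per chain.
#' @param parameters Named list; each element a list with `mean`,
#'   `var`, `rho` (lag-1 autocorrelation in \eqn{[0,1)}).
#' @param correlations Named list of target stationary cross-parameter
#'   correlations, names of the form `"A~B"` (planted through a
#'   Gaussian copula on the AR(1) innovations, which preserves each
#'   marginal's autocorrelation; exact when the two parameters share
#'   `rho`).
#' @param chain_offsets Matrix (n_chains x parameters) of per-chain
#'   mean offsets in stationary-SD units (default none).
#' @param trend Named vector of linear trend slopes in SD units over
#'   the whole trace (a non-stationarity pathology; default none).
#' @param n_taxa,n_islands Tree-island model size (used when `islands`
#'   is NULL).
#' @param islands Optional explicit list of island topologies.
#' @param island_probs Island probabilities (vector, or matrix
#'   n_chains x islands for per-chain overrides, e.g. a stuck chain).
#' @param stickiness Island stay-probability (scalar or per-chain).
#' @param mode_switch Optional list(chain=, at=): that chain undergoes
#'   a deterministic island switch at the given sample fraction.
#' @param n_characters Alignment length feature.
#' @param seed RNG seed (required).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chains = 4L, n_samples = 1000L,
                           parameters = default_parameters(),
                           correlations = default_correlations(),
                           chain_offsets = NULL, trend = NULL,
                           n_taxa = 25L, n_islands = 2L, islands = NULL,
                           island_probs = NULL, stickiness = 0,
                           mode_switch = NULL, n_characters = 1000L,
                           seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is_count(n_chains), n_chains >= 1L, is_count(n_samples))
  for (p in parameters) {
    if (p$rho < 0 || p$rho >= 1) stop("rho must lie in [0, 1)")
    if (p$var <= 0) stop("variance must be positive")
  }
  if (any(stickiness < 0 | stickiness >= 1))
    stop("stickiness must lie in [0, 1)")
  structure(list(n_chains = n_chains, n_samples = n_samples,
                 parameters = parameters, correlations = correlations,
                 chain_offsets = chain_offsets, trend = trend,
                 n_taxa = n_taxa, n_islands = n_islands, islands = islands,
                 island_probs = island_probs, stickiness = stickiness,
                 mode_switch = mode_switch, n_characters = n_characters,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_parameters <- function() {
  list(LnL = list(mean = -5000, var = 100, rho = 0.3),
       LnPr = list(mean = 20, var = 25, rho = 0.3),
       TL = list(mean = 2, var = 0.04, rho = 0.3),
       alpha = list(mean = 0.5, var = 0.01, rho = 0.2),
       pinvar = list(mean = 0.3, var = 0.004, rho = 0.2))
}

#' @rdname synthetic_spec
#' @export
default_correlations <- function() {
  list("LnPr~TL" = -0.98, "alpha~pinvar" = 0.59)
}

# Innovation correlation matrix from the "A~B" correlation list.
copula_matrix <- function(parameters, correlations) {
  pn <- names(parameters)
  C <- diag(length(pn))
  dimnames(C) <- list(pn, pn)
  for (nm in names(correlations %||% list())) {
    ab <- strsplit(nm, "~", fixed = TRUE)[[1L]]
    if (length(ab) != 2L || !all(ab %in% pn))
      stop("bad correlation name: ", nm)
    C[ab[1L], ab[2L]] <- C[ab[2L], ab[1L]] <- correlations[[nm]]
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) stop("correlation targets are not positive definite")
  C
}

#' Generate a synthetic run set
#'
#' Builds paired parameter and topology traces per chain from a
#' [synthetic_spec()], plus a plausible move-acceptance table, and
#' attaches the analytic ground truth: true ESS per parameter, the
#' stationary split frequency each chain should approach, and the
#' expected large-n ASDSF implied by any per-chain island-probability
#' differences (zero when chains share a spec).
#'
#' @param spec A [synthetic_spec()].
#' @return A [run_set()] with attribute `ground_truth`.
#' @export
gen_runset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pn <- names(spec$parameters)
  p <- length(pn)
  C <- copula_matrix(spec$parameters, spec$correlations)
  CH <- chol(C)
  islands <- spec$islands %||%
    random_islands(spec$n_taxa, spec$n_islands, seed = child_seed(spec$seed, 999L))
  taxa <- islands[[1L]]$tip.label
  k <- length(islands)
  probs_mat <- island_prob_matrix(spec, k)
  stick <- rep_len(spec$stickiness, spec$n_chains)
  gens <- seq_len(spec$n_samples) * 10000  # nominal thinned generation stamps

  param_traces <- topo_traces <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    Z <- with_seed_internal(child_seed(spec$seed, ch),
      matrix(stats::rnorm(spec$n_samples * p), ncol = p)) %*% CH
    cols <- lapply(seq_len(p), function(j) {
      ps <- spec$parameters[[j]]
      u <- ar1_filter(Z[, j], ps$rho)
      x <- ps$mean + sqrt(ps$var) * u
      if (!is.null(spec$chain_offsets))
        x <- x + spec$chain_offsets[ch, j] * sqrt(ps$var)
      sl <- if (!is.null(spec$trend)) spec$trend[pn[j]] else NA_real_
      if (!is.na(sl) && sl != 0)
        x <- x + sl * sqrt(ps$var) * seq(0, 1, length.out = spec$n_samples)
      x
    })
    names(cols) <- pn
    param_traces[[ch]] <- parameter_trace(sprintf("run%d", ch), gens, cols)
    sw <- if (!is.null(spec$mode_switch) && spec$mode_switch$chain == ch)
      spec$mode_switch$at else NULL
    topo_traces[[ch]] <- gen_tree_chain(
      taxa, islands, probs = probs_mat[ch, ], stickiness = stick[ch],
      n = spec$n_samples, seed = child_seed(spec$seed, 100L + ch),
      chain_id = sprintf("run%d", ch), switch_at = sw)
  }
  acc <- with_seed_internal(child_seed(spec$seed, 7L), {
    mv <- c("ExtSPR", "ExtTBR", "NNI", "ParsSPR", "Nodeslider",
            "Multiplier", "Dirichlet")
    move_acceptance(stats::setNames(round(stats::runif(length(mv), 0.1, 0.6), 3),
                                    mv),
                    round(stats::runif(1L, 0.2, 0.8), 3))
  })
  rs <- run_set(sprintf("synthetic_%d", spec$seed), param_traces, topo_traces,
                n_taxa = length(taxa), n_characters = spec$n_characters,
                acceptance = acc)
  attr(rs, "ground_truth") <- ground_truth(spec, islands, probs_mat)
  rs
}

# Default island probabilities: ranked, with the dominant island ahead
# of the rest (p_i proportional to k - i + 1). A posterior split evenly
# over islands is the degenerate case for split-frequency correlation,
# not the typical one.
island_prob_matrix <- function(spec, k) {
  ip <- spec$island_probs
  if (is.null(ip)) ip <- (k:1) / sum(k:1)
  if (is.matrix(ip)) {
    stopifnot(nrow(ip) == spec$n_chains, ncol(ip) == k)
    pm <- ip
  } else {
    stopifnot(length(ip) == k)
    pm <- matrix(ip, spec$n_chains, k, byrow = TRUE)
  }
  if (any(abs(rowSums(pm) - 1) > 1e-8)) stop("island probabilities must sum to 1")
  pm
}

# Analytic ground truth for a spec: true per-parameter ESS, stationary
# per-chain split frequencies, and the large-n expected ASDSF (mean of
# per-split across-chain SDs of the stationary frequencies).
ground_truth <- function(spec, islands, probs_mat) {
  true_ess <- vapply(spec$parameters, function(ps)
    spec$n_samples * (1 - ps$rho) / (1 + ps$rho), numeric(1L))
  keysets <- lapply(islands, decompose_splits)
  splits <- sort(unique(unlist(keysets)))
  member <- vapply(keysets, function(ks) splits %in% ks,
                   logical(length(splits)))
  member <- matrix(member, nrow = length(splits))
  exp_freq <- member %*% t(probs_mat)  # splits x chains
  rownames(exp_freq) <- splits
  exp_asdsf <- if (ncol(exp_freq) >= 2L)
    mean(apply(exp_freq, 1L, stats::sd)) else NA_real_
  list(true_ess = true_ess,
       expected_split_freq = exp_freq,
       expected_asdsf = exp_asdsf,
       true_topo_ess = spec$n_samples * (1 - spec$stickiness) /
         (1 + spec$stickiness))
}

#' Generate a survey cohort with planted effects
#'
#' Builds a table of per-analysis diagnostics and data-set features for
#' regression and congruence testing. Features are drawn from realistic
#' ranges (25-250 taxa; a few hundred to a few thousand characters);
#' ESS-family diagnostics follow a planted linear model in the features
#' plus Gaussian noise, and the remaining diagnostics are drawn from
#' right-skewed null distributions that straddle their thresholds, so a
#' cohort contains both passing and failing analyses.
#'
#' @param n_analyses Number of analyses (rows), at least 20.
#' @param effects Named list of planted effects. `ess` and `topo_ess`
#'   are named vectors with any of `intercept`, `n_taxa`,
#'   `n_characters`, `tl_per_branch` (raw-scale slopes); `ess_sd` and
#'   `topo_ess_sd` set the residual SDs. Defaults: intercepts 2000 and
#'   1500, all slopes 0, SDs 300 and 400.
#' @param seed RNG seed (required).
#' @return A data frame (class `survey_table`) with one row per
#'   analysis.
#' @export
gen_survey_cohort <- function(n_analyses, effects = list(), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is_count(n_analyses), n_analyses >= 20L)
  eff_ess <- effects$ess %||% c(intercept = 2000)
  eff_topo <- effects$topo_ess %||% c(intercept = 1500)
  ess_sd <- effects$ess_sd %||% 300
  topo_sd <- effects$topo_ess_sd %||% 400
  lin <- function(eff, feats) {
    out <- rep(eff[["intercept"]] %||% 0, nrow(feats))
    for (nm in setdiff(names(eff), "intercept"))
      out <- out + eff[[nm]] * feats[[nm]]
    out
  }
  with_seed_internal(seed, {
    feats <- data.frame(
      n_taxa = sample(25:250, n_analyses, replace = TRUE),
      n_characters = sample(300:3000, n_analyses, replace = TRUE),
      tl_per_branch = stats::rlnorm(n_analyses, log(0.05), 0.5))
    params <- c("LnL", "LnPr", "TL", "alpha", "pinvar")
    ess_cols <- lapply(params, function(p)
      lin(eff_ess, feats) + stats::rnorm(n_analyses, 0, ess_sd))
    names(ess_cols) <- paste0("ess_", params)
    psrf_cols <- lapply(c("TL", "alpha", "pinvar"), function(p)
      1 + abs(stats::rnorm(n_analyses, 0, 0.01)))
    names(psrf_cols) <- paste0("psrf_", c("TL", "alpha", "pinvar"))
    out <- cbind(
      data.frame(analysis_id = sprintf("a%04d", seq_len(n_analyses))),
      feats,
      as.data.frame(ess_cols),
      data.frame(topo_ess = lin(eff_topo, feats) +
                   stats::rnorm(n_analyses, 0, topo_sd),
                 asdsf = stats::rlnorm(n_analyses, log(0.012), 1),
                 split_corr = pmax(0, 1 - abs(stats::rnorm(n_analyses, 0, 0.05)))),
      as.data.frame(psrf_cols),
      data.frame(accept_ExtSPR = stats::runif(n_analyses, 0.05, 0.5),
                 accept_ExtTBR = stats::runif(n_analyses, 0.05, 0.5),
                 accept_NNI = stats::runif(n_analyses, 0.1, 0.6),
                 accept_ParsSPR = stats::runif(n_analyses, 0.05, 0.5),
                 accept_Nodeslider = stats::runif(n_analyses, 0.1, 0.7),
                 swap_acceptance = stats::runif(n_analyses, 0.2, 0.8)))
    class(out) <- c("survey_table", class(out))
    out
  })
}
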