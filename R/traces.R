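#' Parameter trace for one MCMC chain
#'
#' Container for the generation-indexed continuous samples of one cold
#' chain: log likelihood (LnL), log prior (LnPr), tree length (TL), GTR
#' exchangeabilities, base frequencies, gamma shape (alpha), proportion
#' of invariable sites (pinvar), kappa, and any other sampled scalar.
#'
#' @param chain_id Identifier for the chain (character scalar).
#' @param generations Strictly increasing integer vector of generation
#'   indices, one per retained sample.
#' @param columns Named list (or data frame) of numeric vectors, one per
#'   sampled quantity, each the same length as `generations`.
#' @return An object of class `parameter_trace` with elements
#'   `chain_id`, `generations`, `columns` (a data frame) and
#'   `n_samples`.
#' @seealso [read_p_file()], [apply_burnin()], [thin_trace()]
#' @export
parameter_trace <- function(chain_id, generations, columns) {
  stopifnot(length(chain_id) == 1L)
  generations <- as.numeric(generations)
  if (anyNA(generations) || is.unsorted(generations, strictly = TRUE))
    stop("generations must be strictly increasing")
  columns <- as.data.frame(columns, check.names = FALSE)
  if (anyDuplicated(names(columns)))
    stop("parameter names must be unique")
  if (nrow(columns) != length(generations))
    stop("all columns must have one value per generation")
  if (!all(vapply(columns, is.numeric, logical(1L))))
    stop("all parameter columns must be numeric")
  structure(
    list(chain_id = as.character(chain_id),
         generations = generations,
         columns = columns,
         n_samples = length(generations)),
    class = "parameter_trace")
}

#' Topology trace for one MCMC chain
#'
#' Ordered tree samples from one chain over a fixed taxon set. Trees are
#' stored unrooted: all split-based diagnostics are invariant to the
#' root, and MrBayes analyses of the kind diagnosed here are unrooted.
#'
#' @param chain_id Identifier for the chain.
#' @param taxa Ordered character vector of taxon labels.
#' @param trees List of `phylo` objects (or a `multiPhylo`); every
#'   tree's leaf set must equal `taxa`.
#' @return An object of class `topology_trace` with elements
#'   `chain_id`, `taxa`, `trees`, `n_samples`.
#' @export
topology_trace <- function(chain_id, taxa, trees) {
  stopifnot(length(chain_id) == 1L)
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon label")
  if (length(trees) == 0L) stop("topology trace must contain at least one tree")
  trees <- unclass(trees)
  idx <- attr(trees, "phyloconv_index")
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) stop("trees must be phylo objects")
    if (!setequal(tr$tip.label, taxa))
      stop(sprintf("tree %d leaf set does not match taxa", i))
  }
  trees <- lapply(trees, function(tr) if (ape::is.rooted(tr)) ape::unroot(tr) else tr)
  attr(trees, "phyloconv_index") <- idx
  structure(
    list(chain_id = as.character(chain_id),
         taxa = taxa,
         trees = trees,
         n_samples = length(trees)),
    class = "topology_trace")
}

#' Paired parameter and topology traces for one analysis
#'
#' One analysis unit: the cold chains of 2-4 independent
#' Metropolis-coupled runs, each contributing a parameter trace and a
#' matching topology trace, plus data-set features.
#'
#' @param analysis_id Identifier for the analysis.
#' @param param_traces List of [parameter_trace()] objects (2-4).
#' @param topo_traces List of [topology_trace()] objects paired
#'   one-to-one with `param_traces` by `chain_id`.
#' @param n_taxa,n_characters Data-set dimensions (counts).
#' @param acceptance Optional [move_acceptance()] object.
#' @return An object of class `run_set`.
#' @export
run_set <- function(analysis_id, param_traces, topo_traces,
                    n_taxa = NULL, n_characters = NULL, acceptance = NULL) {
  stopifnot(is.list(param_traces), is.list(topo_traces))
  if (length(param_traces) != length(topo_traces))
    stop("param and topo traces must be paired one-to-one")
  pid <- unname(vapply(param_traces, function(x) x$chain_id, character(1L)))
  tid <- unname(vapply(topo_traces, function(x) x$chain_id, character(1L)))
  if (!identical(sort(pid), sort(tid)))
    stop("param and topo traces must share chain ids")
  topo_traces <- topo_traces[match(pid, tid)]
  ns <- c(vapply(param_traces, function(x) x$n_samples, numeric(1L)),
          vapply(topo_traces, function(x) x$n_samples, numeric(1L)))
  if (length(unique(ns)) != 1L)
    stop("all traces must have the same number of samples")
  if (is.null(n_taxa)) n_taxa <- length(topo_traces[[1L]]$taxa)
  structure(
    list(analysis_id = as.character(analysis_id),
         param_traces = param_traces,
         topo_traces = topo_traces,
         n_taxa = n_taxa,
         n_characters = n_characters,
         acceptance = acceptance),
    class = "run_set")
}

#' Move acceptance proportions
#'
#' Acceptance proportions for MCMC proposal mechanisms, plus the
#' cold/first-heated chain swap acceptance used to guide Metropolis
#' coupling temperature adjustment.
#'
#' @param moves Named numeric vector of acceptance proportions in
#'   \eqn{[0,1]}. Names are normalised against the usual MrBayes move
#'   vocabulary (ExtSPR, ExtTBR, NNI, ParsSPR, Nodeslider, plus
#'   parameter moves such as Multiplier and Dirichlet).
#' @param swap_acceptance Proportion of accepted swaps between the cold
#'   and first heated chain, in \eqn{[0,1]} (or `NA`).
#' @return An object of class `move_acceptance`.
#' @export
move_acceptance <- function(moves, swap_acceptance = NA_real_) {
  moves <- unlist(moves)
  if (length(moves) && (is.null(names(moves)) || any(!nzchar(names(moves)))))
    stop("moves must be named")
  if (any(moves < 0 | moves > 1, na.rm = TRUE))
    stop("acceptance proportions must lie in [0, 1]")
  if (!is.na(swap_acceptance) && (swap_acceptance < 0 || swap_acceptance > 1))
    stop("swap acceptance must lie in [0, 1]")
  names(moves) <- normalize_move_names(names(moves))
  structure(list(moves = moves, swap_acceptance = as.numeric(swap_acceptance)),
            class = "move_acceptance")
}

# Canonical capitalisation for known MrBayes move names.
move_vocabulary <- c("ExtSPR", "ExtTBR", "NNI", "ParsSPR", "Nodeslider",
                     "Multiplier", "Slider", "Dirichlet", "TLMultiplier",
                     "Beta", "UniformPi")

normalize_move_names <- function(x) {
  hit <- match(tolower(x), tolower(move_vocabulary))
  ifelse(is.na(hit), x, move_vocabulary[hit])
}

#' @export
print.parameter_trace <- function(x, ...) {
  cat(sprintf("parameter_trace '%s': %d samples x %d parameters (%s)\n",
              x$chain_id, x$n_samples, ncol(x$columns),
              paste(names(x$columns), collapse = ", ")))
  invisible(x)
}

#' @export
print.topology_trace <- function(x, ...) {
  cat(sprintf("topology_trace '%s': %d trees on %d taxa\n",
              x$chain_id, x$n_samples, length(x$taxa)))
  invisible(x)
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf("run_set '%s': %d chains, %d samples, %d taxa\n",
              x$analysis_id, length(x$param_traces),
              x$param_traces[[1L]]$n_samples, x$n_taxa))
  invisible(x)
}
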