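# Bipartition machinery: canonical split keys, split-frequency tables,
# Robinson-Foulds distances, consensus and maximum clade credibility
# trees, and tree-level features. Splits are represented by a canonical
# key: the comma-joined, sorted labels on the side of the bipartition
# containing the alphabetically first taxon. This orientation is unique
# per bipartition, so keys hash identically across chains.

#' Decompose an unrooted tree into its nontrivial splits
#'
#' Enumerates the bipartitions induced by the internal edges of a tree.
#' Trivial splits (a single taxon against the rest) are excluded; an
#' unrooted binary tree on n taxa yields n - 3 splits and a star tree
#' yields none. Rooted trees are unrooted first.
#'
#' @param tree A `phylo` object.
#' @param taxa Optional taxon vector the tree must match (error
#'   otherwise); defaults to the tree's own leaf set.
#' @return Character vector of canonical split keys (see
#'   [split_members()]).
#' @export
decompose_splits <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(taxa) && !setequal(tree$tip.label, taxa))
    stop("tree leaf set does not match taxa")
  sorted_taxa <- sort(tree$tip.label)
  memb <- split_membership(tree, sorted_taxa)
  if (is.null(memb)) return(character())
  vapply(seq_len(nrow(memb)), function(i)
    paste(sorted_taxa[memb[i, ]], collapse = ","), character(1L))
}

# Logical matrix of canonical split memberships (rows = internal edges,
# columns = sorted taxa, TRUE marks the side holding the first taxon);
# NULL when the tree has no internal edge.
split_membership <- function(tree, sorted_taxa) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- length(tr$tip.label)
  if (n < 4L) return(NULL)
  tr <- ape::reorder.phylo(tr, "postorder")
  nn <- max(tr$edge)
  memb <- matrix(FALSE, nn, n)
  memb[cbind(seq_len(n), match(tr$tip.label, sorted_taxa))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    memb[p, ] <- memb[p, ] | memb[ch, ]
  }
  internal <- tr$edge[, 2L] > n
  if (!any(internal)) return(NULL)
  sides <- memb[tr$edge[internal, 2L], , drop = FALSE]
  sz <- rowSums(sides)
  keep <- pmin(sz, n - sz) >= 2L
  sides <- sides[keep, , drop = FALSE]
  if (!nrow(sides)) return(NULL)
  flip <- !sides[, 1L]
  sides[flip, ] <- !sides[flip, , drop = FALSE]
  unique(sides)
}

#' Taxa on the stored side of a split key
#' @param key A canonical split key as returned by [decompose_splits()].
#' @return Character vector of taxon labels.
#' @export
split_members <- function(key) strsplit(key, ",", fixed = TRUE)[[1L]]

# Per-sample topology identities for a trace: integer id per tree plus
# the split-key set of each unique topology. Uses the index planted by
# the synthetic generator when present; otherwise deduplicates by object
# identity (cheap when samples repeat topologies) and falls back to
# keying every tree.
trace_topo_ids <- function(trace, max_identity_unique = 64L) {
  idx <- attr(trace$trees, "phyloconv_index")
  if (!is.null(idx)) {
    keysets <- lapply(idx$unique_trees, decompose_splits, taxa = trace$taxa)
    return(list(ids = idx$ids, keysets = keysets))
  }
  trees <- trace$trees
  uniq <- list()
  ids <- integer(length(trees))
  for (i in seq_along(trees)) {
    hit <- 0L
    for (j in seq_along(uniq)) {
      if (identical(trees[[i]], uniq[[j]])) { hit <- j; break }
    }
    if (!hit) {
      if (length(uniq) >= max_identity_unique) { ids <- NULL; break }
      uniq[[length(uniq) + 1L]] <- trees[[i]]
      hit <- length(uniq)
    }
    ids[[i]] <- hit
  }
  if (!is.null(ids)) {
    keysets <- lapply(uniq, decompose_splits, taxa = trace$taxa)
    return(list(ids = ids, keysets = keysets))
  }
  # distinct objects throughout: key every tree, then collapse topologies
  keys_all <- lapply(trees, decompose_splits, taxa = trace$taxa)
  sig <- vapply(keys_all, function(k) paste(sort(k), collapse = ";"), character(1L))
  usig <- unique(sig)
  ids <- match(sig, usig)
  keysets <- keys_all[match(usig, sig)]
  list(ids = ids, keysets = keysets)
}

#' Split-frequency table across chains
#'
#' Tabulates, for every bipartition observed in any chain, the
#' within-chain occurrence frequency (count / number of samples). A
#' split absent from a chain scores 0 there.
#'
#' @param traces A [topology_trace()] or list of them sharing a taxon
#'   set.
#' @return An object of class `split_freq_table`: list with `taxa`,
#'   `splits` (canonical keys), `freq` (splits x chains matrix),
#'   `n_chains`, `chain_ids`.
#' @export
split_frequencies <- function(traces) {
  if (inherits(traces, "topology_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  taxa <- traces[[1L]]$taxa
  for (tr in traces) {
    if (!inherits(tr, "topology_trace")) stop("expected topology traces")
    if (!setequal(tr$taxa, taxa)) stop("traces must share a taxon set")
    if (tr$n_samples == 0L) stop("empty topology trace")
  }
  per_chain <- lapply(traces, function(tr) {
    tid <- trace_topo_ids(tr)
    counts <- tabulate(tid$ids, nbins = length(tid$keysets))
    tab <- new.env(parent = emptyenv())
    for (j in seq_along(tid$keysets)) {
      for (k in tid$keysets[[j]]) {
        tab[[k]] <- (if (is.null(tab[[k]])) 0 else tab[[k]]) + counts[[j]]
      }
    }
    stats::setNames(unlist(as.list(tab)) / tr$n_samples,
                    names(as.list(tab)))
  })
  all_splits <- sort(unique(unlist(lapply(per_chain, names))))
  freq <- vapply(per_chain, function(f) {
    v <- f[all_splits]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(all_splits)))
  freq <- matrix(freq, nrow = length(all_splits),
                 dimnames = list(all_splits,
                                 vapply(traces, `[[`, character(1L), "chain_id")))
  structure(list(taxa = sort(taxa), splits = all_splits, freq = freq,
                 n_chains = length(traces),
                 chain_ids = colnames(freq)),
            class = "split_freq_table")
}

#' @export
print.split_freq_table <- function(x, ...) {
  cat(sprintf("split_freq_table: %d splits x %d chains on %d taxa\n",
              length(x$splits), x$n_chains, length(x$taxa)))
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the nontrivial bipartitions of two
#' trees on the same taxa. The normalized variant divides by the
#' pair-specific maximum (the total number of splits in both trees),
#' which remains meaningful for polytomous consensus trees; two trees
#' sharing no splits then have distance 1.
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @param normalized Return the normalized distance?
#' @return A nonnegative number; 0 for identical topologies.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share a taxon set")
  s1 <- decompose_splits(t1)
  s2 <- decompose_splits(t2)
  rf_from_keys(s1, s2, normalized)
}

rf_from_keys <- function(s1, s2, normalized = FALSE) {
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) return(d)
  mx <- length(s1) + length(s2)
  if (mx == 0L) return(0)
  d / mx
}

# Pooled split frequencies over one or more traces (counts over the
# union of all samples), used by consensus and MCC construction.
pooled_split_freq <- function(traces) {
  if (inherits(traces, "topology_trace")) traces <- list(traces)
  tab <- split_frequencies(traces)
  n <- vapply(traces, `[[`, numeric(1L), "n_samples")
  w <- n / sum(n)
  pooled <- as.vector(tab$freq %*% w)
  stats::setNames(pooled, tab$splits)
}

#' Majority-rule consensus tree
#'
#' Builds the consensus topology containing exactly the splits whose
#' pooled (across-chain) frequency is at least `threshold`. Thresholds
#' of at least 0.5 guarantee pairwise compatibility, so the result is a
#' (possibly polytomous) tree; split frequencies are recorded as node
#' labels.
#'
#' @param traces A [topology_trace()] or list of them.
#' @param threshold Minimum pooled split frequency, in \eqn{[0.5, 1]}.
#' @return A `phylo` object with node labels giving each retained
#'   split's pooled frequency.
#' @export
consensus_tree <- function(traces, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0.5 || threshold > 1)
    stop("threshold must lie in [0.5, 1]: majority rule does not guarantee compatibility below 0.5")
  pooled <- pooled_split_freq(traces)
  keep <- pooled[pooled >= threshold]
  taxa <- if (inherits(traces, "topology_trace")) traces$taxa else traces[[1L]]$taxa
  build_tree_from_splits(names(keep), unname(keep), sort(taxa))
}

# Construct a phylo from a compatible split set; `freqs` become node
# labels. Views each split as the clade on the side NOT containing the
# first sorted taxon, nests clades by containment, and emits newick.
build_tree_from_splits <- function(keys, freqs, taxa) {
  clades <- lapply(keys, function(k) setdiff(taxa, split_members(k)))
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]
  freqs <- freqs[ord]
  # children[[i]]: clades nested directly under clade i (0 = root)
  parent <- integer(length(clades))
  for (i in seq_along(clades)) {
    parent[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (all(clades[[i]] %in% clades[[j]])) parent[i] <- j  # smallest container
    }
  }
  taxon_parent <- vapply(taxa, function(tx) {
    best <- 0L
    for (j in seq_along(clades)) if (tx %in% clades[[j]]) best <- j
    best
  }, integer(1L))
  emit <- function(node) {
    kids_c <- which(parent == node)
    kids_t <- taxa[taxon_parent == node]
    parts <- c(vapply(kids_c, emit, character(1L)), kids_t)
    if (node == 0L) sprintf("(%s);", paste(parts, collapse = ","))
    else sprintf("(%s)%g", paste(parts, collapse = ","), freqs[[node]])
  }
  tr <- ape::read.tree(text = emit(0L))
  if (ape::is.rooted(tr) && length(tr$tip.label) > 2L) tr <- ape::unroot(tr)
  tr
}

#' Maximum clade credibility tree of a sample
#'
#' Scores every sampled topology by the sum of the logarithms of its
#' splits' pooled frequencies and returns the best-scoring sampled
#' topology. Scores use unrooted split frequencies (not rooted clade
#' frequencies), consistent with unrooted analyses. Ties are broken by
#' first occurrence in the sample.
#'
#' @param traces A [topology_trace()] or list of them.
#' @return The winning sampled tree (`phylo`), with attributes
#'   `log_clade_credibility` and `first_index`.
#' @export
mcc_tree <- function(traces) {
  if (inherits(traces, "topology_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  pooled <- pooled_split_freq(traces)
  best <- NULL
  best_score <- -Inf
  best_pos <- Inf
  pos0 <- 0L
  for (tr in traces) {
    tid <- trace_topo_ids(tr)
    first_pos <- pos0 + vapply(seq_along(tid$keysets), function(j)
      which(tid$ids == j)[[1L]], integer(1L))
    scores <- vapply(tid$keysets, function(ks)
      if (length(ks)) sum(log(pooled[ks])) else 0, numeric(1L))
    for (j in seq_along(scores)) {
      if (scores[[j]] > best_score + 1e-12 ||
          (abs(scores[[j]] - best_score) <= 1e-12 && first_pos[[j]] < best_pos)) {
        best_score <- scores[[j]]
        best_pos <- first_pos[[j]]
        best <- tr$trees[[which(tid$ids == j)[[1L]]]]
      }
    }
    pos0 <- pos0 + tr$n_samples
  }
  attr(best, "log_clade_credibility") <- best_score
  attr(best, "first_index") <- best_pos
  best
}

#' Average branch length of a tree
#'
#' Total tree length divided by the number of branches (TL/branch), a
#' data-set feature used in the survey regressions.
#'
#' @param tree A `phylo` with branch lengths.
#' @return The mean branch length.
#' @export
tl_per_branch <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  mean(tree$edge.length)
}
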