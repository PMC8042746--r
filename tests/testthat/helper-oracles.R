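# Independent oracles and fixture builders used across test files.
# The oracles deliberately avoid the package's own code paths: splits
# come from phangorn, autocorrelations from direct summation.

library(ape)

# --- trees ---------------------------------------------------------------

tree_of <- function(txt) ape::read.tree(text = txt)

# all 15 unrooted binary 5-taxon topologies
all_five_taxon_trees <- function() {
  trs <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  lapply(seq_along(trs), function(i) trs[[i]])
}

# canonical split keys computed independently through phangorn
oracle_splits <- function(tree) {
  sp <- phangorn::as.splits(tree)
  labs <- attr(sp, "labels")
  m <- as.matrix(sp)
  n <- length(labs)
  first <- sort(labs)[1L]
  keys <- character(0)
  for (i in seq_len(nrow(m))) {
    side <- labs[m[i, ] == 1]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!first %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2, normalized = FALSE) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) return(d)
  mx <- length(s1) + length(s2)
  if (mx == 0) 0 else d / mx
}

# per-chain split frequencies by explicit enumeration
oracle_chain_freqs <- function(trees) {
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (k in oracle_splits(tr)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
  }
  l <- as.list(counts)
  if (!length(l)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(unlist(l), names(l)) / length(trees)
}

# brute-force ASDSF over a list of tree lists (one per chain)
oracle_asdsf <- function(chains, min_freq, divisor = "sample") {
  freqs <- lapply(chains, oracle_chain_freqs)
  splits <- sort(unique(unlist(lapply(freqs, names))))
  f <- sapply(freqs, function(fr) {
    v <- fr[splits]; v[is.na(v)] <- 0; unname(v)
  })
  f <- matrix(f, nrow = length(splits))
  keep <- apply(f >= min_freq, 1, any)
  f <- f[keep, , drop = FALSE]
  if (!nrow(f)) return(0)
  m <- ncol(f)
  sds <- apply(f, 1, stats::sd)
  if (divisor == "population") sds <- sds * sqrt((m - 1) / m)
  mean(sds)
}

# --- scalar traces -------------------------------------------------------

# direct-summation autocorrelation (divisor n), no stats::acf
oracle_autocorr <- function(x, k) {
  n <- length(x); m <- mean(x)
  c0 <- sum((x - m)^2) / n
  sum((x[seq_len(n - k)] - m) * (x[(k + 1):n] - m)) / n / c0
}

# initial-positive-sequence ESS by direct summation
oracle_ess <- function(x) {
  n <- length(x)
  tau <- 1
  k <- 1L
  while (k < n) {
    r <- oracle_autocorr(x, k)
    if (r <= 0) break
    tau <- tau + 2 * r
    k <- k + 1L
  }
  list(ess = n / tau, act = tau)
}

# four-taxon island fixtures used in several files
island_ab_cd <- function() tree_of("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
island_ac_bd <- function() tree_of("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")

# topology_trace from a plain list of trees
trace_of <- function(trees, chain_id = "c1") {
  taxa <- trees[[1L]]$tip.label
  topology_trace(chain_id, taxa, trees)
}
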