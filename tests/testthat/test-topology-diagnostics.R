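# Hand-computed two-chain fixture: chain 1 samples only AB|CD, chain 2
# is an even mixture of AB|CD and AC|BD, so each included split has
# per-chain frequencies {1.0, 0.5} or {0.0, 0.5}; both have SD 0.3536
# with the sample (m - 1) divisor.
asdsf_fixture <- function() {
  ab <- island_ab_cd(); ac <- island_ac_bd()
  split_frequencies(list(
    trace_of(rep(list(ab), 10), "c1"),
    trace_of(c(rep(list(ab), 5), rep(list(ac), 5)), "c2")))
}

test_that("ASDSF reproduces the hand-computed two-chain value", {
  tab <- asdsf_fixture()
  a <- asdsf(tab, min_freq = 0.1)
  expect_equal(a$asdsf, sd(c(1, 0.5)), tolerance = 1e-12)
  expect_equal(a$asdsf, 0.35355339, tolerance = 1e-6)
  expect_equal(a$n_splits_included, 2L)

  # raising min_freq to 0.6 keeps only AB|CD; the mean SD is unchanged
  a2 <- asdsf(tab, min_freq = 0.6)
  expect_equal(a2$n_splits_included, 1L)
  expect_equal(a2$asdsf, 0.35355339, tolerance = 1e-6)

  # population divisor variant
  a3 <- asdsf(tab, min_freq = 0.1, sd_divisor = "population")
  expect_equal(a3$asdsf, 0.25, tolerance = 1e-12)
})

test_that("ASDSF is zero for identically distributed chains and errors on one chain", {
  ab <- island_ab_cd()
  tab <- split_frequencies(list(trace_of(rep(list(ab), 8), "c1"),
                                trace_of(rep(list(ab), 8), "c2")))
  expect_equal(asdsf(tab)$asdsf, 0)
  expect_error(asdsf(split_frequencies(trace_of(rep(list(ab), 8)))),
               "two chains")
})

test_that("ASDSF matches the brute-force enumeration oracle on random fixtures", {
  set.seed(81)
  for (rep in 1:6) {
    n_taxa <- sample(4:6, 1)
    n_chains <- sample(2:4, 1)
    isl <- random_islands(n_taxa, sample(2:3, 1), seed = 500 + rep)
    chains <- lapply(seq_len(n_chains), function(ch)
      gen_tree_chain(isl[[1]]$tip.label, isl,
                     probs = NULL, stickiness = runif(1, 0, 0.5),
                     n = sample(10:50, 1), seed = 600 + 10 * rep + ch,
                     chain_id = paste0("c", ch)))
    tab <- split_frequencies(chains)
    for (mf in c(0, 0.1, 0.5)) {
      got <- suppressWarnings(asdsf(tab, min_freq = mf)$asdsf)
      want <- oracle_asdsf(lapply(chains, `[[`, "trees"), mf)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("ASDSF is invariant to chain order and stricter inclusion is monotone", {
  tab <- asdsf_fixture()
  tab_rev <- structure(list(taxa = tab$taxa, splits = tab$splits,
                            freq = tab$freq[, 2:1], n_chains = 2L,
                            chain_ids = rev(tab$chain_ids)),
                       class = "split_freq_table")
  expect_equal(asdsf(tab_rev)$asdsf, asdsf(tab)$asdsf)
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.9),
                   function(mf) asdsf(tab, min_freq = mf)$n_splits_included,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ASDSF is invariant under taxon relabelling", {
  isl <- random_islands(6, 2, seed = 82)
  chains <- lapply(1:2, function(ch)
    gen_tree_chain(isl[[1]]$tip.label, isl, n = 40, seed = 83 + ch,
                   chain_id = paste0("c", ch)))
  a1 <- asdsf(split_frequencies(chains))$asdsf
  perm <- setNames(sample(isl[[1]]$tip.label), isl[[1]]$tip.label)
  chains2 <- lapply(chains, function(tr) {
    trees <- lapply(tr$trees, function(t) {
      t$tip.label <- unname(perm[t$tip.label]); t
    })
    topology_trace(tr$chain_id, unname(perm[tr$taxa]), trees)
  })
  a2 <- asdsf(split_frequencies(chains2))$asdsf
  expect_equal(a2, a1, tolerance = 1e-12)
})

test_that("split-frequency correlation has the documented extremes", {
  ab <- island_ab_cd()
  tab_same <- split_frequencies(list(trace_of(rep(list(ab), 10), "c1"),
                                     trace_of(rep(list(ab), 10), "c2")))
  # identical chains but a single split: correlation undefined
  expect_error(split_freq_correlation(tab_same), "fewer than 2")

  # two splits with swapped frequencies across chains: exactly -1
  ac <- island_ac_bd()
  tab_swap <- split_frequencies(list(
    trace_of(c(rep(list(ab), 9), rep(list(ac), 1)), "c1"),
    trace_of(c(rep(list(ab), 1), rep(list(ac), 9)), "c2")))
  expect_equal(split_freq_correlation(tab_swap, min_freq = 0.1), -1)
})

test_that("chains sharing an island distribution correlate above 0.99", {
  isl <- random_islands(8, 2, seed = 84)
  hits <- vapply(1:20, function(s) {
    chains <- lapply(1:2, function(ch)
      gen_tree_chain(isl[[1]]$tip.label, isl, probs = c(0.6, 0.4),
                     n = 2000, seed = 1000 * s + ch,
                     chain_id = paste0("c", ch)))
    split_freq_correlation(split_frequencies(chains)) > 0.99
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pseudo topological ESS approaches n for iid samples", {
  isl <- random_islands(6, 2, seed = 85)
  meds <- vapply(1:10, function(s)
    topological_ess(gen_tree_chain(isl[[1]]$tip.label, isl, probs = c(0.6, 0.4),
                                   n = 2000, seed = s),
                    method = "pseudo", seed = s)$ess, numeric(1))
  expect_lt(abs(median(meds) - 2000) / 2000, 0.2)
})

test_that("pseudo topological ESS decreases with island stickiness", {
  isl <- random_islands(6, 2, seed = 86)
  med_at <- vapply(c(0, 0.4, 0.8, 0.95), function(s) {
    median(vapply(1:10, function(r)
      topological_ess(gen_tree_chain(isl[[1]]$tip.label, isl,
                                     probs = c(0.6, 0.4), stickiness = s,
                                     n = 3000, seed = 50 * r + 1),
                      method = "pseudo", seed = r)$ess, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_at) < 0))
})

test_that("single-reference pseudo ESS equals the distance-trace ESS", {
  isl <- random_islands(6, 2, seed = 87)
  tt <- gen_tree_chain(isl[[1]]$tip.label, isl, probs = c(0.6, 0.4),
                       n = 500, seed = 88)
  te <- topological_ess(tt, method = "pseudo", n_refs = 1, seed = 89)
  ref <- with(list(), {
    set.seed(89); sample.int(500, 1)
  })
  dtrace <- vapply(tt$trees, function(tr) rf_distance(tr, tt$trees[[ref]]),
                   numeric(1))
  expect_equal(te$ess, ess(dtrace)$ess, tolerance = 1e-9)
  expect_equal(te$n_reference_trees, 1L)
})

test_that("approximate topological ESS tracks the island autocorrelation", {
  isl <- random_islands(6, 2, seed = 90)
  for (s in c(0, 0.6)) {
    meds <- vapply(1:8, function(r)
      topological_ess(gen_tree_chain(isl[[1]]$tip.label, isl,
                                     probs = c(0.6, 0.4), stickiness = s,
                                     n = 4000, seed = 300 + r),
                      method = "approx")$ess, numeric(1))
    true <- 4000 * (1 - s) / (1 + s)
    expect_lt(abs(median(meds) - true) / true, 0.25)
  }
})

test_that("topological ESS errors when every sampled tree is identical", {
  tt <- trace_of(rep(list(island_ab_cd()), 20))
  expect_error(topological_ess(tt), "zero topological variance")
})
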