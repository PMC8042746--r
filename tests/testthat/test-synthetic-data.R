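test_that("AR(1) generator is seeded, stationary and correctly autocorrelated", {
  x1 <- gen_ar1_trace(5000, mean = 2, variance = 4, rho = 0.5, seed = 121)
  x2 <- gen_ar1_trace(5000, mean = 2, variance = 4, rho = 0.5, seed = 121)
  expect_identical(x1, x2)
  expect_false(identical(x1, gen_ar1_trace(5000, 2, 4, 0.5, seed = 122)))

  x0 <- gen_ar1_trace(10000, mean = 3, variance = 1, rho = 0, seed = 123)
  expect_lt(abs(mean(x0) - 3), 4 / sqrt(10000))

  xr <- gen_ar1_trace(20000, rho = 0.9, seed = 124)
  expect_lt(abs(autocorrelation(xr, 1) - 0.9), 0.02)
  expect_equal(attr(xr, "true_ess"), 20000 * 0.1 / 1.9)

  # stationarity: first- and second-half means agree within 4 SEs
  half <- length(xr) / 2
  se <- sd(xr) / sqrt(half * (1 - 0.9) / (1 + 0.9))
  expect_lt(abs(mean(xr[1:half]) - mean(xr[(half + 1):length(xr)])), 4 * se)

  expect_error(gen_ar1_trace(100, rho = 1, seed = 1), "rho")
  expect_error(gen_ar1_trace(100, rho = 0.5), "seed")
})

test_that("tree-island chains hit their stationary frequencies", {
  isl <- random_islands(6, 2, seed = 131)
  taxa <- isl[[1]]$tip.label
  tt1 <- gen_tree_chain(taxa, list(isl[[1]]), n = 30, seed = 132)
  expect_true(all(vapply(tt1$trees, function(tr)
    rf_distance(tr, isl[[1]]) == 0, logical(1))))

  tt <- gen_tree_chain(taxa, isl, probs = c(0.6, 0.4), n = 10000, seed = 133)
  f1 <- mean(attr(tt, "island_index") == 1L)
  expect_lt(abs(f1 - 0.6), 0.02)

  # split frequencies equal island-probability sums
  tab <- split_frequencies(tt)
  shared <- intersect(decompose_splits(isl[[1]]), decompose_splits(isl[[2]]))
  only1 <- setdiff(decompose_splits(isl[[1]]), shared)
  if (length(shared)) expect_equal(unname(tab$freq[shared, 1]),
                                   rep(1, length(shared)))
  expect_lt(max(abs(tab$freq[only1, 1] - f1)), 1e-12)

  expect_identical(attr(gen_tree_chain(taxa, isl, n = 50, seed = 134),
                        "island_index"),
                   attr(gen_tree_chain(taxa, isl, n = 50, seed = 134),
                        "island_index"))
  bad <- ape::rtopology(5, rooted = FALSE)
  expect_error(gen_tree_chain(taxa, list(bad), n = 10, seed = 1), "mismatched")
})

test_that("sticky chains have the two-state Markov run-length behaviour", {
  isl <- random_islands(5, 2, seed = 135)
  s <- 0.95; p <- c(0.5, 0.5)
  tt <- gen_tree_chain(isl[[1]]$tip.label, isl, probs = p, stickiness = s,
                       n = 50000, seed = 136)
  idx <- attr(tt, "island_index")
  runs <- rle(idx)$lengths
  # leave probability per step: (1 - s) * (1 - p_same)
  expected_run <- 1 / ((1 - s) * 0.5)
  expect_lt(abs(mean(runs) - expected_run) / expected_run, 0.1)
  expect_lt(abs(autocorrelation(as.numeric(idx == 1L), 1) - s), 0.03)
})

test_that("run sets carry analytic ground truth", {
  spec <- synthetic_spec(n_chains = 2, n_samples = 500, n_taxa = 6,
                         island_probs = matrix(c(0.5, 0.5, 0.9, 0.1), 2,
                                               byrow = TRUE),
                         seed = 141)
  rs <- gen_runset(spec)
  gt <- attr(rs, "ground_truth")
  expect_named(gt$true_ess, names(default_parameters()))
  expect_equal(unname(gt$true_ess["LnL"]), 500 * 0.7 / 1.3)
  # per-split frequency gap 0.4 between chains -> expected ASDSF 0.4/sqrt(2)
  # over island-specific splits; shared splits contribute 0
  ef <- gt$expected_split_freq
  gaps <- abs(ef[, 1] - ef[, 2])
  expect_true(all(gaps %in% c(0, 0.4)))
  n_specific <- sum(gaps == 0.4)
  expect_equal(gt$expected_asdsf,
               n_specific * (0.4 / sqrt(2)) / nrow(ef), tolerance = 1e-12)
})

test_that("identical per-chain specs pass multichain diagnostics at large n", {
  rs <- gen_runset(synthetic_spec(n_chains = 4, n_samples = 8000, n_taxa = 10,
                                  seed = 142))
  rec <- diagnose_runset(rs, seed = 142)
  expect_true(all(rec$pass[c("asdsf", "psrf", "split_corr")]))
})

test_that("a mean trend depresses the ESS of the affected parameter", {
  spec0 <- synthetic_spec(n_chains = 1, n_samples = 4000, n_taxa = 6, seed = 143)
  spec1 <- synthetic_spec(n_chains = 1, n_samples = 4000, n_taxa = 6,
                          trend = c(TL = 6), seed = 143)
  x0 <- gen_runset(spec0)$param_traces[[1]]$columns$TL
  x1 <- gen_runset(spec1)$param_traces[[1]]$columns$TL
  true <- 4000 * (1 - 0.3) / (1 + 0.3)
  expect_lt(ess(x1)$ess, 0.5 * true)
  expect_gt(ess(x0)$ess, 0.6 * true)
})

test_that("a chain mean offset raises PSRF", {
  off <- matrix(0, 2, 5); off[2, ] <- 3
  rs <- gen_runset(synthetic_spec(n_chains = 2, n_samples = 1000, n_taxa = 6,
                                  chain_offsets = off, seed = 144))
  rec <- diagnose_runset(rs, seed = 144)
  expect_true(all(rec$psrf > 1.5))
  expect_false(rec$pass[["psrf"]])
})

test_that("a mode switch creates between-chain topology disagreement", {
  spec <- synthetic_spec(n_chains = 2, n_samples = 1000, n_taxa = 8,
                         mode_switch = list(chain = 2, at = 0.5), seed = 145)
  rec <- diagnose_runset(gen_runset(spec), seed = 145)
  expect_false(rec$pass[["asdsf"]])
})

test_that("survey cohorts are reproducible with planted effects and sane ranges", {
  t1 <- gen_survey_cohort(60, seed = 151)
  t2 <- gen_survey_cohort(60, seed = 151)
  expect_identical(t1, t2)
  expect_true(all(t1$n_taxa >= 25 & t1$n_taxa <= 250))
  expect_true(all(t1$asdsf > 0))
  expect_true(all(t1$split_corr >= 0 & t1$split_corr <= 1))
  expect_false(anyDuplicated(t1$analysis_id) > 0)
  expect_error(gen_survey_cohort(10, seed = 1), "n_analyses")

  eff <- gen_survey_cohort(400, effects = list(ess = c(intercept = 3000,
                                                       n_taxa = -8)),
                           seed = 152)
  lo <- mean(eff$ess_TL[eff$n_taxa > 200])
  hi <- mean(eff$ess_TL[eff$n_taxa < 75])
  expect_gt(hi - lo, 500)
})

test_that("bundles contain one .p and .t file per chain", {
  rs <- gen_runset(synthetic_spec(n_chains = 4, n_samples = 50, n_taxa = 6,
                                  seed = 153))
  d <- withr::local_tempdir()
  files <- write_mrbayes_bundle(rs, d)
  expect_length(list.files(d, pattern = "[.]p$"), 4)
  expect_length(list.files(d, pattern = "[.]t$"), 4)
  # written split frequencies equal the in-memory ones
  rs2 <- read_mrbayes_bundle(d)
  f1 <- split_frequencies(rs$topo_traces)
  f2 <- split_frequencies(rs2$topo_traces)
  expect_equal(f2$freq[rownames(f1$freq), ], f1$freq, ignore_attr = TRUE)
})
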