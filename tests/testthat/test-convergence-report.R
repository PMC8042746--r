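record_of <- function(ess = c(TL = 500, alpha = 500), topo_ess = 500,
                      asdsf = 0.005, psrf = 1.001, split_corr = 0.99) {
  list(ess = ess, topo_ess = topo_ess, asdsf = asdsf, psrf = psrf,
       split_corr = split_corr)
}

test_that("threshold boundaries follow the documented conventions", {
  th <- thresholds()
  # ESS passes at exactly 200; ASDSF and PSRF fail at their thresholds
  f <- evaluate(record_of(ess = c(TL = 200, alpha = 200), topo_ess = 250,
                          asdsf = 0.009, psrf = 1.01, split_corr = 0.95), th)
  expect_true(all(f))

  f2 <- evaluate(record_of(asdsf = 0.01), th)
  expect_false(f2[["asdsf"]])
  f3 <- evaluate(record_of(psrf = 1.02), th)
  expect_false(f3[["psrf"]])

  # one parameter short of the ESS threshold fails the all-parameters rule
  f4 <- evaluate(record_of(ess = c(TL = 199, alpha = 10000, pinvar = 10000)), th)
  expect_false(f4[["ess"]])

  # split correlation passes at its threshold
  expect_true(evaluate(record_of(split_corr = 0.9), th)[["split_corr"]])
})

test_that("LnL and LnPr are excluded from the ESS pass flag unless requested", {
  rec <- record_of(ess = c(LnL = 50, LnPr = 50, TL = 500, alpha = 500))
  expect_true(evaluate(rec)[["ess"]])
  expect_false(evaluate(rec, include_lnl = TRUE)[["ess"]])
})

test_that("missing diagnostics are indeterminate, never passes", {
  rec <- record_of()
  rec$asdsf <- NULL
  f <- evaluate(rec)
  expect_true(is.na(f[["asdsf"]]))
  rec$split_corr <- NA_real_
  expect_true(is.na(evaluate(rec)[["split_corr"]]))
})

test_that("evaluate is monotone: improving a value never flips pass to fail", {
  th <- thresholds()
  for (ess_v in c(150, 200, 300)) {
    expect_true(evaluate(record_of(ess = c(TL = 300)), th)[["ess"]] >=
                  evaluate(record_of(ess = c(TL = ess_v)), th)[["ess"]] ||
                  ess_v >= 300)
  }
  a_vals <- c(0.05, 0.02, 0.01, 0.005, 0.001)
  flags <- vapply(a_vals, function(a)
    evaluate(record_of(asdsf = a), th)[["asdsf"]], logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("failure binning applies the four rules", {
  th <- thresholds()
  expect_identical(bin_failures(record_of(topo_ess = 150, asdsf = 0.02,
                                          ess = c(LnL = 300, TL = 300)), th),
                   c(3L, 4L))
  expect_identical(bin_failures(record_of(), th), integer(0))
  expect_identical(bin_failures(record_of(topo_ess = 150,
                                          ess = c(LnL = 150, TL = 300)), th),
                   c(1L, 2L))
  # any continuous parameter below threshold -> bin 1, even if LnL passes
  expect_identical(bin_failures(record_of(ess = c(LnL = 300, TL = 100)), th), 1L)
})

test_that("bins are empty exactly when ESS, topological ESS and ASDSF pass", {
  set.seed(91)
  for (i in 1:50) {
    rec <- record_of(ess = c(LnL = runif(1, 50, 400), TL = runif(1, 50, 400)),
                     topo_ess = runif(1, 50, 400),
                     asdsf = runif(1, 0, 0.03))
    f <- evaluate(rec, include_lnl = TRUE)
    bins <- bin_failures(rec)
    expect_identical(length(bins) == 0L,
                     isTRUE(f[["ess"]]) && isTRUE(f[["topo_ess"]]) &&
                       isTRUE(f[["asdsf"]]))
  }
})

test_that("congruence counts match direct enumeration and conserve totals", {
  tab <- gen_survey_cohort(120, seed = 92)
  flags <- evaluate_survey(tab)
  cc <- congruence_counts(flags, "ess", "asdsf")
  expect_equal(sum(cc), 120)
  fa <- !flags$ess; fb <- !flags$asdsf
  expect_equal(unname(cc),
               c(sum(fa & !fb), sum(fb & !fa), sum(fa & fb), sum(!fa & !fb)))

  all_pass <- flags; all_pass[] <- TRUE
  expect_equal(unname(congruence_counts(all_pass, "ess", "psrf")),
               c(0, 0, 0, 120))
  same <- congruence_counts(flags, "topo_ess", "topo_ess")
  expect_equal(unname(same[c("fail_A_only", "fail_B_only")]), c(0, 0))
  expect_error(congruence_counts(flags, "ess", "nope"), "unknown diagnostic")
})

test_that("heating recommendation doubles above 0.5 and halves below", {
  expect_equal(recommend_heating(0.1, 0.8), 0.2)
  expect_equal(recommend_heating(0.1, 0.2), 0.05)
  expect_equal(recommend_heating(0.1, 0.5), 0.1)
  expect_error(recommend_heating(0, 0.5), "positive")
  expect_error(recommend_heating(0.1, 1.2), "swap acceptance")
})

test_that("re-analysis comparison is null for identical runs", {
  rs <- gen_runset(synthetic_spec(n_chains = 2, n_samples = 400, n_taxa = 8,
                                  seed = 93))
  cmp <- compare_reanalysis(rs, rs, seed = 93)
  expect_equal(cmp$delta_failures, 0)
  expect_equal(unname(cmp$rf), c(0, 0, 0))
})

test_that("fixing single-chain ESS failures lowers the failure count by their number", {
  th <- thresholds()
  base <- list(analysis_id = "x", parameters = c("TL", "alpha"),
               ess = matrix(c(300, 300, 300, 300), 2,
                            dimnames = list(c("TL", "alpha"), c("c1", "c2"))),
               psrf = c(TL = 1.0, alpha = 1.0),
               topo_ess = c(c1 = 300, c2 = 300),
               asdsf = 0.005, split_corr = 0.99)
  before <- base
  before$ess["TL", ] <- c(100, 100)     # ESS failure in both chains
  expect_equal(phyloconv:::count_failures(before, th) -
                 phyloconv:::count_failures(base, th), 2)
})

test_that("swapping the majority island moves the 50% consensus", {
  isl <- random_islands(8, 2, seed = 94)
  taxa <- isl[[1]]$tip.label
  mk <- function(p, seed) {
    tts <- lapply(1:2, function(ch)
      gen_tree_chain(taxa, isl, probs = p, n = 400,
                     seed = seed + ch, chain_id = paste0("run", ch)))
    pts <- lapply(1:2, function(ch)
      parameter_trace(paste0("run", ch), 1:400,
                      list(LnL = gen_ar1_trace(400, rho = 0.2, seed = seed + 10 + ch))))
    run_set(paste0("rs", seed), pts, tts)
  }
  cmp <- compare_reanalysis(mk(c(0.8, 0.2), 100), mk(c(0.2, 0.8), 200),
                            seed = 95)
  expect_gt(cmp$rf[["consensus50"]], 0)
})

test_that("diagnose_runset assembles a complete record with pass flags", {
  rs <- gen_runset(synthetic_spec(n_chains = 3, n_samples = 600, n_taxa = 10,
                                  seed = 96))
  rec <- diagnose_runset(rs, seed = 96)
  expect_s3_class(rec, "diagnostics_record")
  expect_equal(dim(rec$ess), c(5, 3))
  expect_length(rec$psrf, 5)
  expect_length(rec$topo_ess, 3)
  expect_named(rec$pass, c("ess", "topo_ess", "asdsf", "psrf", "split_corr"))
  expect_true(all(rec$pass[c("psrf", "split_corr")]))
  expect_equal(rec$n_samples, 450)      # 25% burn-in removed from 600
  expect_true(is.finite(rec$tl_per_branch) && rec$tl_per_branch > 0)
})

test_that("thresholds read from YAML override the defaults", {
  f <- withr::local_tempfile(lines = c("ess_min: 100", "asdsf_max: 0.05"))
  th <- read_thresholds(f)
  expect_equal(th$ess_min, 100)
  expect_equal(th$asdsf_max, 0.05)
  expect_equal(th$psrf_max, 1.02)
  expect_error(thresholds(ess_min = -1), "positive")
})
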