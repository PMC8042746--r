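---
title: "Assessing convergence of Bayesian phylogenetic MCMC with phyloconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing convergence of Bayesian phylogenetic MCMC with phyloconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconv)
```

## The problem

A Bayesian phylogenetic analysis returns samples, not answers: a Markov
chain wanders through tree space and parameter space, and only if it
has left its starting region (burn-in) and mixed long enough do its
samples approximate the posterior. Neither condition is guaranteed for
a finite chain, and tree topology — discrete, high-dimensional, often
multimodal ("tree islands") — is exactly the kind of parameter on which
chains stall without any visible trouble in the continuous traces.
`phyloconv` implements the diagnostics used in practice to detect such
failures, a classifier that applies the conventional thresholds, and a
synthetic-posterior generator with known ground truth so that every
estimator in the package can be checked against analytic values.

The expected input is the output bundle of a MrBayes-style analysis:
per-chain parameter samples (`.p` dialect), per-chain tree samples
(`.t` Nexus dialect with a translate block), and optionally move
acceptance proportions. Only cold chains are diagnosed; heated chains
of a Metropolis-coupled run sample a powered posterior and are never
mixed into diagnostics. All tree handling is unrooted: every statistic
here is a function of bipartitions (splits), which do not depend on a
root, and rooted input is coerced on read.

## Preprocessing: burn-in and thinning

A fixed burn-in fraction (default 0.25) is removed before every
diagnostic; the removed count is `ceiling(fraction * n)`, a
deterministic and conservative convention. Traces can additionally be
thinned to a fixed number of retained samples with an even-spacing rule
that always includes the last sample (`floor(k * n / keep)` for
`k = 1..keep`). The 25% / retain-1,000 combination mirrors common
practice for 10-million-generation analyses. Burn-in fractions are
deliberately expressed in retained-sample units, not generations; when
a protocol states burn-in in generations, divide by the sampling
interval before calling `apply_burnin()`.

## Single-chain diagnostics

**ESS and autocorrelation time.** For a scalar trace of length $n$ with
empirical lag-$k$ autocorrelations $\hat\rho_k$ (biased, divisor-$n$
estimator, the standard spectral choice that keeps the autocovariance
sequence positive definite), the autocorrelation time is
$\tau = 1 + 2\sum_{k=1}^{K}\hat\rho_k$, where $K$ stops before the
first nonpositive $\hat\rho_k$ (initial positive sequence). ESS is
$n/\tau$. This is the estimator family used by Tracer-style tools;
Geyer's initial-monotone truncation of pair sums is available via
`ess(x, method = "monotone")` and typically agrees within a few
percent. No cap at $n$ is applied — ESS slightly above $n$ is honest
estimator noise on near-iid traces, and reports flag it rather than
hide it. On AR(1) input with lag-1 autocorrelation $\rho$ the true
value is $n(1-\rho)/(1+\rho)$; the acceptance checks verify recovery
within 15% of truth at $n = 20{,}000$ for $\rho$ up to 0.9.

**Topological ESS.** Two estimators are provided, and the method used
is recorded in the result because published uses differ. The default
pseudo-ESS draws `n_refs = 10` reference trees uniformly from the
sample (seeded), computes the scalar trace of Robinson–Foulds (RF)
distances to each reference, applies the scalar ESS to each, and
reports the median — the median makes the estimate robust to an
unluckily central reference. The approximate variant estimates a
topological autocorrelation function directly:
$\rho_{\mathrm{topo}}(k) = 1 - D(k)/D_\infty$, with $D(k)$ the mean
squared RF distance between samples $k$ apart and $D_\infty$ its
all-pairs analogue, then applies the same initial-positive-sequence
sum. RF is used as the tree distance in both because it is the
cheapest metric consistent with split-based reasoning;
a run whose trees are all identical has no topological variance and
raises an error rather than reporting a meaningless number.

## Multi-chain diagnostics

**PSRF.** With $m$ chains of length $n$, within-chain variance $W$
(mean of per-chain sample variances) and between-chain component
$B/n$ (variance of the chain means),
$$\mathrm{PSRF} = \sqrt{\frac{\frac{n-1}{n}W + B/n}{W}}.$$
This is the square-root form without degrees-of-freedom correction —
the simplest variant consistent with "ratio of among-chain to
within-chain variance"; the classical extra $B/(mn)$ term is available
by flag since conventions differ across tools. Identical chains give
$\sqrt{(n-1)/n} \approx 1$; chains stuck in different places give
values far above 1 (a 3-SD offset in one of four chains yields
PSRF ≈ 1.8 at $n = 10{,}000$).

**ASDSF.** All bipartitions observed in any chain are enumerated; a
split is included if its within-chain frequency reaches `min_freq`
(default 0.1) in *at least one* chain — the minimum-partition-frequency
semantics implied by the usual 0.1 convention; an "all chains" variant
exists for sensitivity checks. Each included split contributes the
standard deviation of its per-chain frequencies (sample SD, divisor
$m-1$, the MrBayes across-run convention; population SD available),
and ASDSF is the mean of these SDs. Zero included splits is defined as
ASDSF 0 with a warning flag rather than an error, since it occurs
legitimately for near-star posteriors with a high `min_freq`. Note
that even perfectly exchangeable chains have nonzero expected ASDSF of
order $\sqrt{f(1-f)/n}$ per split: at 750 retained samples a split
near frequency 0.5 contributes ≈ 0.018, which is why short,
well-behaved analyses routinely fail the 0.01 threshold while passing
everything else — and why collecting more samples, not changing the
model, is the first remedy for bin-4 failures.

**Split-frequency correlation.** Pearson correlation of the included
splits' frequency vectors between chain pairs, averaged over pairs for
$m > 2$. With only two included splits the statistic degenerates to
±1, and with a posterior split exactly 50/50 between two
non-overlapping islands its sign is a coin flip; the implementation
therefore refuses fewer than two included splits and the generator's
default island probabilities are deliberately asymmetric (see below).

## Classification, binning, congruence, heating

`thresholds()` fixes the conventional cutoffs: ESS and topological ESS
200, ASDSF 0.01, PSRF 1.02, split correlation 0.9. Boundary semantics
are mixed in common usage, so they are fixed here and documented: ESS,
topological ESS and split correlation pass *at* the threshold (≥);
ASDSF and PSRF fail at it (strict <). LnL and LnPr are trace summaries
rather than model parameters; they are excluded from the ESS pass flag
by default (`include_lnl = TRUE` restores them) but they *do* count as
continuous traces for failure bin 1, which is the reading most
consistent with binning "at least one continuous parameter" failures.
The four failure bins are: (1) any continuous-parameter ESS below
threshold; (2) topological ESS below threshold with LnL ESS also
below; (3) topological ESS below threshold with LnL ESS above —
the signature of topology mixing problems invisible to continuous
traces; (4) ASDSF above threshold. A missing diagnostic makes the
corresponding flag indeterminate (`NA`), never a pass.

`congruence_counts()` produces the two-set Venn counts (fail A only /
fail B only / both / neither) used to ask whether diagnostics agree on
which analyses are broken. `recommend_heating()` encodes the coarse
temperature rule: double the Metropolis-coupling temperature when
cold↔heated swap acceptance exceeds 0.5 (chains too similar), halve it
below 0.5 (heated chains wandering unproductively), leave it unchanged
at exactly 0.5. `compare_reanalysis()` totals failed thresholds
(single-chain failures counted per chain, multi-chain ones once per
analysis) before and after a re-run and reports normalized RF
distances between the 50% and 95% consensus trees and MCC trees of
the two run sets.

## Tree-space machinery

Splits are stored canonically: the side of the bipartition containing
the alphabetically first taxon, keyed by its sorted labels, so the
same bipartition hashes identically across chains and label orders.
Consensus trees contain exactly the splits whose pooled (across-chain)
frequency reaches the threshold; thresholds below 0.5 are refused
because compatibility is no longer guaranteed there. The MCC tree is
the *sampled* topology maximizing the sum of log pooled split
frequencies — split (unrooted) frequencies, not rooted clade
frequencies, a deliberate divergence from rooted MCC conventions that
matches unrooted analyses; exact ties go to the earliest-sampled
topology. Normalized RF divides by the pair-specific maximum (the
total split count of both trees), which stays meaningful when
consensus trees are polytomous. Pooled frequencies drive consensus and
MCC construction; per-chain frequencies drive ASDSF — summary trees
describe the combined sample, disagreement measures must not.

## The synthetic generator

`gen_runset()` builds multi-chain posteriors whose convergence
properties are known exactly, which is what makes the test suite and
acceptance checks possible:

- Parameter traces are stationary Gaussian AR(1) processes
  (true ESS $= n(1-\rho)/(1+\rho)$), cross-correlated through a
  Gaussian copula on the innovations — this preserves each marginal's
  autocorrelation (hence its true ESS) while planting correlation
  structure, exactly when the correlated pair shares $\rho$.
- Topology traces follow a sticky island model: stay with probability
  $s$, otherwise draw an island independently. The stationary
  frequency of a split is the total probability of islands containing
  it, and the island indicator has lag-1 autocorrelation $s$, so the
  topological ESS target is $n(1-s)/(1+s)$.
- Pathologies are planted by per-chain mean offsets (in SD units,
  driving PSRF up), linear trends (non-stationarity, driving ESS
  down), per-chain island-probability overrides (driving ASDSF up by a
  computable amount: a frequency gap $g$ between two chains
  contributes $g/\sqrt{2}$ per affected split), stuck chains (a
  degenerate probability vector) and deterministic mode switches.

Defaults are chosen once to emulate a typical thinned four-run
analysis and stay fixed: 4 chains of 1,000 retained samples; 25 taxa;
two tree islands with ranked probabilities (2/3, 1/3) — asymmetric
because an exactly even island split is the degenerate case for
split-frequency correlation, not the typical one; modest residual
autocorrelation ($\rho$ 0.2–0.3, what thinning to every ten-thousandth
generation leaves behind); and built-in LnPr–TL correlation −0.98 with
α–pinvar correlation 0.59, the two strong parameter interactions a
tree-length prior and an I+Γ model induce in real analyses. Branch
lengths are fixed per island (optional lognormal jitter) since
split-based diagnostics ignore them; LnL/LnPr are synthesized traces,
not likelihood computations, because every diagnostic here operates on
traces. `gen_survey_cohort()` generates regression-ready tables with
features in realistic ranges (25–250 taxa) and diagnostics from a
planted linear model plus noise; its null cohorts yield uniform
regression p-values, which the acceptance checks exploit.

What the generator does **not** emulate: actual likelihood surfaces,
within-island branch-length posteriors, Metropolis-coupling dynamics,
or model misspecification. Passing tests show the *estimators* are
correct and calibrated under known truth; they do not certify any
particular empirical analysis, whose pathologies can be richer.

## Numerical choices and problem sizes

Autocorrelations are computed in doubling windows until a truncation
point appears, so cost is $O(n \cdot K)$ rather than $O(n^2)$.
Topological distance traces deduplicate topologies first (by the
generator's planted index when present, by object identity or split
keys otherwise), so RF distances are computed once per pair of unique
topologies. Exact ties in MCC scoring are resolved at $10^{-12}$
tolerance toward the earliest sample. Degenerate inputs error
explicitly: constant traces (zero variance), all-identical tree
samples (zero topological variance), fewer than two included splits
(undefined correlation), constant PCA columns, collinear regression
designs (condition number above $10^{10}$).

The test and acceptance workloads use $n = 20{,}000$ for ESS and
topological-ESS calibration (15–25% tolerance bands at 20 seeds),
$10{,}000 \times 4$ chains over 100 replicates for PSRF coverage,
500-analysis cohorts for classification and congruence, and 100
cohorts of 200 analyses for regression recovery — sizes at which the
median-based checks are stable while the whole suite completes in a
few minutes on one core.

## Known limitations

- The `.p`/`.t` readers target the MrBayes dialects (plus generic TSV
  and newline-delimited newick); BEAST logs, checkpoint files and
  partitioned-model output are out of scope.
- ASDSF inclusion uses the at-least-one-chain rule by default; tools
  differ, and values near the 0.01 threshold can change under the
  all-chains variant — both are exposed.
- The "95% consensus" is implemented as threshold-0.95 majority rule;
  a 95% credible *set* of trees is a different object and is not
  provided.
- Geweke, Heidelberger–Welch and Raftery–Lewis diagnostics are not
  implemented; nor are tree-space visualizations (MDS plots) or SPR /
  quartet / geodesic tree distances.
- ESS variants differ slightly across packages (truncation rules,
  bias corrections); both truncation rules here are documented, but
  neither is asserted to replicate any specific tool bit-for-bit.
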