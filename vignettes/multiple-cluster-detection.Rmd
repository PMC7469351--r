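---
title: "Detecting multiple spatial disease clusters: model, criterion, and Monte Carlo inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multiple spatial disease clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiscan)
```

## The multiple-cluster model

A study space consists of `m` regions with observed case counts
`y_i` and baseline expected counts `mu_i^0 > 0` (typically from indirect
age–sex standardization, so that `sum(mu_i^0) = sum(y_i)` on real data).
Counts are assumed independently Poisson. Given `K` pairwise disjoint
windows `w_1, ..., w_K` — connected sets of regions proposed by a scan —
the rate model is

$$\log \mu_i = \alpha + \sum_{k=1}^K \beta_k z_{ki} + \log \mu_i^0,$$

with `z_ki = 1` when region i belongs to window k. Inside window k the
rate multiplier is `theta_k = exp(alpha + beta_k)`; outside all windows
it is `exp(alpha)`. The null model (`K = 0`) is
`log mu_i = alpha + log mu_i^0`. Hot spots correspond to `beta_k > 0`;
the package does not enforce positivity at the fitting stage (that
would destroy the closed form), but candidates fitted with
`beta_k <= 0` are flagged with a warning, and the information criterion
penalizes them naturally.

Because the design is a partition into K + 1 groups, the MLE is closed
form: each group's fitted rate is its observed/expected ratio, and
`fit_multicluster()` evaluates the *full* Poisson log-likelihood
(including the `log y_i!` terms). The constant matters: the selection
statistic below divides by a criterion value, so all likelihoods must be
on one common scale. The closed form is verified in the test suite
against an independent iteratively-reweighted-least-squares maximizer on
hundreds of random instances.

## The information criterion and RDC

Treating the window configuration `z` as drawn from a selection
distribution `h(z)`, a Laplace approximation of the marginal likelihood
yields, after dropping terms below O(1) in `m`,

$$C(K) = -2\, l(\hat\psi \mid z) - 2 \log h(z) + (K + 1) \log m .$$

With the recommended `h(z) = (1/m)^K` — each window's location chosen
roughly uniformly among `m` positions, appropriate while windows are
small relative to the map — this becomes

$$C(K) = -2\, l(\hat\psi \mid z) + (3K + 1)\log m, \qquad K \ge 1 .$$

The number of clusters is chosen to maximize the relative difference

$$RDC(K) = \frac{C_0 - C(K)}{C_0},$$

with `K_hat = 0` whenever no prefix beats the null (`max RDC <= 0`).
Two conventions required a decision:

* **The null criterion.** `C(K)` is defined for `K >= 1`; for the null
  reference we use the same expression at `K = 0` with `q = 1` parameter
  and an empty selection (`log h = 0`): `C0 = -2 l(alpha_hat^0) + log m`.
  This is the natural continuation of the formula and keeps
  `C(K) - C0` equal to `3K log m` minus twice the likelihood gain.
* **Prefix nesting.** `RDC` is evaluated over prefixes
  `(w_1*, ..., w_K*)` of the sequential scan ordering, not over all
  subsets of candidates: the candidate list is ordered by detection
  strength, and the prefix path is the one the sequential procedure
  actually walks. (Subset search is combinatorial in `kmax` and was
  deliberately not implemented as a default path.)
* **Ties and degeneracy.** Ties in `max RDC` go to the smaller K.
  `C0 <= 0` aborts with a diagnostic rather than being silently
  possible; with full Poisson likelihoods on non-trivial counts,
  `-2 l > 0` holds in practice, and the guard asserts it at run time.

`select_clusters()` also emits `-2 log L`, AIC and BIC traces. These are
for comparison only: on data with one strong planted cluster and noise
candidates they keep decreasing long past the true K (their per-window
penalties, 2 and `log m`, sit below typical noise likelihood gains at
`m` in the hundreds), while `C`, whose per-window penalty is
`3 log m`, attains an interior minimum. The acceptance tests check this
qualitative contrast rather than strict monotonicity of BIC over long
traces, whose late noise gains can fall below `log(m)/2`.

## Candidate generation: the sequential scan

`scp_candidates()` iterates a single-cluster scan: find the most likely
cluster among regions not yet assigned to a previous candidate, attach
it, repeat up to `kmax`, a secondary p-value threshold, or exhaustion.
Previously detected regions are *left out of window membership*; the
study-area totals are not reduced, which keeps each iteration's
statistic on a common scale and makes the candidates disjoint by
construction.

Three window families are provided:

* **circular** (default): for each center region, the nested sets of
  its 1st, 2nd, … nearest regions by centroid distance, up to an
  expected-count cap (`max_fraction`, default 0.5 of the study total —
  the conventional "up to half the population at risk" rule). This
  family is fast (a compiled kernel scans all centers in one pass) and
  is the default for simulation work.
* **flexible**: all connected subsets of each region's
  `neighbor_limit`-nearest neighborhood (default 20) containing the
  center. Exhaustive enumeration is exponential in the neighborhood
  size, so a per-center emission cap guards against blow-ups and logs
  truncation.
* **restricted**: the flexible family restricted to regions whose
  one-sided Poisson mid-p value, `P(X > y) + 0.5 P(X = y)` at mean
  `mu_i^0`, falls below `alpha1` (default 0.2, the conventional choice
  in the restricted-scan literature). This prunes the enumeration
  drastically and scales to larger maps.

**Conditioning.** Scan inference conditions on the observed total: null
replicates are multinomial reallocations of `O = sum(y_i)` with
probabilities proportional to `mu_i^0`, and the scan layer evaluates the
LLR against expectations rescaled so `sum(E_i) = O`. Two consequences
are worth spelling out. First, the statistic becomes invariant to an
overall rate shift — without the rescaling, any dataset whose total
exceeds its baseline expectation (for example, one containing true
clusters) inflates the LLR of *large* windows and can merge distinct
clusters into one huge candidate. Second, the scan LLR of a single
window then equals the multiple-cluster GLM likelihood-ratio for the
same window *exactly*, which the tests assert to 1e-10; the two routes
(direct scan formula versus two GLM fits) are kept independent in code
precisely so this identity is a meaningful cross-check.

**Secondary p-values.** All candidates of one SCP run are compared
against a single set of `replications` null maxima of the full-map scan
(the standard practice of scan software): `p_s` for each candidate is
the Monte Carlo tail probability of its LLR under that distribution,
yielding p-values that are non-decreasing in rank. Deterministic
tie-breaking throughout (maximum LLR, then smaller window, then member
order) makes the whole candidate sequence reproducible bit-for-bit under
a fixed seed.

## Overall significance of the selected model

`overall_test()` computes the observed `T = max_K RDC(K)`, then for each
of `R` multinomial null replicates *regenerates candidates from scratch*
with the same scan configuration and recomputes `T*`; the overall
p-value is `p_M = (1 + #\{T^* \ge T\})/(R + 1)`. Inside replicates the
per-candidate `p_s` Monte Carlo is skipped entirely (with the threshold
set to 1): `T` depends only on the windows and the criterion, and
skipping the inner loop removes a nested simulation, making the test
cost `R` scan runs rather than `R^2`. Whether the reference procedure
regenerates candidates per replicate or refits the observed windows is
genuinely ambiguous; regeneration is the default here because it
reflects the full selection pipeline under the null, and the cheaper,
anti-conservative refitting variant is available behind
`refit_windows = TRUE`.

Because the observed dataset, conditioned on its total, is exchangeable
with the multinomial replicates under the null, the test is exact up to
Monte Carlo discreteness: `P(p_M <= alpha) = floor(alpha (R+1))/(R+1)`.
The acceptance suite measures the empirical size on a null lattice and
`scripts/acceptance.R` recomputes it from scratch (200 null datasets,
R = 99, level 0.05 — sizes chosen so a full run completes on one CPU in
minutes; the reference experiment is the same design at 1000 datasets
and R = 9999).

## The synthetic study design

The built-in scenarios emulate a national disease-mapping study:

* an 18x18 rook-adjacency lattice, `m = 324` regions — the region count
  of the motivating national disease-mapping analysis, whose true
  geography is not redistributable;
* five clusters A–E of sizes 5, 7, 8, 8, 5 (33 cluster regions) with
  cluster-level baseline expectations 1941.88, 772.14, 760.88, 437.49,
  598.06, split equally within each cluster — the within-cluster
  allocation is not dictated by the reference design, and the equal
  split is this package's choice;
* a study total of 333524.31 expected cases, the remainder split equally
  over the 291 background regions;
* per-cluster relative risks by scenario: S1 all 1.0 (null), S2–S4 all
  clusters at 1.5 / 1.3 / 1.2, S5 mixed (1.6, 1.3, 1.4, 1.3, 1.2),
  S6–S7 cluster A only at 1.3 / 1.2. Counts are independent Poisson,
  `y_i ~ Poisson(rr_i mu_i^0)`.

`plant_clusters()` grows clusters from random seeds, disjoint and at
graph distance at least 2 from each other, in two shapes: `"blob"`
(randomized breadth-first accretion, irregular) and `"ball"` (the
regions nearest the seed centroid). The built-in scenarios default to
ball shapes deliberately: all package-level evaluation uses the circular
scan, and a ball cluster is representable by a circular window, so the
evaluation measures the selection-and-testing machinery rather than the
scan-geometry mismatch. The mismatch itself is real and worth knowing
about: with irregular blob clusters the circular scan fragments a
cluster into a core window plus leftover slivers, region-level
sensitivity plateaus below 1, and the selected K counts fragments — the
very phenomenon that motivated flexibly shaped scans. Users studying it
can set `shape = "blob"`.

What the generator does **not** emulate: real administrative geographies
(heterogeneous region sizes and adjacency degree), spatially correlated
baseline rates, overdispersion, or covariate-driven expectations.
Passing simulation tests therefore demonstrate correctness of the
machinery under the stated Poisson design, not performance on any
particular real map.

## Numerical conventions and edge cases

* Canonical region order is file/construction order; ids are opaque
  strings. Distance ties (k-nearest-neighbor adjacency, circular window
  accretion) break by lexicographic id; a window's own center always
  sorts first.
* Regions with zero baseline expectation make the likelihood undefined
  and are removed by `drop_zero_expected()` with a warning, reducing m.
* `x log x` terms at `x = 0` evaluate to 0; a window with zero observed
  cases fits `theta_k = 0` with finite log-likelihood.
* Monte Carlo p-values always take the form `(1 + exceedances)/(R + 1)`
  and live on the grid `{1/(R+1), ..., 1}`.
* All simulation entry points consume R's global RNG stream: a single
  `set.seed()` before a pipeline reproduces it exactly. Replication runs
  sequentially; there is no parallel path whose scheduling could change
  results.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `method` | `"circular"` | window family (`flexible`, `restricted`) |
| `max_fraction` | 0.5 | expected-count cap per circular window, as a fraction of the study total |
| `neighbor_limit` | 20 | neighborhood (max window) size, flexible scans |
| `alpha1` | 0.2 | mid-p eligibility threshold, restricted scan |
| `kmax` | 20 | maximum number of SCP candidates |
| `ps_threshold` | 1.0 | retain candidates while `p_s` does not exceed it |
| `replications` | 999 | Monte Carlo size for `p_s` |
| `R` (overall test) | 999 | Monte Carlo size for `p_M` |

`kmax = 20` with `ps_threshold = 1` retains all candidates up to the
cap, which is the configuration the selection criterion is designed
for: the criterion, not the secondary p-values, decides K. Simulation
defaults in the tests are scaled down (`kmax = 8` on null maps,
`R = 99`, 50–200 datasets) and are documented next to each experiment.

## Known limitations

* The `RR` column of the candidate table is the window SMR
  `O_k / E_k`; the GLM report prints both `theta_k` and
  `theta_k / theta_outside`, which differ once other clusters absorb
  part of the total.
* No overdispersion, spatial random effects, or quasi-likelihood: the
  inferential guarantees assume independent Poisson counts given the
  baseline.
* Low-rate (cold-spot) windows are out of scope; the model requires
  elevated rates and the scan suppresses them.
* The flexible scan's exhaustive enumeration is practical only with
  modest `neighbor_limit` or with the restricted variant; the circular
  kernel is the only path engineered for large Monte Carlo studies.
* Exact reproduction of analyses built on external geographies requires
  their coordinate/adjacency/expectation files; readers of the
  SaTScan-style formats are provided for that purpose.
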