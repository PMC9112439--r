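---
title: "Methods: space-time scan statistics and Bayesian disease mapping in scanmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-time scan statistics and Bayesian disease mapping in scanmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanmap)
```

# The problem

Cancer registries record incident cases at fine geography. Two questions
recur in small-area surveillance: *where and when is incidence elevated
beyond what the local age structure explains*, and *how does the
underlying risk surface evolve over time*. `scanmap` implements a
complete tract-level pipeline for both, exercised end-to-end on a
synthetic registry generator because individual-level registry data are
typically restricted.

The pipeline is: age standardization → internally standardized expected
counts → (a) a Bayesian spatio-temporal relative-risk model and (b) a
cylindrical space–time scan statistic → covariate comparison of cluster
versus non-cluster tracts.

# Age standardization

**Direct standardization** weights age-specific rates by a fixed
standard population. With weights $w_a$ (the 2000 U.S. Standard Million
by default), counts $c_a$ and person-years $p_a$:

$$\text{rate} = 10^5 \times \frac{\sum_a w_a (c_a/p_a)}{\sum_a w_a}.$$

The result is invariant to rescaling all $w_a$; a positive count over a
zero denominator is an error by design, because the registry exclusion
filter (`apply_exclusions()`) removes case cells whose census population
estimate is zero before any rate is formed. The default age scheme has
16 bins (5-year bins to 60–64, then 65–74, 75–84, 85+); 18- and 19-bin
schemes are available because published analyses differ in how elderly
strata are pooled, and the scheme is an explicit argument everywhere
rather than a constant.

**Internal (indirect) standardization** computes, separately per year
$j$, the study-wide age-specific rates
$r_{aj} = \sum_i O_{ija} / \sum_i p_{ija}$ and applies them to each
tract's age structure: $E_{ij} = \sum_a r_{aj}\, p_{ija}$. Two
consequences matter downstream: $\sum_i E_{ij} = \sum_i O_{ij}$ exactly
within every year (tested as an invariant), so standardized incidence
ratios $O/E$ center at 1 and the scan statistic is scale-free.

**Quantile trends.** Tract-level adjusted rates are summarized per year
by empirical quantiles (type-7 linear interpolation, pinned for
reproducibility) with an OLS line through the (year, quantile) points.
A mixed-model quantile regression with tract-level random intercepts
and slopes could model the same trajectories subject-specifically; we
deliberately report the descriptive population-level quantile paths
instead, since those are what registry surveillance reports communicate,
and the OLS slope per year is the headline trend number.

# The spatio-temporal relative-risk model

Observed tract-year counts are modeled as

$$O_{ij} \sim \text{Poisson}(E_{ij}\, RR_{ij}), \qquad
\log RR_{ij} = \alpha + u_i + \beta\, t_j + \delta_{ij},$$

with $t_j$ the centered calendar year (so $\alpha$ is the study-midpoint
log relative risk and $\beta$ a per-year trend), $u_i$ an intrinsic
conditional autoregressive (ICAR) field on the queen-contiguity graph
— each $u_i$ normal around the mean of its neighbours with conditional
variance $\sigma_u^2/d_i$ — and $\delta_{ij}$ iid
$\mathcal N(0, \sigma_\delta^2)$ space–time interaction. The ICAR prior
is improper; identifiability comes from a sum-to-zero constraint,
applied per connected component when the graph is disconnected.
Unstructured tract-level heterogeneity is not modelled separately: at
registry scale the interaction term already absorbs cell-level
overdispersion, and a convolution model would not be identifiable from
the tract-year counts the pipeline ingests.

Priors: $\alpha, \beta \sim \mathcal N(0, 10^2)$ (diffuse on the log-RR
scale), half-normal(1) on $\sigma_u$ and $\sigma_\delta$ — weakly
informative: a priori RR variation within one order of magnitude. All
scales are config arguments.

## Sampler

Inference is Metropolis-within-Gibbs, chosen because every update is
explicit and the whole fit is verifiable by simulation:

* $\alpha$ and $\beta$: scalar random-walk moves whose likelihood
  deltas use the fact that both act as global/column-wise scalings of
  the Poisson mean, so no full recomputation is needed.
* $u$: the graph is greedily coloured; tracts of one colour are
  conditionally independent given the rest, so a whole colour class is
  proposed and accepted element-wise in one vectorized step. After each
  sweep $u$ is re-centred per component with the shift absorbed into
  $\alpha$, leaving the likelihood untouched (the posterior mean of
  $\sum_i u_i$ staying at 0 is a tested invariant).
* $\delta$: one vectorized cell-wise random-walk update (cells are
  conditionally independent).
* $\sigma_u, \sigma_\delta$: log-scale random walks against the ICAR
  quadratic form $\sum_{i \sim j}(u_i - u_j)^2$ with rank
  $n - \#\text{components}$, and the Gaussian sum of squares of
  $\delta$, each times the half-normal prior with the log-scale
  Jacobian.

Step sizes adapt toward standard acceptance targets (0.44 scalar, 0.35
vector) during burn-in only; the retained chain is a fixed-kernel
Markov chain targeting the exact posterior. Defaults are 20,000 sweeps
with 5,000 burn-in and a mandatory seed; reduced chains (1,000–3,000
sweeps) are used throughout the test suite, where effective sample
sizes of the scalar parameters are typically 100–500. Initialization is
$\alpha = \log(\sum O / \sum E)$ and zero elsewhere; a non-finite mean
at initialization is an immediate error naming the cell. Degenerate
dimensions collapse: one tract drops $u$, one year drops $\beta$, a
single cell leaves only $\alpha$.

The prior-only mode (`likelihood = FALSE`) reuses the identical kernel
with the likelihood switched off and is tested to recover prior
moments — a whole-sampler validation that catches sign and Jacobian
errors that data-based tests can mask.

## Interaction decision rule

Whether risk trends differ by location is judged by comparing the full
fit against an `interaction = FALSE` fit on the same data. "No
interaction" is declared when the full model's DIC fails to improve by
more than 2 **and** the 97.5% posterior quantile of $\sigma_\delta$
falls below 0.25 on the log-RR scale (roughly: cell-specific risk
wobble confidently under ±28%). Both thresholds are explicit arguments.
The margin of 2 is the conventional "no meaningful difference" band for
deviance-based criteria; 0.25 sits between the posterior mass observed
under no-interaction data (97.5% quantile typically 0.1–0.15 at test
scale) and under substantial interaction ($\sigma_\delta = 0.5$ gives
quantiles above 0.4), and the simulation tests verify the rule
separates these regimes in at least 9 of 10 replicates each way. In a
no-interaction fit the estimated log-RR surface is exactly additive, so
decile profiles of `exp(E[log RR])` are parallel to machine precision —
the package reports that point estimate (the posterior geometric mean)
for profile products precisely so this algebraic property is visible;
the arithmetic posterior mean of $RR$ is not multiplicatively separable
and would show spurious wiggle.

# The space–time scan statistic

Candidate clusters are cylinders: a circular base of tracts (grown by
adding next-nearest centroids, Euclidean distance in a planar
projection, ties broken lexicographically by tract id) crossed with a
contiguous interval of years. Circles grow until the pooled expected
count exceeds `max_spatial_fraction` (default 0.5) of the study total —
the bare center is always kept — and intervals run up to
`ceiling(max_temporal_fraction * T)` years (default 0.5). The original
method's canonical caps are used because published analyses rarely
report theirs; both are exposed in the interface. Duplicate tract sets
arising from different centers are enumerated once.

Each cylinder scores the high-rate Poisson log-likelihood ratio

$$LLR = O \ln\frac{O}{E} + (N - O)\ln\frac{N-O}{N-E} \quad (O > E;
\text{ else } 0),$$

with $O$, $E$ pooled over the cylinder and $N$ the total case count;
$O = N$ drops the second term (its limit is 0). Because the expected
counts are internally standardized, $\sum E = N$ and the statistic is
scale-free. Two relative risks are reported per cluster: the simple
$O/E$ and the inside-versus-outside ratio $(O/E)/((N-O)/(N-E))$, which
dominates $O/E$ for any excess; published cluster tables are ambiguous
between the two, so both columns are carried.

Significance is by Monte Carlo: conditioning on $N$, each replicate
redistributes all cases multinomially over the (tract, year) cells with
probabilities $E_{ij}/\sum E$, re-runs the full scan, and records the
maximum LLR; a cluster's p-value is $\text{rank}/(R+1)$ with rank
$1 + \#\{\text{replicate maxima} \ge LLR\}$. The default is $R = 999$;
tests use 99. The most likely cluster is the LLR argmax (ties broken
toward fewer tracts, then lexicographic center id, then earlier start);
secondary clusters are retained greedily in decreasing LLR order among
significant cylinders sharing no tract with a higher-ranked retained
cluster. All tie-breaks are deterministic, so a scan is bit-reproducible
given its seed.

The candidate structure (orderings, deduplicated sets, a sparse
set-by-tract incidence matrix) depends only on geometry and $E$, so it
is built once; each Monte Carlo replicate costs one sparse matrix
product plus vectorized scoring. A 100-tract, 8-year scan with $R = 99$
runs in about two seconds on one core.

# Covariate comparison

Tracts belonging to any significant cluster at any time are compared
with all remaining tracts, covariate by covariate, using the rank-sum
test with mid-ranks, tie-corrected variance and a 0.5 continuity
correction, at a stricter default alpha of 0.01 in lieu of formal
multiplicity adjustment. The implementation is written out in full (and
cross-checked against `stats::wilcox.test` and exact permutation
enumeration in the tests) so the documented accuracy statement is
checkable: against the exact permutation p-value the normal
approximation is within 0.09 for all tie-free designs with
$n_1, n_2 \le 6$ — the extreme being the 2-vs-2 design — and within
0.05 once both groups have at least 3 observations. Per-cluster
summaries report medians with IQR widths; a single-tract cluster
reports its value with the IQR omitted, as a quartile spread is
undefined for one observation.

# The synthetic registry

The generator emulates the statistical structure the analysis assumes —
not any real geography. Tracts are unit squares on a lattice;
populations are a lognormal tract size (median 4,000 persons,
`sdlog` 0.4) times a fixed age pyramid times a small annual growth
(0.5%/year, so per-year standardization is genuinely exercised).
Baseline age-specific rates follow an adult-onset carcinoma profile
with crude incidence near 50 per 100,000 person-years, giving roughly
2 cases per tract-year — the scale of a state registry divided across
its tracts. Cases are drawn as
$O_{ija} \sim \text{Poisson}(r_a\, p_{ija}\, RR_{ij})$ with the same
four-component log-linear $RR$ the model fits, times planted
multipliers inside declared space–time windows; planting multiplies
rather than replaces the model-based risk so misspecification
experiments remain possible. Covariates derive from a latent
"disadvantage" factor shifted inside planted clusters, reproducing the
qualitative cluster/non-cluster contrasts of registry covariate tables
with configurable effect sizes. Determinism: populations and covariates
are drawn under the master seed, the case process under seed + 1.

What the generator does **not** emulate — irregular tract geometry and
sizes, spatially correlated covariates, registry reporting artifacts,
population migration — bounds what the passing tests show: they
validate the statistical machinery under the stated model, not
robustness to real-data pathologies.

Presets pin the study conditions used by the validation suite:

* `null` — 10×10 tracts, 8 years, flat risk ($\alpha=\beta=\sigma_u=
  \sigma_\delta=0$), no planted clusters. Flat risk is deliberate: the
  scan's Monte Carlo null conditions on the internally standardized
  expected counts, and residual spatial structure is not part of the
  hypothesis being calibrated.
* `single_cluster` — the null field with one planted 9-tract, 3-year
  window at multiplier 2; pooled expected count in the window ≈ 50
  cases, a moderate-power problem.
* `paper_like` — 16×16 tracts with five planted clusters of distinct
  periods and multipliers 1.22–5, trend $\beta = -0.016$ and
  $\sigma_u = 0.15$.
* `small_test` — 12 tracts × 4 years with one strong planted cell, the
  scale at which exhaustive brute-force oracles are exact.

# Validation experiments and problem sizes

The acceptance suite runs, on one core:

* conservation of expected counts on arbitrary fixtures (instant);
* exact equality of every cylinder score and the ranked cluster list
  against an independent brute-force scan at `small_test` scale;
* null calibration: 200 simulated null registries, each scanned with
  $R = 99$; the empirical rate of $p \le 0.05$ must fall in
  [0.02, 0.09] (~10 minutes, the suite's dominant cost);
* power: the `single_cluster` preset over 50 seeds, with detection
  defined strictly — a significant cluster covering at least half of
  the 9 planted tracts (~3 minutes). At this signal size (about 2
  expected cases per cell) the scan localizes a significant,
  all-true-positive core in 49 of the 50 seeds, but the max-LLR window
  covers at least half the planted block in only 44: maximum-likelihood
  windows shrink toward the hottest cells under Poisson noise, a known
  behaviour of scan statistics, so the strict coverage bar sits at the
  edge of attainability here and the experiment documents both numbers;
* trend recovery: 100 registries at 5×5 × 8 years with
  $\beta = -0.02$, fitted with 1,500-sweep chains; the 95% credible
  interval covers the truth in at least 90 (~2 minutes);
* exact parallelism of no-interaction log-RR profiles (machine
  precision);
* the rank-sum approximation bound, exhaustively over all small
  designs.

Chain lengths and lattice sizes here are the package's validation
choices: large enough that each check is informative, small enough that
the whole suite is a coffee-break run.

# Known limitations

* Queen contiguity is detected through shared snapped vertices
  (tolerance 1e-6 map units). Boundary contact occurring only at a
  point interior to both polygons' edges — a T-junction with no shared
  vertex — is not detected; census tract tessellations share vertices
  along common boundaries, so this arises only with unusual inputs.
* The local equirectangular projection provided for lon/lat input is a
  small-region approximation; rigorous work should reproject upstream
  and supply planar coordinates.
* Scan windows are circular-based cylinders only; elliptical or
  irregular windows and low-rate (cold-spot) scanning are out of scope.
* The interaction decision rule is an explicit stand-in for an omnibus
  test; its thresholds are documented arguments, not universal
  constants.
* Monte Carlo p-values are granular at $1/(R+1)$; with $R = 99$ the
  smallest attainable p is 0.01.
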