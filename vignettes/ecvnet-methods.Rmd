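---
title: "Network-based patient subtyping with edge contribution values: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based patient subtyping with edge contribution values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvnet)
```

## The problem and the model

Tumor subtypes defined by clustering molecular profiles frequently fail to
separate patient prognoses, arguably because profile-level similarity does
not capture differences in the *regulatory system* driving each tumor.
`ecvnet` addresses this by working at the level of a gene regulatory
network estimated from the cohort's expression data.

The cohort network is a Bayesian network over the p genes: a DAG G in which
each gene j has a conditional density given its parents. The joint density
factorizes into local densities, so the network score is a sum of
per-family scores and structure search only ever re-scores the families a
move changes. The local model is additive nonparametric regression,

$$x_{ij} = m_1^{(j)}(pa_{i1}^{(j)}) + \dots + m_{q_j}^{(j)}(pa_{i q_j}^{(j)}) + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_j^2),$$

with each smooth $m_k^{(j)}$ a cubic B-spline expansion. The fitted value of
$m_k^{(j)}$ at one patient's parent expression is that patient's **edge
contribution value** (ECv) for the edge $j_k \to j$: how much that edge
contributes to the patient's expression of gene $j$ under the cohort-level
model. Two patients with identical marginal expression of a gene can use
its incoming edges very differently; the ECv matrix (patients × edges)
makes this visible, and hierarchical clustering of the matrix defines
network-based subtypes.

## The local fit and the family score

For a child with parents, we stack the per-parent B-spline design matrices
and solve a penalized least-squares problem with a second-difference
(curvature) penalty per parent. Conditional on the penalty weights this is
Bayesian ridge regression, so the marginal likelihood is available in
closed form with the noise variance profiled out; we use its logarithm as
the family score, plus a $-\tfrac12 \log n$ Laplace term for the intercept.
The score is decomposable and deterministic, and in simulation it
consistently identifies true families (see `test-bspline.R` and
`test-network_estimation.R`).

Tunable parameters, defaults, and why:

* **`n_basis` (10), `degree` (3)** — cubic splines with 10 basis functions
  per parent; knots at equally spaced quantiles of the covariate. Enough
  flexibility for monotone, saturating, and U-shaped responses at the
  sample sizes the package targets (n in the low hundreds), while keeping
  each family solve a ≤ 30-dimensional Cholesky.
* **`lambda_grid` (10 points, 1e-3…1e3)** — smoothness weights are chosen
  by empirical Bayes: a shared-λ grid search followed by one per-parent
  coordinate sweep. A full per-parent grid would cost $10^q$ solves for no
  measurable gain.
* **`ridge` (1e-3)** — a proper prior on the penalty null space (the
  constant and linear directions the curvature penalty cannot see). This
  value is deliberately moderate: with a near-improper choice (1e-6) the
  null-space term adds ≈ 25 nats of complexity cost per parent, more than
  the ≈ 21-nat gain of the *first* parent of a genuinely additive
  three-parent family at n = 150 — a greedy search then cannot enter the
  family at all. At 1e-3 single-parent entry is possible while a two-gene
  null cohort (n = 300) still selects the empty network in 100/100 seeds.
* **Centering** — each fitted component is shifted to zero mean over the
  training samples, with the offset absorbed into the intercept. This fixes
  the absolute scale of ECvs (training columns average to zero); all
  downstream statistics (variance ranking, the multi-group delta statistic)
  are invariant to this choice.
* **Out-of-range evaluation** — inputs are clamped to the training range
  (constant extension). Splines extrapolate polynomially and wildly;
  clamping is the conservative choice for patients outside the training
  support.

## Structure search

Full-scale versions of this analysis estimate ~20,000-gene networks with a
massively parallel sampler on dedicated hardware. At package scale we use
greedy hill-climbing: best-improvement moves among edge addition, deletion,
and reversal under an acyclicity check and a per-node parent cap (default
3), with random restarts (default 5; restart 1 is the empty graph). Two
non-obvious choices:

* **Pair-addition escape.** An additive family can score *worse* than empty
  for every single parent and far better once two are present (each
  component alone explains too little to pay the complexity cost). When no
  single move improves, the climber evaluates adding the best parent *pair*
  to one family, guarded by a log(#pairs) multiplicity threshold so the
  best of ~1,000 chance-level pairs cannot enter.
* **Exhaustive oracle.** For p ≤ 5 genes, `exhaustive_search()` enumerates
  every DAG under the parent cap (25 DAGs for p = 3, reported via the
  `n_dags` attribute) and returns the global optimum, with ties broken by
  fewest edges then lexicographic edge list. The test suite requires greedy
  search to attain the exhaustive optimum in ≥ 90% of seeds on 3–4 gene
  problems.

Scores are cached by (child, sorted parent set), so restarts and pair
scans mostly hit the cache.

## Subtyping and subtype-specific edges

Edges are ranked by the unbiased sample variance of their ECv column;
clustering uses the top N columns. N defaults to 250 — the headline setting
for TCGA-scale networks of ~150,000 edges — but is an explicit parameter
(the original choice is described only as approximately the smallest value
that gave meaningful results; no selection rule exists). Clustering is
agglomerative with Ward linkage on Euclidean distances of raw (unscaled)
ECv columns; single, complete, and average linkage and per-column z-scoring
are available but off by default. Cluster labels are renumbered by
decreasing size with ties broken by smallest member id, so results are
deterministic and invariant to row/column order. The number of subtypes k
is a parameter (default 3); `silhouette_scan()` is guidance only.

For M subtype groups, the per-edge multi-group statistic is the absolute
difference between the group's mean ECv and the pooled mean of all other
groups. At M = 2 the two groups receive the identical value (computed once
and duplicated, so the symmetry is exact in floating point). Each group's
top `ceiling(0.01 × E)` edges are selected (ties by edge id) and an edge is
*subtype-specific* when selected by exactly one group. Exclusive sets are
therefore pairwise disjoint by construction.

## Survival machinery

Kaplan–Meier estimation and the M-sample log-rank test (hypergeometric
variance with the standard tie correction, χ² reference with M − 1 df) are
implemented directly; the test suite cross-checks both against the
`survival` package and against a label-permutation oracle, and verifies
type-I error calibration (0.05 ± 0.02 over 1,000 null simulations).
Pairwise subtype comparisons report unadjusted p-values by default (the
convention in the analyses this package follows), with an optional
Bonferroni flag. Records lacking a subtype label are dropped with a
message.

## The synthetic world: what it emulates and what a green test establishes

`generate_cohort()` is the package's acceptance surface: it must plant
subtype structure that the pipeline *should* recover, and nothing the
pipeline could cheat on. Its design went through explicit analysis that is
worth recording.

**What ECv clustering can and cannot see.** Every ECv column is a fixed,
cohort-level transform $\hat m(\cdot)$ applied to one gene's expression.
Consequently two subtypes are distinguishable in ECv space only if the
*marginal distributions* of parent genes differ between them; and if
per-gene subtype means are forcibly equalized, only higher-moment
differences (variance, shape) remain, which a nonlinear $\hat m$ can
convert into ECv location shifts. Three corollaries drove the design:

1. *Scale-only signal is unclusterable.* Amplitude-scaling a zero-mean edge
   function gives the affected subtype a wider — but identically centered —
   distribution. In that geometry the affected patients are farther from
   each other than from everyone else, and no distance-based clustering can
   group them.
2. *Post-hoc mean matching injects unobservable intercepts.* Equalizing a
   child gene's subtype means is equivalent to adding per-subtype
   intercepts to its regression — which flattens the pooled spline fit
   exactly where an unbalanced planted signal lives (measured on an
   idealized motif: standardized ECv gap drops from ≈ 3.3 to ≈ 0.3).
3. *Balance dissolves both problems.* If every subtype perturbs its own,
   equally sized share of the network, per-gene marginals match across
   subtypes *by construction*: mean matching becomes a no-op, and the
   information survives — in which edge carries each patient's signal.

The frozen world is therefore a balanced **subtype-program architecture**:
Gaussian root regulators feed **switch** genes through saturating sigmoid
responses; each switch is owned by one subtype, and hyperactivation in the
owner means an `effect_size`-fold (default 3×) drive *and* operation in the
ultrasensitive (high Hill coefficient) regime, pinning owner patients at
the ±3a response rails while other subtypes see a moderate smooth response.
Switches feed shared **integrator** genes through strong dosage-sensitive
(quadratic) responses — one switch per subtype per integrator — so each
integrator's marginal distribution is subtype-independent, yet the per-edge
decomposition reveals which input is railed. Raw expression clustering is
blind here twice over: gene marginals carry no subtype location signal, and
the railed switches split patients by the biologically irrelevant *sign* of
the deviation, which the even (quadratic) response folds away in ECv space.
This is precisely the claim the method makes on real tumors — same basal
network, different edge usage — distilled into a verifiable generative
model.

Remaining generator defaults: 15 genes, 3 subtypes × 50 patients, 10
altered edges (quota beyond the nine switch edges lands on fold edges read
from *another* subtype's switch, where the switch idles near its set point
and the alteration is physiologically present but neutral), observation
noise sd 0.3 against unit-variance roots, exponential survival with
per-subtype hazards 0.004/0.002/0.001 per day and exponential censoring at
rate 0.001 (≈ 30% censoring) — a 4× hazard span typical of strongly
prognostic subtype splits.

**What a green test does not establish.** The generator emulates additive
nonlinear regulation with Gaussian noise and a planted, balanced,
detectable signal. Real RNA-seq has count noise, batch effects,
missingness, unbalanced and entangled subtype programs, and ~10³× more
genes; recovery there depends on scale and preprocessing this package does
not model. Success on the synthetic world establishes the *machinery* —
scores, search, quantification, statistics — not clinical performance.

## Numerical choices and degenerate inputs

* Family solves use Cholesky factorizations of (Zᵀ Z + K); a singular
  system raises an error suggesting a smaller basis.
* Quantile knots are nudged strictly inside the covariate range to protect
  conditioning; a constant covariate is an error.
* `delta_ecv` requires every group to be non-empty; a group absent from the
  ECv matrix is an error, not a silent drop.
* The log-rank statistic falls back to a pseudoinverse when a group is
  entirely censored before the first event (singular variance matrix).
* Readers reject NA, non-numeric cells, ragged rows, duplicate ids, cycles,
  and self-loops with located error messages; nothing is coerced silently.
* All generators take a mandatory seed and restore the caller's RNG state.

## Known limitations

* Greedy search with a parent cap is a stand-in for the published
  large-scale sampler; beyond ~30 genes, expect minutes, and beyond a few
  hundred, use a pre-estimated network as input.
* The score's prior is an empirical-Bayes convenience, not the published
  criterion's exact constants (which are not stated in the source
  analysis); any decomposable consistent score satisfies the same
  contracts.
* Heteroscedastic noise, interaction (non-additive) regulation, and
  categorical covariates are out of scope.
* N (edges kept for clustering) and k (subtypes) remain user choices;
  nothing in the method selects them automatically.
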