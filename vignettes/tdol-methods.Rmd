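---
title: "Temporal drivers of liking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal drivers of liking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdol)
```

## The problem

Drivers-of-liking analysis asks which sensory attributes matter most for
consumer liking. With multi-attribute time-intensity (MATI) data — repeated
intensity ratings of several attributes over the course of consumption — the
question becomes temporal: the importance of an attribute can itself change
as a product is chewed, dissolves and is swallowed. `tdol` estimates
relative-importance *trajectories* and their dynamics.

Sensory attributes are almost never independent, so ordinary regression
coefficients are unreliable importance measures. The package therefore uses
two non-additive importance models, chosen by data shape:

* **Choquet integral / capacity (fuzzy measure)** — for panel-level data,
  where each time point offers only a handful of product means (one
  observation per product). The capacity $v$ assigns a weight to every
  *subset* of attributes, so complementarity and redundancy are part of the
  model rather than a nuisance.
* **LMG variance decomposition** — for consumer-level data, where each time
  point offers one row per consumer and regression is feasible. The LMG share
  of a predictor is its sequential $R^2$ gain averaged over all orderings of
  predictors, which is exactly the Shapley value of the $R^2$ game.

## The capacity model

A capacity on attributes $N = \{1,\dots,n\}$ is a set function
$v : 2^N \to [0,1]$ with $v(\emptyset) = 0$, $v(N) = 1$, and
$v(S) \le v(T)$ for $S \subseteq T$. The Choquet integral of a profile
$x \in [0,1]^n$ with respect to $v$ is

$$C_v(x) = \sum_{i=1}^n \left(x_{(i)} - x_{(i-1)}\right) v(A_{(i)}),$$

with $x_{(1)} \le \dots \le x_{(n)}$ the sorted values and $A_{(i)}$ the set
of attributes whose value is at least $x_{(i)}$. For an additive capacity it
reduces to the weighted mean; in general it is idempotent and monotone.

Identification works in the Möbius representation
$m(S) = \sum_{T \subseteq S} (-1)^{|S \setminus T|} v(T)$, where the Choquet
integral is linear: $C_m(x) = \sum_S m(S) \min_{i \in S} x_i$.
`fit_capacity_ls()` solves

$$\min_m \sum_i \left(C_m(x_i) - y_i\right)^2 + \rho\, \lVert m - m_\mathrm{unif}\rVert^2
\quad \text{s.t.} \quad \textstyle\sum_S m(S) = 1, \; v_m \text{ monotone},$$

a quadratic program (solved with the dual active-set method of
`quadprog::solve.QP`) whose monotonicity constraints are linear in $m$:
$\sum_{T \subseteq S} m(T \cup \{i\}) \ge 0$ for every attribute $i$ and
$S \subseteq N \setminus \{i\}$.

Importance and interaction are read off the fitted capacity:

* the **Shapley value** $\phi_i$ — the average marginal contribution of
  attribute $i$ over all attribute orderings; $\sum_i \phi_i = 1$;
* the **pairwise Shapley interaction index** $I_{ij} \in [-1,1]$ — positive
  when two attributes are complementary, negative when substitutive, zero for
  an additive capacity.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_additive` | 2 | largest interacting subset size; 2 keeps direct effects plus pairwise interactions (10 coefficients for 4 attributes) and is the smallest model that still reports interactions |
| `ridge` | 1e-6 | pull toward the uniform additive capacity; negligible for determined fits, makes the underdetermined case a unique minimum-deviation problem |
| monotonicity tolerance | 1e-9 | validation tolerance; the QP imposes the constraints exactly |

### Underdetermination is structural, not an accident

A study with 3 products and 4 attributes gives 3 observations per time point
against 10 free Möbius coefficients at `k_additive = 2`. Every pointwise fit
is flagged `underdetermined`; the ridge term selects, among all capacities
that reproduce the data, the one closest to the uniform additive capacity.
Two consequences users should keep in mind:

1. the solution is unique and deterministic, but *biased toward equal
   importance* — with very few products, strongly non-uniform true structures
   are systematically attenuated;
2. trajectories are most trustworthy in their ordering and in their changes
   over time, less so in the absolute spread between attributes.

The package's recovery experiments (see `scripts/acceptance.R`, quantity
`pipeline_shapley_mae`) measure exactly this attenuation on synthetic data
with a known generating capacity.

## Commensurability

The Choquet integral requires all inputs on one scale. Attributes are min–max
scaled to $[0,1]$ per fit (each variable's observed minimum goes to 0, its
maximum to 1; records are kept for exact inversion; a constant variable is
mapped to 0.5 and flagged, since it carries no information). Liking, however,
is **not** min–max scaled per fit: with only 3 products that would pin the
most- and least-liked product of every time point to 1 and 0, erasing the
actual hedonic spread and (verified on synthetic data with a known capacity)
roughly doubling the Shapley recovery error. Liking is instead mapped by its
declared scale range (e.g., 0–100 line scale), which is deterministic and
comparable across time points.

## LMG for consumer and just-about-right data

`lmg_shares()` computes, for each predictor *group*, the average over group
orderings of the increase in $R^2$ when the group enters after its
predecessors. Groups matter because a just-about-right (JAR) attribute coded
$\{-1, 0, +1\}$ (too weak / just right / too strong) enters as one 3-level
factor: `expand_jar_design()` builds its indicator columns (reference level
"just about right") and the group's share is attributed jointly to them.
Shares are invariant to the reference level because the column span is
unchanged. Defaults: shares normalized to sum to 1; exact enumeration up to 8
groups (computed over group subsets with Shapley weights rather than by
looping over orderings); a seeded Monte-Carlo average over orderings beyond
that. Degenerate inputs are handled without crashing the trajectory: a JAR
attribute with a single observed level is dropped with a warning, a
zero-variance liking time point yields a missing row, and rank-deficient
designs go through a rank-tolerant least-squares path.

## Functional smoothing and dynamics

Raw MATI series and importance trajectories are smoothed with cubic B-splines
(order 4) by minimizing

$$\sum_j \left(y_j - f(t_j)\right)^2 + \lambda \int f''(t)^2\, dt.$$

Defaults follow standard functional-data practice: `n_basis = min(#points,
20)` with equally spaced interior knots; the curvature penalty matrix is
assembled by composite Simpson quadrature (201 points per knot span, which is
effectively exact for piecewise-polynomial integrands at the tolerances
used); $\lambda$ is chosen by generalized cross-validation over the
log-spaced grid $10^{-6}\dots10^{4}$ when not supplied, which is
deterministic. Curves are never extrapolated outside the observed time
domain.

Derivatives are exact basis-expansion derivatives. `derivative_report()`
locates zero crossings of the first derivative (sign change on a 201-point
grid, refined by bisection) and classifies each as a maximum or minimum by
the sign of the second derivative; first derivatives below a noise floor of
$10^{-10}$ relative to the curve scale count as zero, so constant curves
report no spurious extrema. "Stable" intervals are maximal runs where both
$|f'|$ and $|f''|$ stay below thresholds; the defaults (10% of each curve's
own maximum $|f'|$ and $|f''|$) make the qualitative rule "close to zero"
concrete while adapting to each curve's scale.

Two caveats are documented rather than hidden: smoothing does not preserve
the row-sum-1 constraint of importance trajectories exactly (evaluated rows
typically re-sum to $1 \pm 0.02$; `trajectory_from_curves(renormalize =
TRUE)` restores it when needed), and `dominant_driver()` can be run on either
the raw per-time trajectory or its smoothed version — the two can disagree
near crossings.

## The synthetic-data generator

Tests and recovery experiments run on synthetic data with known ground
truth, shaped after a small product-guidance study:

* 3 products × 4 texture attributes × 9 trained panelists on a 0–150 line
  scale, time-intensity curves of gamma-density shape
  $(t/t_p)^a e^{a(1-t/t_p)}$ peaking at $t_p = 10$ s with steep decay,
  sampled on 3–90 s in steps of 3 s; product × attribute amplitudes are drawn
  independently (product profiles cross, as they do when prototypes trade one
  texture property off against another); Gaussian rating noise (default sd 8
  line-scale units, a realistic trained-panel dispersion) truncated to the
  legal range;
* liking for the Choquet path generated as the Choquet integral of a known
  capacity applied to min–max scaled panel means, on a 0–100 scale;
* 40 consumers × 3 JAR attributes on 14–90 s in steps of 4, with liking =
  baseline − per-attribute penalties for non-just-right responses;
* 5 CATA item proportion series on 1–25 s from smooth logistic trajectories.

All randomness flows through one seeded stream per call (the global RNG
state is left untouched), so fixed seeds give bitwise-identical tables.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot show about real data: panelist-specific response styles and
drift, session and carry-over effects, non-Gaussian rating behaviour near
scale ends, and time-varying importance structure (ground-truth capacities
are constant in time so that recovery has a well-defined target).

## Numerical choices

* Subsets are encoded as bitmasks over the attribute order; Möbius/zeta
  transforms are the fast $O(n 2^n)$ bitwise recursions, exact to floating
  point round-off.
* QP determinism: `quadprog::solve.QP` is deterministic for fixed inputs;
  after solving, coefficients are renormalized to sum exactly to 1.
* With `ridge = 0` the Hessian gets a $10^{-10}$ jitter so the QP stays
  positive definite; an underdetermined fit with `ridge = 0` is an error
  unless explicitly allowed, because its optimum is non-unique.
* Ties in `dominant_driver()` (equality within $10^{-12}$) go to the
  lexicographically first attribute and are flagged.
* Serialization: capacities and curves round-trip through JSON at 17
  significant digits, bit-exactly; trajectory CSVs carry 15 significant
  digits.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(noise_sd = 0, seed = 11)
panel <- gen_mati_curves(cfg)
means <- mati_dataset(attr(panel, "truth"), scale = "line")

truth <- mobius_capacity(
  local({m <- numeric(16); m[2^(0:3) + 1] <- c(.30, .17, .18, .15)
         m[4] <- .20; m}),
  cfg$attributes, k_additive = 2)
liking <- gen_liking_from_capacity(means, truth, seed = 12)

res <- pointwise_importance_choquet(means, liking)
res$importance                       # 30 x 4 Shapley trajectory
curves <- importance_curves(res$importance)
derivative_report(curves)            # extrema and stable intervals
dominant_driver(res$importance)      # per-time winning attribute
```

## Known limitations

* Pointwise capacity fits at 3 products are underdetermined; see above.
* The LMG path provides no interaction indices — that is a property of the
  statistic, not an omission.
* Exact LMG enumeration is exponential in the number of groups (hence the
  Monte-Carlo fallback above 8 groups).
* The packaged reference tables are published outputs whose raw inputs are
  unavailable; they serve as consistency fixtures (row sums, ranges, printed
  cells), never as fitting targets.
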