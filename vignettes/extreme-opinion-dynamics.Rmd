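---
title: "Modelling the rise of extreme opinions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the rise of extreme opinions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stubborn)
```

## The model

Each of $N$ agents on a fixed undirected network holds a continuous opinion
$q_i \in [-1, 1]$; $q > 0$ is a positive stance, $q < 0$ a negative one, and
$|q| > q_e$ counts as *extreme* (the default $q_e = 0.5$ mirrors the
four-category layout of most opinion surveys: strong-positive, positive,
negative, strong-negative). At every time step all nodes are updated
synchronously from the arithmetic mean $\bar q_i$ of their neighbours'
opinions:

* **adopt** — if $\bar q_i$ has the same sign as $q_i$ and is more extreme
  ($|\bar q_i| > |q_i|$), the node adopts $\bar q_i$;
* **ignore** — if $\bar q_i$ has the same sign and lies in the
  *inflexibility range* $(1-a)|q_i| \le |\bar q_i| \le |q_i|$, nothing
  happens;
* **compromise** — otherwise (an opposing or much more moderate mean), the
  node moves to a convex combination of $q_i$ and $\bar q_i$.

The stubbornness $a \in [0, 1]$ controls the width of the inflexibility
range. Boundary ties are assigned to the *ignore* rule, so exactly one rule
fires for every input; every branch is a convex combination of values in
$[-1,1]$, so opinions can never leave the interval.

### The two compromise conventions

The package deliberately supports two weightings of the compromise rule,
selected by `model_params(compromise_weight = )`:

* `"self"` (default): $q \mapsto (1-a)\,\bar q + a\,q$. The node's own
  opinion carries the stubbornness weight. At $a = 0$ all three rules
  collapse to $q \mapsto \bar q$ — plain synchronous neighbour averaging —
  so the dynamics reduces to a consensus model whose final state is
  (approximately) the mean of the initial opinions. At $a = 1$ the
  compromise is the identity: opinions only ever ratchet outward by
  adopting more extreme same-sign means, signs never flip, and the positive
  fraction $f$ is conserved.
* `"neighbors"`: $q \mapsto a\,\bar q + (1-a)\,q$, the weighting implied by
  the model's worked single-node example (a node at $q = 0.5$ with $a=0.8$
  facing an opposing mean moves to $-0.3$). At $a = 1$ an opposing
  neighbourhood mean is adopted outright while same-sign more-moderate
  means are still ignored; this is the regime that produces abrupt,
  first-order-like extreme-consensus transitions and macroscopic opinion
  cascades at high mean degree.

These are genuinely different models at the extremes of $a$, and the
literature this package implements describes the consensus limit with one
weighting while its worked example and its reported critical phenomenology
(an order-change degree near $4.5$, square-root scaling at the transition,
a $3/2$ avalanche-size tail) are only reproducible with the other. Rather
than silently pick one and lose half of the phenomenology, the package
makes the convention an explicit, documented parameter: consensus-limit
studies use the default `"self"`; criticality and avalanche studies use
`"neighbors"` with $a = 1$. The inflexibility range is
$[(1-a)|q|,\,|q|]$ under both conventions, and both satisfy the
sign-symmetry property (negating every opinion negates the trajectory).

### Relaxation and stopping

`relax()` iterates synchronous sweeps until the largest per-node change in
one sweep falls below `tol` ($10^{-9}$ by default), with a cap of
`max_steps` ($10^4$) sweeps. Synchronous averaging can oscillate with
period 2 (a two-node graph at $a = 0$ swaps opinions forever), so the
relaxer also detects period-2 cycles — the state matching the state two
steps earlier to within `tol` — and returns the time average of the two
phases with `cycle_detected = TRUE`. Non-convergence is reported through
flags, never raised as an error, and cycle-averaged states participate in
sweep statistics like any other final state (averaging over the cycle is
unbiased between the two phases).

Nodes with degree 0 have no social input and keep their opinion. A node at
exactly $q = 0$ has no sign, so the adopt/ignore rules cannot apply; the
default convention applies the compromise formula (dropping the $q$ term).
With continuous initial opinions both situations are measure-zero.

## Networks and initial conditions

Networks are Erdős–Rényi draws $G(n, p)$ with $p = \langle k\rangle/(n-1)$,
generated through igraph; the realised mean degree is stored alongside the
target. Initial conditions place exactly `round(f0 * n)` uniformly chosen
nodes at $q \sim \mathrm{Uniform}(0, 1)$ and the rest at
$q \sim \mathrm{Uniform}(-1, 0)$; fixing the count rather than sampling
per-node removes binomial variance from the control parameter. The expected
initial extremist fraction is $(1 - q_e) f_0$. Simulations run on the full
graph; cluster observables are normalised by the size of the largest
connected component.

## Observables

`fractions()` reports $f = N^+/N$ (nodes with $q > 0$) and
$f_e = N_e^+/N$ (nodes with $q > q_e$), with strict inequalities and the
total node count as denominator. `e_clusters()` forms the subgraph induced
by one polarity's extremists and sizes its connected components; `g1` and
`g2` are the two largest sizes normalised by the largest-component size.
The phase analysis tracks positive extremists only; the negative side is
available by symmetry.

## Sweeps and reproducibility

`run_sweep()` crosses an increasing `f0` grid with independent network
realizations: each cell draws a fresh graph and initial condition, relaxes,
and records $f$, $f_e$, $g_1$, $g_2$. The cell at grid index $i$ and
realization $r$ is seeded `base_seed + (r-1)|grid| + (i-1)`, so any single
cell can be reproduced in isolation and reruns are bit-identical.
`model_curve()` extracts the parametric $(f, f_e)$ relation that survey
data can be compared against.

## Avalanches

Starting from a relaxed state, `perturb_one()` forces one *vulnerable* node
($0 < q < q_e$) to $q = 1$ and re-relaxes; the avalanche size $S$ counts
the other previously vulnerable nodes that end extreme. The trigger is
excluded (it was made extreme by fiat), triggers are evaluated one at a
time against the same base state, and the mean $\langle S\rangle$ is taken
over successful triggers ($S \ge 1$) only. `avalanche_scan()` runs every
vulnerable trigger; because a perturbation of a relaxed state can only
propagate outward from changed nodes, the compiled scanner re-evaluates
just the active frontier each sweep with incrementally maintained
neighbour sums, and restores the base state between triggers. An optional
`max_triggers` cap subsamples triggers uniformly when states hold many
thousands of vulnerable nodes; the package's own studies use it only where
stated.

`fit_tail()` fits a discrete power law to pooled sizes by maximum
likelihood, with the lower cutoff chosen by Kolmogorov–Smirnov
minimisation over candidate cutoffs (at least 100 tail observations are
required). The normalising Hurwitz zeta is evaluated by an Euler–Maclaurin
expansion; the KS statistic of the selected fit is reported as a
goodness diagnostic, and `rplaw_discrete()` provides the generator half of
round-trip tests. Because any single `f0` away from the exact critical
point yields a cutoff distribution — and at desk scale the ensemble at a
fixed `f0` mixes realizations whose pseudo-critical points straddle it,
steepening the pooled tail — the critical exponent itself is measured by
`fit_tail_envelope()`: the envelope of the size distributions across a
family of `f0` slices approaching the transition, fitted in log–log
coordinates over its leading non-increasing range. The single-slice MLE is
reported alongside as a per-condition summary.

## Critical points, transition order, and $k_c$

`find_critical_points()` reads the percolation point $f_0^{c1}$ off the
peak of the mean second-largest e-cluster (the classic finite-size
signature of a percolation threshold) and the extreme-transition point
$f_0^{c2}$ off the peak of the largest avalanche size $S^*$, refining both
off-grid with a local quadratic fit through the three points around the
grid argmax. A peak sitting on the grid boundary raises an error asking
for a wider grid rather than returning a silently censored estimate.

Two order classifiers are provided, because the quantity that defines the
transition order — a discontinuity of the infinite-size $g_1(f_0)$ curve —
is not directly visible at desk scale. `classify_order()` thresholds the
largest single-step increment of the mean curve (default 0.1 on the
normalised scale) with a finite-size shrink check across sizes; it matches
the definition directly but requires the mean-curve jump to stand clear of
the steps a steep continuous curve produces, which at $N \le 10^4$ it does
not: realization averaging smears the jump across the
realization-to-realization spread of the transition point, and measured
max steps differ little between continuous and discontinuous degrees.
`classify_order_bimodal()` instead detects branch coexistence — at a
discontinuous transition the per-realization $g_1$ values at some $f_0$
split into two well-separated groups — as the largest gap between
consecutive sorted per-realization values, maximised over the grid, with
at least three realizations required on each side so a single straggler
cannot mimic coexistence. On single-graph curves with coupled initial
conditions the two regimes are unambiguous (a smooth curve at
$\langle k\rangle = 4$, a jump of $\approx 0.46$ at $5$), and the gap
statistic separates them by a factor of several at twenty realizations;
the default threshold 0.2 sits between the observed within-branch spread
and the observed branch separations. Because the trimmed gap can only
ever *understate* coexistence (a lopsided split clips a genuine gap),
the degree scan resolves any non-monotone label sequence at its first
first-order label.

`fit_zeta()` estimates the hybrid-transition exponent $\zeta$ in
$|g_1 - g_{1,c}| \propto |f_0 - f_0^c|^{\zeta}$ as the least-squares slope
in log–log coordinates over a window of grid points on the stated side of
the critical point (from above for $f_0^{c1}$, from below for
$f_0^{c2}$), between one grid step and `window` (default 0.05) away from
it. For the approach from above, the reference level $g_{1,c}$ defaults to
the curve's interpolated value at the critical point. For the approach
from below, the realization-averaged curve cannot supply the reference
directly: close to a discontinuous transition the average mixes the two
branches across the spread of per-realization transition locations, so
the curve's value *at* $f_0^{c2}$ sits an arbitrary way up the smeared
jump. The fitter therefore excludes branch-mixing grid points, flagged by
per-point standard errors several times the window median, and treats
$g_{1,c}$ as a nuisance parameter chosen to maximise the log–log
linearity of the remaining clean-branch points — the usual treatment of
an unknown critical offset, and one that recovers planted exponents and
offsets exactly on noise-free curves. Points with non-positive
differences are dropped with a warning, and fewer than five usable points
is an error, not a silent fit.

`estimate_kc()` brackets the order-change degree as the midpoint between
the largest second-order and smallest first-order degree on the scanned
grid, with half the grid step as its uncertainty; non-monotone label
sequences are rejected as classification noise. `scan_transition_orders()`
packages the whole protocol (per-degree sweeps at two sizes, jump
classification with the finite-size check, bracketing).

The phase diagram maps $f_0^{c1}$ and $f_0^{c2}$ per degree through each
sweep's own $f_0 \to \bar f_e$ relation into the observable
$(f_e, \langle k\rangle)$ plane; `classify_society()` interpolates the two
lines at a society's effective degree and returns phase I (no giant
e-cluster), II (incipient giant e-cluster, growing cascades), or III
(extremist consensus). `fit_mean_degree()` fits an effective
$\langle k\rangle$ to empirical $(f, f_e)$ points by grid search over
candidate degrees, scoring each candidate's simulated curve by vertical
squared residuals; it is validated by parameter recovery on
model-generated point clouds, not against any external survey.

## The empirical arm

`to_ffe()` converts four-category counts to $(f, f_e)$ points per polarity,
dividing by the full surveyed total (including nonresponse) by default; a
flag restricts the denominator to the category sum. Star-rating histograms
are mapped to categories by `star_map` objects (10-star movie and 5-star
book conventions ship as constructors; a six-level party-orientation map
ships as a JSON config, since that assignment is data, not code).
Categories are stored disjointly — the moderate count excludes the extreme
subset — so that the inclusive counts the fractions need are recovered as
sums; the shuffle null redistributes each polarity's votes uniformly across
that polarity's levels, preserving polarity totals exactly.

The LOESS smoother follows the classical locally weighted regression
recipe: at each evaluation point the window reaches the
$r = \lceil \mathrm{span}\cdot n\rceil$-th nearest observation, weights are
tricube in the scaled distance, and a degree-1 weighted polynomial is
evaluated at the point (degree and robustness iterations are parameters;
the default runs none). The Nadaraya–Watson smoother uses a Gaussian
kernel, with the bandwidth chosen by leave-one-out cross-validation over 30
log-spaced values spanning 0.01–1 times the abscissa range.
`departure_point()` operationalises "departure from linearity": a line
through the origin is fitted to the low-$f$ part of the smoothed curve
(below 0.3 by default) and the departure is the first abscissa where the
curve exceeds the line by three low-$f$ residual standard deviations; all
three constants are explicit arguments.

## The synthetic poll generator

`gen_polls()` emulates the shape of category-count survey tables: per unit
a latent $f \sim \mathrm{Uniform}(0.05, 0.95)$, a latent
$f_e = g(f)$ from a named curve family (linear, piecewise with a planted
changepoint, or a model sweep's curve), a negative side mirrored through
the same $g$ applied to $1-f$, and multinomial counts at the chosen number
of respondents (optionally Dirichlet-overdispersed). It reproduces the
*sampling structure* of such tables — counts, polarity symmetry,
unit-to-unit latent spread — but not country covariates, temporal
autocorrelation, or questionnaire effects, so passing recovery tests shows
the estimators work at survey-like sample sizes, not that any real-world
poll follows the planted curves. `gen_from_model()` closes the loop from
simulator to empirical pipeline: `fit_mean_degree()` must recover the
generating degree from polls sampled off a sweep curve.

## Study sizes

The package's own validation studies (tests and the acceptance script) use
deliberately desk-scale problems chosen as the smallest sizes at which the
respective phenomena are stable: the consensus limit on
$N = 10^4$, $\langle k\rangle = 4$; the order-change scan over
$\langle k\rangle \in [4, 5]$ in steps of $0.25$ at $N = 10^4$ with 20
realizations per grid point on an $f_0$ grid of step $0.01$ through the
transition region; the scaling-exponent fit at $\langle k\rangle = 5$,
$N = 2\times 10^4$, 10 realizations on a $2.5\times 10^{-3}$-spaced grid;
the avalanche envelope over thirteen $f_0$ slices straddling the extreme
transition at $N = 10^4$, six realizations per slice with avalanche scans
subsampled to 150 triggers per state. Unit tests run far smaller systems
(hundreds of nodes) where exact oracle comparisons are feasible.

## Known limitations

* Stubbornness is homogeneous across agents; no opinion noise, network
  rewiring, or asynchronous updating.
* Only Erdős–Rényi topologies are generated internally; any
  `opinion_network` built from an edge list can be simulated, but
  heavy-tailed degree distributions have not been validated.
* Under the `"neighbors"` convention at $a = 1$ relaxation can end in
  period-2 cycles; the cycle average is used, and avalanche scans on such
  states inherit that approximation.
* The jump-based order classification depends on an explicit threshold and
  finite-size check; near the order-change degree the label is genuinely
  noisy at desk scales, which is why the bracketing estimator reports a
  half-grid-step uncertainty and rejects non-monotone label sequences.
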