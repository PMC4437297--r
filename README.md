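# stubborn

Agent-based modelling of how public opinion becomes extreme, and the survey
statistics that signal it. The package is for computational social
scientists and sociophysicists who want to simulate stubbornness-driven
opinion dynamics on random networks, characterise the percolation of
extremist clusters and the cascades they enable, and analyse real or
synthetic categorical survey data on the same footing.

## The model

Each of $N$ agents holds a continuous opinion $q \in [-1, 1]$ on an
Erdős–Rényi contact network with mean degree $\langle k\rangle$; opinions
with $|q| > q_e$ are *extreme* (default $q_e = 0.5$, mirroring four-category
surveys). At each step every node is updated synchronously from the mean
opinion $\bar q$ of its neighbours:

* $q \to \bar q$ if $\bar q$ is same-signed and more extreme than $q$;
* $q \to q$ (no change) if $\bar q$ is same-signed with
  $(1-a)|q| \le |\bar q| \le |q|$ — stubbornness $a \in [0,1]$ widens this
  inflexibility range;
* otherwise $q$ moves to a convex combination of $q$ and $\bar q$
  (two supported weightings; see `?model_params` and the methods vignette).

Runs start from a fraction $f_0$ of nodes with opinions uniform on
$(0, 1)$, the rest uniform on $(-1, 0)$. The headline observables are the
final fractions $f$ (positive) and $f_e$ (extreme positive), the largest
and second-largest connected components of extremists (*e-clusters*), the
size $S$ of the cascade triggered by forcing one vulnerable node
($0 < q < q_e$) to $q = 1$, and the nonlinearity of the $(f, f_e)$ relation
— the survey-measurable early warning that a society is approaching an
extreme phase. The analysis suite locates the two critical points of the
$f_0$ sweep (e-cluster percolation at $f_0^{c1}$, extremist takeover at
$f_0^{c2}$), classifies their order, estimates the order-change degree
$k_c$ and the hybrid-transition exponent $\zeta$, fits power-law avalanche
tails, and builds the $(f_e, \langle k\rangle)$ phase diagram on which
societies can be placed.

The empirical arm converts four-category poll counts, star-rating
histograms, and orientation-mapped vote counts into $(f, f_e)$ points,
smooths them with locally weighted (LOESS) or Nadaraya–Watson kernel
regression, detects the departure from the linear (non-interacting)
baseline, and provides a within-polarity shuffle null plus synthetic poll
generators so the whole pipeline is testable offline.

## Worked example

```r
library(stubborn)

params <- model_params(a = 1, q_e = 0.5)
sweep <- run_sweep(n = 2000, k_mean = 4.2,
                   f0_grid = seq(0.1, 0.9, by = 0.1),
                   n_realizations = 5, base_seed = 1, params = params)
head(model_curve(sweep), 4)
#>    f0   f     fe
#> 1 0.1 0.1 0.0531
#> 2 0.2 0.2 0.1078
#> 3 0.3 0.3 0.1556
#> 4 0.4 0.4 0.2042
```

With full stubbornness signs never flip, so $f$ equals $f_0$; the extreme
fraction starts near the non-interacting expectation
$f_e \approx (1-q_e) f_0$ (0.05 at $f_0 = 0.1$) and outgrows it as
interacting extremists pull moderates over the threshold — by $f_0 = 0.4$
the model already shows 0.204 instead of 0.20, and the excess widens with
$f_0$ together with the largest e-cluster (`g1` in `sweep$summary`).

```r
set.seed(2)
net <- generate_er(2000, 4.2)
state <- relax(init_opinions(net, 0.55), params)
avalanche_scan(state, params)
#> avalanche_summary: 507 triggers, 75 succeeded, <S> = 1.13, S* = 3
```

507 moderates are vulnerable; forcing each one in turn to $q = 1$ shows the
society is still stable — 75 triggers convert anyone at all, and the
largest cascade converts 3 nodes. Near the extreme transition the same scan
produces cascades spanning a finite fraction of the network.

```r
polls <- gen_polls(n_units = 300, respondents = 1500,
                   g = latent_piecewise(0.33, changepoint = 0.5),
                   seed = 3)
pts <- subset(to_ffe(polls), polarity == "positive")
trend <- loess_fit(data.frame(x = pts$f, y = pts$fe), span = 0.8)
departure_point(trend, cutoff = 0.45)
#> [1] 0.4533333
#> attr(,"slope")
#> [1] 0.3384012
```

A synthetic 300-country poll table with a planted change of regime at
$f = 0.5$: the LOESS trend recovers the low-$f$ slope (0.338 fitted vs
0.33 planted) and flags the departure from linearity at $f \approx 0.45$,
the survey-side signature that cascading extremism has set in.

A command-line interface wrapping the same functions ships at
`inst/cli/stubborn` (subcommands `sweep`, `avalanche`, `phase`,
`pollcurve`, `synth`; every run writes CSV plus a JSON provenance record).

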