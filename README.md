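# oifnet

Directed predictive-causality networks from ecological time series.

Ecologists monitoring a community — a biweekly visual census of fish
species, fishery landings next to a temperature record — want to know *who
forces whom*: which species interact, in which direction, at which time
delay, and how the web of interactions reshapes the community through time.
Linear correlation cannot answer this (it is symmetric and haunted by
"mirage" correlations in nonlinear systems), and convergent cross mapping
(CCM) answers it only when long, convergent libraries are available.

`oifnet` implements the *optimal information flow* (OIF) approach: directed
interactions are scored by **transfer entropy** evaluated at the
**mutual-information-optimal time delay**, turning a multispecies abundance
table into a weighted directed interaction network. The transfer entropy
from a source S to a target T with unit Markov orders is

```
TE(S -> T) = sum p(T_t, T_{t-u}, S_{t-u}) log [ p(T_t | T_{t-u}, S_{t-u}) / p(T_t | T_{t-u}) ]
```

with probabilities estimated either on a fixed grid of equal-width bins or
with a box (step) kernel of radius `r` (default `r = 0.25` in z-score
units), and the delay `u` chosen to maximize `MI(S(t-u); T(t))` — the delay
that minimizes the information distance `d = exp(-MI)` between the two
species. CCM (simplex projection on shadow manifolds, with cross-map skill
`rho` and its convergence over library length) and plain correlation are
provided as comparators, plus the machinery downstream of the network:
time-resolved *dynamical networks* at a fixed inference resolution `g`, and
*effective alpha-diversity* — the count of species retaining at least one
inferred interaction above a threshold — optimized against taxonomic
alpha-diversity.

Benchmarks are generated in-package: the coupled logistic two-species map
`S(beta_xy, beta_yx)` with known embedded causality, a 15-species seasonal
community with a planted interacting core, Gaussian VAR(1) processes whose
transfer entropy has a closed form (TE = Granger causality for Gaussian
processes), and explicit-lag coupled pairs for delay recovery.

## Worked example

Two species, X forcing Y with strength 0.8 and no reverse coupling:

```r
library(oifnet)

ts <- simulate_coupled_logistic(beta_yx = 0.8, n_steps = 1000)
optimal_delay(ts$values[, "X"], ts$values[, "Y"], u_range = 1:10,
              config = estimator_config(estimator_kind = "kernel"))
#> delay search over u in {1..10}: u* = 3 (MI = 1.2523)

fit <- oif(ts, method = "te",
           config = estimator_config(estimator_kind = "kernel"))
fit
#> oif network (te): 2 species, 1000 time points
#>   global delay u = 3
#>   raw score range: [0.1417, 1.574]
round(coef(fit), 3)      # normalized scores, row = source, column = target
#>   X Y
#> X 0 1
#> Y 0 0
```

The raw range says it directly: 1.57 bits flow from X into Y, 0.14 bits
(estimation floor) in the reverse direction — the planted unidirectional
coupling, recovered with its direction and a nontrivial delay.

Community-scale analysis on the synthetic census (15 species, 285 biweekly
samples, 5 interacting):

```r
cm <- simulate_community(seed = 1)
nets <- dynamical_networks(cm$ts, method = "te",
                           config = estimator_config(estimator_kind = "kernel"),
                           g = 30, window_mode = "sliding", step = 5,
                           delay_policy = "fixed",
                           bias_correction = "shuffle", shuffle_seed = 1)
srch <- optimize_threshold(nets, cm$ts, criterion = "corr")
srch
#> threshold_search (corr): theta* = 0.00 (score 0.9586)
head(srch$alpha, 4)
#>   time alpha_eff alpha_tax theta
#> 1   30         6         6     0
#> 2   35         6         6     0
#> 3   40         6         6     0
#> 4   45         6         6     0
```

At the optimized threshold the effective alpha-diversity tracks the
taxonomic one window by window (score 0.96) and stays within ~1 species of
the planted interacting count (5) on average.

A thin command-line wrapper over the same functions ships in
`inst/cli/oif.R` with subcommands `simulate`, `delay`, `infer`, `ccm`,
`scan` and `diversity`; every run archives its resolved configuration
(YAML) and a log with seed, version and timing.

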