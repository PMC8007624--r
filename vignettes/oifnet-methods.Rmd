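---
title: "Methods: optimal information flow networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal information flow networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the estimators it
implements, the choices made where more than one defensible implementation
exists, what the synthetic generators do and do not emulate, and the known
limits of the approach. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The model

The package treats causality as *predictive* causality: species S is said
to force species T to the extent that S's past reduces the uncertainty of
T's next state beyond what T's own past already explains. That quantity is
the transfer entropy

$$TE_{S\to T}^{(k,l)} = \sum p\!\left(T_t, T_{t-u}^{(k)}, S_{t-u}^{(l)}\right)
  \log\frac{p\!\left(T_t \mid T_{t-u}^{(k)}, S_{t-u}^{(l)}\right)}
           {p\!\left(T_t \mid T_{t-u}^{(k)}\right)},$$

an asymmetric, directed functional of the joint distribution. The Markov
orders default to $k = l = 1$ (a memoryless community: the next state
depends on the current one), and the source–target delay $u$ is *not*
fixed a priori: it is selected, per pair or globally, as the delay
maximizing the mutual information $MI(S(t-u); T(t))$, equivalently
minimizing the information distance $d = e^{-MI}$ (MI in nats). Selecting
the delay of maximum shared information focuses the estimate on the
strongest (possibly episodic) interaction rather than the average one.

Three comparators are implemented behind the same interface: Pearson
correlation (linear, symmetric, no direction), plug-in mutual information
(nonlinear, still symmetric), and convergent cross mapping (state-space
reconstruction; directed, but requiring convergence over library length).

### Assumptions

* Abundances are sampled at a fixed interval on a shared clock; delays are
  expressed in samples.
* Series are complete — the reader rejects missing cells rather than
  imputing values, because every estimator below assumes an uninterrupted
  joint sample.
* Stationarity is assumed *within a window*; nonstationarity across the
  record is the business of the dynamical-network machinery, not of a
  single estimate.

## Probability estimation and its parameters

Two plug-in density estimators stand behind the information measures:

* **Fixed-grid histogram** (`estimator_kind = "histogram"`): bins of width
  `r` anchored at 0, on z-scored data. This kind admits an *exact*
  brute-force oracle (`plugin_te_oracle()`), against which the production
  implementation is verified to $10^{-12}$ over random symbol sequences,
  alphabets 2–8, orders $k,l \in \{1,2\}$ and delays 1–3.
* **Box kernel** (`estimator_kind = "kernel"`): the step-kernel estimator
  counting neighbours within max-norm radius `r` of every sample point
  (compiled in C++). It pools local neighbourhoods instead of imposing a
  global grid, and carries a much smaller small-sample bias on short,
  noisy ecological series; it is the estimator of record for the
  community-scale analyses.

Parameters that matter, with defaults and reasons:

| parameter | default | units | why |
|---|---|---|---|
| `r` | 0.25 | z-score units | calibrated width for abundance series; series are standardized first so the width is scale-free |
| `k`, `l` | 1 | samples | memoryless Markov assumption |
| `u` | selected | samples | MI-optimal delay, candidates `1:10` |
| `log_base` | 2 | — | results in bits; the distance $e^{-MI}$ always uses nats; bits = nats / ln 2 holds exactly for every estimator |
| `min_samples` | 30 | samples | minimum-data floor, the same 30 points that set the network resolution `g` |
| `E`, `tau` (CCM) | selected, 1 | — | embedding dimension by leave-one-out simplex self-prediction over `1:10`, smallest dimension on (near-)ties |

Two bandwidth remarks. First, `r = 0.25` is a choice for bounded, skewed
abundance distributions; for the *Gaussian* closed-form validation the
acceptance suite uses `r = 0.75`, because the plug-in bias of fine grids in
three dimensions at $n = 5\times10^4$ dominates the (smooth, unimodal)
Gaussian target — bandwidth should match the smoothness of the density,
not the habit of the field. Second, the histogram kind at `r = 0.25` on
*unbounded* marginals (e.g. Gaussian noise) occupies thousands of cells and
its bias at $n \le 10^4$ is of order 0.1–0.5 bits; the hygiene checks of
independence therefore use either bounded series or the kernel kind. These
are documented properties of plug-in estimation, not defects of one
implementation.

### Bias correction for panels

On short panels with observation noise, every pair of a community carries a
common finite-sample bias (measured by the suite at roughly 0.4 bits for
285-point noisy series with the kernel estimator). `transfer_entropy()`
and `infer_interaction_matrix()` therefore offer a *shuffled-source
baseline* (`bias_correction = "shuffle"`): the mean TE after permuting the
source series (seeded, 2 permutations by default) is subtracted,
Marschinski–Kantz style. This is a bias correction — the package
deliberately implements no surrogate-ensemble significance testing. The
correction is off by default and switched on for the planted-structure
community analyses, where contrast between true and spurious edges is what
is being measured.

## Convergent cross mapping choices

* Embedding convention: point $i$ of the shadow manifold is
  $(x(t_i), x(t_i-\tau), \ldots, x(t_i-(E-1)\tau))$; a series of length
  $n$ yields $n-(E-1)\tau$ points.
* Neighbours: the $E+1$ nearest library points (bounding simplex) under
  Euclidean distance, weighted $w_i \propto e^{-d_i/d_1}$; when the
  nearest distance is exactly zero, the zero-distance neighbours share
  uniform weight.
* **Exclusion rule**: a prediction at time $t$ always excludes library
  vectors with $|t_i - t| \le$ `theiler`; the default `theiler = 0` thus
  excludes exactly the predictee itself (leave-one-out). Literal
  self-inclusion would hand every cross-map a zero-distance neighbour
  carrying the answer and drive every skill to 1; leave-one-out is the
  standard simplex-projection scheme and makes the independent-series
  null behave (skill near 0).
* Libraries of length $L$ are the *first* $L$ embedded points, making the
  convergence profile deterministic and bitwise reproducible.
* Direction semantics follow the cross-mapping convention: the causal
  claim "X forces Y" is supported when X is well estimated *from the
  manifold of Y* — the caused variable's reconstructed states contain the
  causer.

## The synthetic community: what it emulates, what it does not

`simulate_community()` plays the role of a 12-year biweekly census
(default 285 samples, 15 species). Its frozen default conditions:

* **Interacting core** — species 1–5, always present, chaotic
  (multiplicative logistic updates, growth rates 3.6–3.9), coupled through
  a directed ring plus two chords with strengths near 0.5. These are the
  "truly interacting" species recorded as ground truth (any $|B|$ entry at
  or above 0.1).
* **Sporadic species** — species 6–15, stable noisy populations (growth
  rates 2.2–2.8, process noise sd 0.05) that are *observed* only
  sporadically: zero-inflated detection with mean per-sample probability
  0.45%, seasonally modulated, so each contributes a fluctuating presence
  signal at the window scale — the "rare species with many zero values" of
  real censuses.
* **Shared forcing** — a sinusoid of relative amplitude 0.1 and period 26
  samples (annual at biweekly sampling) on every growth rate. The
  amplitude is deliberately moderate: strong shared forcing creates
  *genuine* cross-predictability between non-interacting species (a
  common-driver effect, not an estimator artifact), and no estimator in
  this family can remove it. The suite demonstrated exactly that before
  the amplitude was fixed.
* **Observation noise** — lognormal, sd 0.1.

What it does not emulate: trends and regime shifts, interaction strengths
that drift with temperature, observation error correlated across species,
and true extinction/colonization dynamics of the dominant species. Passing
the recovery tests on this generator shows the machinery recovers *known*
planted structure under census-like sampling; it does not certify
performance on any real census.

### Why the diversity benchmark uses sliding windows

The dynamical-network default is the incremental (expanding-window) scheme
at resolution $g = 30$ samples. For the *effective-diversity* benchmark
the acceptance analysis uses sliding windows instead: taxonomic
alpha-diversity over an expanding window is a cumulative presence count —
a monotone staircase that saturates at $S$ — whereas the benchmark needs
the fluctuating, seasonal richness signal that only local windows retain.
Both modes are exported; the choice is a property of the question (global
accumulation vs. local community state), not of the data.

Window-level estimates at $g = 30$ necessarily use 29 usable sample
vectors once the unit delay is folded in; matrix inference inside windows
therefore relaxes the standalone 30-sample floor (with a warning at the
resolution level), keeping the documented window counts (a series of
length $n$ yields $n-g+1$ expanding matrices at step 1).

## Numerical conventions

* $0 \log 0 = 0$ in every plug-in sum; only occupied cells are enumerated,
  so the convention is structural rather than an epsilon.
* Ties in every arg-max (delay search, threshold search, embedding
  dimension) resolve to the smallest candidate; the embedding selector
  also treats skills within $10^{-6}$ of the maximum as tied, since
  noise-free self-prediction skills can differ only at rounding level
  across dimensions.
* Zero-variance series raise a dedicated condition
  (`oifnet_zero_variance`) in standalone estimators, but score 0 with a
  warning inside matrix inference — an entirely absent species is data,
  not an exception, at the community scale.
* Negative cross-map skills are floored at 0 before min–max
  normalization; normalized matrices carry off-diagonal values in
  $[0,1]$ with maximum 1, and an all-equal matrix collapses to zeros with
  a warning rather than dividing by zero.
* The coupled logistic map is iterated exactly as written, with no
  clipping; iterates outside $[-0.5, 1.5]$ abort with a divergence error
  (an optional floor-at-zero mode exists), and a zero initial state is
  rejected as absorbing. The community generator, by contrast, *is*
  clipped to $(0,1)$ — it is a data emulator, not a dynamical study.
* The analytic Gaussian VAR transfer entropy comes from the stationary
  solution of the discrete Lyapunov equation
  $\Sigma = A\Sigma A^\top + Q$ (solved exactly by vectorization):
  $TE = \tfrac12\log(\sigma^2_{restricted}/\sigma^2_{full})$, validated
  in-suite against restricted-vs-full least squares on simulated data.

## Design points that were genuinely open

* **The $\pm u$ in the delayed MI**: the package shifts the *source* into
  the past (pairs $S(t-u)$ with $T(t)$), matching the source–target delay
  semantics of the transfer entropy; candidates are $u \ge 1$ in the
  delay search, while `mutual_information()` itself also accepts $u = 0$
  (where symmetry holds to $10^{-12}$ and is tested).
* **The delay applied to the target's own past**: the TE definition is
  implemented as printed, with the *same* $u$ lagging both the target
  history and the source history.
* **Two-species benchmarks run at $u = 1$** where the delay is part of the
  model definition (the coupling acts one step ahead); the delay search
  exists for data whose lag is unknown, and with per-pair optimal delays
  the two-species transfer entropy saturates past moderate couplings as
  the pair synchronizes — an effect of the dynamics, not the estimator.
* **Effective-diversity membership**: a species counts as interacting if
  *any* incident directed link (in or out) meets the threshold; in-only
  and out-only rules are exposed as options. The either-rule privileges
  no direction, matching "count of model-inferred interacting species".
* **Threshold-search scoring**: effective vs. taxonomic alpha series are
  compared contemporaneously (no lag), by Pearson correlation (default)
  or plug-in MI on the two integer count series; degenerate constant
  series score $-\infty$ (correlation) or 0 (MI) instead of erroring.

## Known limitations

* Plug-in information estimates at $n \lesssim 300$ carry biases
  comparable to weak true couplings; the shuffled-source correction
  restores contrast but costs variance. Nearest-neighbour (KSG)
  estimators are out of scope by design.
* Indirect links are *not* removed: a chain $A \to B \to C$ yields a
  nonzero $A \to C$ entry. All inferred flows are reported without
  redundancy filtering.
* Common drivers (seasonality, environment) induce genuine predictive
  information between non-interacting species. The package quantifies
  predictive causality, which is not mechanistic causality; interpreting
  thresholded networks as food webs requires the same caution as any
  observational inference.
* The kernel transfer entropy is implemented for $k = l = 1$ only; higher
  orders are available through the histogram kind.
* Conditional (multivariate) transfer entropy — conditioning on third
  species — is not implemented.

## Problem sizes used by the tests and the acceptance script

Benchmarks run at desk scale, chosen so the full suite completes in well
under a minute of estimator time on one CPU: two-species maps at 1000
steps, the phase-space grid at 10 couplings, VAR validation at
$5\times10^4$ (closed form) and $5\times10^5$ (regression cross-check)
samples, CCM libraries up to 1000 points, delay recovery over 60 seeded
replicates, and the full community pipeline (15 species, 285 samples, 52
sliding windows, 21 thresholds) at two shuffle permutations per pair.
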