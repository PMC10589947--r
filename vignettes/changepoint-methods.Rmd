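---
title: "Detecting single behavioral transitions in telemetry tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single behavioral transitions in telemetry tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(movecpt)
library(dplyr)
```

## The problem

Many questions in movement ecology reduce to locating a *single* behavioral
transition in a telemetry time series: parturition, the onset of migration,
natal dispersal, a mortality event. Around parturition, for example, an
ungulate may relocate her core-use area (a change visible in the raw
*locations*) or switch to slow, tortuous movement around a birth site (a
change visible in derived *movement metrics* — step lengths and turning
angles). The two signatures are logically independent: a female can shift
her centroid without changing her step-length distribution, and can shrink
her movements without moving the centroid. `movecpt` therefore implements
two change-point models sharing one detection machinery, so the two
hypotheses can be confronted with the same data.

Both models assume the track is a regular-interval sequence of planar
coordinates (metres; e.g. UTM), one individual at a time, and that at most
one transition occurs inside the analysis window.

## Shared structure: the spike-and-slab change point

Let $T$ be the number of locations. The change point $\tau$ has a
spike-and-slab prior: a point mass $w$ at $\tau = 0$, meaning *no change
occurred* and every observation is generated by the first (pre-event)
state, mixed with a uniform slab over the candidate change times
$\{2, \dots, T\}$. Observations with time index $t < \tau$ belong to state
1 and those with $t \ge \tau$ to state 2. Detection is then a model-based
statement — the posterior mode of $\tau$ equal to zero *is* the
"no change" conclusion — rather than a post-hoc judgement on a noisy
estimate.

Two support conventions are worth making explicit:

* $t = 1$ contributes no likelihood term in the location model (the
  likelihood conditions on the first location), and $\tau = 1$ would merely
  relabel "no change with state-2 parameters". The slab therefore starts at
  $\tau = 2$; the relabelling equivalence is the reason no probability is
  lost by excluding $\tau = 1$.
* $\tau = 0$ is defined to mean "state 1 throughout", so a detected change
  always means "a *second* regime exists at the end of the series".

The spike weight defaults to $w = 0.5$, the usual uninformative choice for
a yes/no model-selection prior; it is configurable in
`lcpm_priors()`/`mmcpm_priors()`.

## The location-based model (LCPM)

Positions follow a two-state AR(1) attractor process,

$$\mathbf{y}_t \sim \mathcal{N}\!\left(\rho\,\mathbf{y}_{t-1} +
(1-\rho)\,\boldsymbol{\mu}_i,\; \sigma^2 \mathbf{I}\right),
\qquad i = \begin{cases}1 & t < \tau\\ 2 & t \ge \tau,\end{cases}$$

an Ornstein–Uhlenbeck-like process in discrete time: $\rho$ scales the
dependence on the previous location and $1-\rho$ the attraction to the
state's geographic centroid $\boldsymbol{\mu}_i$. At $\rho = 0$ locations
are iid around the centroid; as $\rho \to 1$ the attractor vanishes and
the process becomes a random walk. Only the centroid switches at the
change point: preliminary-analysis experience with ungulate data (and the
desire to keep the two states exchangeable in everything except position)
argues for a single $\sigma$ and a single $\rho$.

Priors: $\sigma \sim U(0, 10^7)$ m; $\rho \sim U(0, 0.8)$, allowing
positive autocorrelation while retaining some centroid attraction;
$\boldsymbol{\mu}_i \sim \mathcal{N}(\mathbf{0}, \mathtt{mu\_sd}^2\,\mathbf{I})$
on *mean-centered* coordinates (`center_locations()`), so a single origin
serves every individual.

**On `mu_sd` (default 5000 m).** The centroid prior scale is the one
genuinely open numerical choice in this model. A scale of order tens of
metres would be inconsistent with the data the model is designed for —
per-individual-centered tracks whose pre/post centroids can sit a
kilometre apart — and would shrink both centroids toward the origin hard
enough to bias the separation by hundreds of metres and ruin interval
coverage. We therefore default to a weakly informative 5000 m standard
deviation per coordinate, which is effectively flat at the scale of a
home-range shift while still proper. It is configurable for other systems.

## The movement-metric model (MMCPM)

Turning angles $a_t$ and step lengths $s_t$ (derived by
`compute_metrics()`) share the single change point:

$$a_t \sim \text{wrapped Cauchy}(\gamma_i, \kappa_i), \qquad
s_t \sim \begin{cases}\text{Weibull}(\alpha_i, \beta_i)\\
\text{Exp}(\lambda_i)\end{cases}$$

with state $i$ assigned by the same $t \ge \tau$ rule. The wrapped Cauchy
is used because it degenerates gracefully to the circular uniform at
$\kappa = 0$ — "equally likely to move in any direction" — and
concentrates at its location $\gamma$ as $\kappa \to 1$. Priors:
$\gamma_i \sim U(-\pi, \pi)$, $\kappa_i \sim U(0, 1)$,
$\alpha_i \sim \text{Gamma}(0.001, 0.001)$,
$\beta_i \sim U(0, \mathtt{beta\_max})$,
$\lambda_i \sim \text{Gamma}(0.001, 0.001)$.

The step family is a per-dataset modelling decision, not an automatic
choice. The Weibull is flexible enough to chase isolated very long steps
and attribute the change point to them; when such outliers are common
(as in the deer case the model family was developed against), the stiffer
exponential is the better-behaved description. Both are implemented;
`"weibull"` is the default for the simulation scenarios.

**On `beta_max` (default 500 m).** The canonical upper bound of 50 for
the Weibull scale prior presumes coarser length units than the metres
used throughout this package — with sub-hourly ungulate steps averaging
over 100 m, a 50 m bound would place zero prior mass on realistic scales.
The default bound of 500 m keeps the prior diffuse on the metre scale and
is configurable (`mmcpm_priors(beta_max = )`).

### Metric conventions

* The step from $t-1$ to $t$ and the turning angle pivoting at $t$ are
  both indexed by $t$, so "$t \ge \tau$" refers to movement *realized at
  or after* the change.
* Turning angles are signed heading changes across two consecutive
  displacement vectors, counter-clockwise positive, wrapped to
  $(-\pi, \pi]$. No convention is forced by the model — the $U(-\pi,\pi)$
  prior on $\gamma$ is symmetric, so any consistent convention yields the
  same likelihood — but one must be fixed and documented; CCW matches the
  mathematical positive direction. The half-open support boundary (which
  of $\pm\pi$ is included) is equally arbitrary and fixed at $+\pi$.
* A zero-length step has no heading: the two adjacent angles are flagged
  missing (`NA`), reported via a warning, and dropped from the likelihood
  product rather than imputed. Zero steps themselves must be removed
  before fitting (they have no density under either family).

## Samplers

Both models use Metropolis-within-Gibbs sweeps (compiled in C++; R draws
the random numbers' seeds via `set.seed()`):

* $\tau$ is drawn *exactly* from its categorical full conditional each
  sweep. The vector of $T-1$ slab weights plus the spike is assembled in
  $O(T)$ from prefix sums of state-1 per-term log-densities and suffix
  sums of state-2 terms, stabilized by max-subtraction. (The test suite
  checks this against brute-force $O(T^2)$ enumeration and, via
  chi-square goodness of fit, against clamped-parameter chains.)
* LCPM centroids have conjugate normal full conditionals (the AR(1)
  residual $\mathbf{y}_t - \rho\,\mathbf{y}_{t-1}$ is normal with mean
  linear in $\boldsymbol{\mu}$); the exponential rate has a conjugate
  Gamma full conditional. Both are drawn directly.
* $\sigma$ (log scale), $\rho$ (logit scale on its support), $\gamma$
  (wrapped random walk), $\kappa$, $\alpha$ (log scale) and $\beta$ use
  adaptive random-walk Metropolis targeting a 0.44 acceptance rate, with
  Robbins–Monro adaptation during burn-in only (frozen afterwards, so the
  post-burn-in kernel is valid MCMC).
* While the spike is active, state 2 has no data. Its centroid (LCPM) and
  rate (exponential) are drawn from their full conditional — the prior.
  The remaining state-2 parameters are updated by the *same random-walk
  kernels targeting the prior*: this has exactly the prior as stationary
  distribution (so the posterior is untouched) but keeps the parameters
  in the vicinity of their last data-informed values, which is what lets
  the chain re-enter the slab. Independent redraws from the very diffuse
  $\text{Gamma}(0.001, 0.001)$ shape prior would produce astronomically
  implausible values and freeze the chain in the spike.

One further move is essential for correctness. The configuration
"$\tau = 2$ with state 1 empty" is an exact relabeling of "no change":
the likelihood is identical with the state parameters exchanged, and
marginalizing the empty state's parameters shows its posterior mass must
equal $P(\tau = 0)$ times the prior odds $(1-w)/((T-1)w)$ — about 1/400
in a typical track. A pure Gibbs chain, however, can *absorb* there:
once state 1 holds no data its parameters drift in the prior, and the
categorical update then sees every alternative as implausible. Both
samplers therefore include a label-swap Metropolis move between
$\tau = 0$ and $\tau = 2$ (exchange the state parameters; accept with
the prior odds), which restores the exact ratio — verified against the
closed form in the test suite — and eliminates a spurious
false-detection mode in no-change data.

A *single chain* is run. With exchangeable state priors the mixture labels
are identified only through time order; label switching across multiple
chains would have to be undone before pooling, and a posterior mode of a
relabeled chain is not meaningful. If multiple chains are needed, an
ordering constraint on the centroids can identify the labels; the
single-chain default avoids the issue.

Two schedules are provided (`mcmc_config()`): the production `"paper"`
profile (200,000 iterations after 100,000 burn-in, thinned by 4; refits
at 2.5x) and the `"desk"` profile (20,000/10,000, thinned by 2) used for
interactive work, the test suite and the replicate studies below. The
desk profile is entirely adequate for the simulated tracks here (a few
hundred observations, unimodal posteriors); the long profile matters for
weakly informative real data.

## Assessment framework

`detect_change()` takes the posterior mode of $\tau$; mode zero means no
change was detected (ties involving zero resolve to zero, conservatively).
Given a detection and a known event time, `classify_success()` centers
the slab draws of $\tau$ on the truth, converts to hours, and applies
a-priori accuracy classes with a ±6 h window:

* **Level 1** — the 95% equal-tailed credible interval lies within ±6 h;
* **Level 2** — the 50% CI lies within ±6 h;
* **Level 3** — the posterior median lies within ±6 h;
* otherwise **unsuccessful**.

The levels are nested by construction. Quantile (not HPD) intervals are
used, and the 95% interval width in hours is reported as a precision
measure. Spike draws are excluded from the quantiles by default: they
live at the coded value 0, not on the change-time scale, and a mixture
quantile would be meaningless; `include_spike = TRUE` restores the
literal mixture if wanted.

Convergence is checked per continuous parameter with the Geweke
diagnostic (`geweke_z()`: first 10% vs last 50%, spectral-density
variance at frequency zero via an AIC-selected AR fit). Angular chains
are first rotated to their circular mean and re-wrapped — a posterior
concentrated near $\pm\pi$ legitimately hops between the support ends,
which a linear diagnostic misreads as non-stationarity. $|z| \le 2$
passes per parameter, and any flagged parameter triggers one refit with
2.5x the iterations (and a fresh seed: replaying the same random numbers
would partially reproduce the flagged trajectory).

The fit-level decision needs care. Under the null each parameter's $z$ is
roughly standard normal (the calibration is itself verified in the test
suite), so "any of 8 parameters above 2" false-alarms on roughly 30% of
perfectly healthy fits — and would do so again on the refit. In a
replicate study with no analyst looking at posteriors, that strict rule
would mislabel a substantial share of clean fits as non-converged. The
runner (`run_grid()`) therefore uses the strict per-parameter rule to
*trigger* the refit, but declares the refit non-converged only when some
$|z|$ exceeds a family-wise-calibrated (Bonferroni) threshold — the
automated stand-in for visually confirming a marginal flag. Both
thresholds are exposed, and single fits checked interactively with
`check_convergence()` always report the strict rule.

`summarize_run()` tabulates replicate outcomes over the six categories
(Levels 1–3, not successful, no change detected, did not converge) as
percentages.

## The simulator and the study-design experiments

`simulate_lcpm_track()` generates the AR(1) attractor process with the
centroid jumping between $(-\text{shift}/2, 0)$ and
$(+\text{shift}/2, 0)$ at the change point; `simulate_mm_track()` draws
state-wise step/angle sequences and reconstructs coordinates by
cumulative heading, so `compute_metrics()` recovers the drawn metrics
exactly (an invertibility property the tests assert at $10^{-9}$).
The change point is placed *between* observations: the state switch
applies from the first post-event index, and the event time is that
fix's timestamp.

`make_scenario_grid()` emits the three study-design experiments:

* **duration** — 48 h pre-event at 15-min fixes, with post-event
  monitoring truncated to 48/24/12/6/3 h. Truncated datasets are derived
  from the *same* complete replicates, not re-simulated.
* **frequency** — 48 h pre / 24 h post at 15 min, thinned to 30 and
  60 min (again from the same replicates; thinned tracks are strict
  subsets, and metrics are recomputed from the thinned coordinates, never
  rescaled — steps along a curved path do not add linearly).
* **magnitude** — LCPM centroid separations 1026.0, 784.5, 523.0 and
  261.5 m (100/75/50/25% of the largest); MMCPM scenarios in which both
  metrics, only angles, only steps, or neither change.

Generating values the scenario definitions do not pin down are fixed once
here and exposed as arguments:

* LCPM noise $\sigma = 150$ m with $\rho = 0.8$, giving a stationary
  per-coordinate SD of $\sigma/\sqrt{1-\rho^2} \approx 250$ m. This makes
  the 1026 m shift an easy ~4-SD signal and the 261.5 m shift a hard
  ~1-SD signal — a realistic gradient from obvious relocation to
  within-home-range noise.
* MMCPM pre-state $\gamma = 0$, $\kappa = 0.2$, Weibull
  $\alpha = 1.3$, $\beta = 120$ m (weakly directional, extensive
  movement); post-state $\gamma = \pi$, $\kappa = 0.7$, $\beta = 35$ m
  (encamped, back-and-forth movement around a fixed site, as after
  parturition). The exponential rates are matched to the same mean steps.

### What the simulations do and do not show

The simulator generates data *from the models' own dynamics*: clean
regular fixes, no observation error, a single instantaneous transition,
stationary behavior within each state. Success rates estimated on these
tracks are therefore statements about the *samplers and the detection
machinery* under each design (duration/interval/magnitude), i.e. a
best-case envelope. They do not establish that free-ranging animals
follow these dynamics — real tracks add GPS error, missed fixes, diel
rhythms, gradual transitions and multiple behavioral changes, any of
which can produce multi-modal change-point posteriors or mask the event.
Validation data remain necessary before treating a detected change as a
particular biological event.

### Parameter recovery and prior boundaries

The recovery checks in the test suite (20 replicates per model, 95%
CI coverage of every continuous parameter) use *interior* generating
values: $\rho = 0.6$, and MMCPM states away from $\gamma = \pi$. The
detection scenarios themselves deliberately sit on prior boundaries
($\rho = 0.8$ is the upper end of its uniform prior; $\gamma = \pi$ is
the edge of the angular support), and an equal-tailed interval can never
cover a boundary truth — a property of interval estimation, not a sampler
defect. Keeping the boundary values in the detection scenarios and the
interior values in the recovery checks separates the two questions
cleanly.

## Numerical choices and degenerate inputs

* All change-point weight vectors are normalized after subtracting the
  maximum log-weight; an all-`-Inf` conditional raises an error rather
  than returning NaN.
* `wrap_to_pi()` maps exact multiples of $-\pi$ to $+\pi$ so the support
  convention is airtight.
* Wrapped Cauchy sampling wraps a linear Cauchy with scale $-\log\kappa$
  (exact; uniform at $\kappa = 0$).
* Tracks must have strictly increasing timestamps; duplicates are
  rejected with row numbers. `thin_to_interval()` requires an integer
  interval multiple. `truncate_after()` refuses to empty a track.
  Metric derivation needs $T \ge 3$; fitting needs $T \ge 4$ usable
  terms.
* `resample_linear()` is deliberately plain chord interpolation for
  mildly irregular data, flagged `interpolated`; it is not a movement
  model and will understate corner-cutting at coarse intervals.
  Continuous-time movement-model interpolation is out of scope.

## Replicate-study problem sizes

The packaged experiments (test suite and `scripts/acceptance.R`) run 20
replicates per scenario cell with the desk MCMC profile — enough for
binomial confidence statements about success rates near 1 while keeping a
full grid in the minutes range on a single core. The production profile
and 50-replicate grids reproduce the same designs at scale via
`make_scenario_grid(n_replicates = 50)` and
`run_grid(..., mcmc = mcmc_config("paper"))`.
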