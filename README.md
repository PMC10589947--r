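# movecpt

Bayesian change-point detection of single behavioral transitions — such as
parturition, migration onset or dispersal — in regular-interval animal
telemetry tracks, for movement ecologists who want a model-based answer to
*"did this animal change its behavior, and if so, when?"* with an explicit,
quantified "no change" outcome.

## The models

Two complementary change-point models describe the two ways a behavioral
shift can show up in a track, and share one detection machinery:

**Location-based model (LCPM).** Planar positions
$\mathbf{y}_t$ follow a two-state AR(1) attractor process

$$\mathbf{y}_t \sim \mathcal{N}\left(\rho\,\mathbf{y}_{t-1} +
(1-\rho)\,\boldsymbol{\mu}_i,\ \sigma^2\mathbf{I}\right),\qquad
i = \begin{cases}1, & t < \tau\\ 2, & t \ge \tau\end{cases}$$

where the geographic centroid $\boldsymbol{\mu}_i$ — the only state-varying
quantity — shifts at the change point $\tau$. This captures an animal
relocating its core-use area.

**Movement-metric model (MMCPM).** Turning angles and step lengths derived
from the track follow state-specific distributions sharing the same single
change point:

$$a_t \sim \text{wrapped Cauchy}(\gamma_i, \kappa_i), \qquad
s_t \sim \text{Weibull}(\alpha_i, \beta_i)\ \text{or}\ \text{Exp}(\lambda_i).$$

This captures a switch to slow, tortuous movement (e.g. tending a neonate)
without any centroid shift.

In both models $\tau$ carries a **spike-and-slab prior**: a point mass at
$\tau = 0$ ("no change; one regime explains everything") mixed with a
uniform slab over candidate change times. A posterior mode of zero *is*
the non-detection conclusion. Samplers are Metropolis-within-Gibbs with an
exact categorical update of $\tau$ (O(T) per sweep via prefix/suffix sums),
conjugate updates where available, and adaptive random-walk Metropolis
elsewhere, compiled in C++.

The package also ships the trajectory simulator and assessment framework
for study-design questions (how long must post-event monitoring last, how
fine must the fix interval be, how large must the change be?): a-priori
success levels test whether the 95% CI (Level 1), 50% CI (Level 2) or
posterior median (Level 3) of the estimated change time falls within ±6 h
of the truth.

## Worked example

Simulate a track with a 1026 m centroid shift after 48 h (15-min fixes,
the strongest scenario of the packaged simulation study), fit the LCPM,
and assess the estimate against the known event:

```r
library(movecpt)

sim <- simulate_lcpm_track(shift = 1026, seed = 7)
fit <- sim$track |> center_locations() |> fit_lcpm(seed = 8)
fit
#> <LCPM> 385 locations, 10000 posterior draws
#>   change point: detected (posterior mode 199; P[tau = 0] = 0.000)

tidy(fit)
#> # A tibble: 7 x 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 mu1_x   -466.       50.3   -564.      -366.
#> 2 mu1_y     24.0      50.2    -74.9      123.
#> 3 mu2_x    516.       51.7    412.       617.
#> # ... with mu2_y, sigma, rho, tau

assess_fit(fit, tau_true = sim$tau_true, fix_minutes = 15)
#> # A tibble: 1 x 15
#>   category  mode q2.5_h q97.5_h width95_h ...
#>   <chr>    <int>  <dbl>   <dbl>     <dbl>
#> 1 Level 1    199      0    2.25      2.25
```

The model detects the change (spike probability 0.000), places its
posterior mode 6 fixes (1.5 h) after the true event at index 193, and the
95% credible interval of the change time spans [0, +2.25] h around the
truth — inside the ±6 h window, a Level 1 success. The recovered
centroids sit ~1000 m apart, matching the simulated shift (coordinates
are per-individual mean-centered, so the pair straddles the origin).

For the metric model: `compute_metrics()` derives steps and turning
angles, `fit_mmcpm()` fits them, and `autoplot()` draws the change-point
posterior. `run_grid(make_scenario_grid(), ...)` reproduces entire
study-design experiments (post-event duration, fix interval, magnitude of
change) and summarizes replicate outcomes with `summarize_run()`.

Real tracks enter through `read_tracks()` (CSV/TSV with `id`, ISO-8601
`timestamp`, planar `x`, `y` in metres), with `thin_to_interval()`,
`truncate_after()`, `window_event()` and `resample_linear()` for
preprocessing.

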