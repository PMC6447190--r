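---
title: "Speed-change discrimination for motion in depth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-change discrimination for motion in depth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedchange)
library(dplyr)
```

## The problem

An object approaching an observer at constant speed in the world does not
move at constant speed on the retina. The visual angle of a point at
lateral offset $x_w$ and distance $z_w$ is $\theta = \arctan(x_w / z_w)$,
so as $z_w$ shrinks the angular speed

$$\dot\theta = \frac{x_w\,v}{x_w^2 + z_w^2}$$

grows: constant world speed maps to *accelerating* retinal speed. Much of
the motion-in-depth literature instead uses constant *retinal* speed,
which corresponds to a decelerating object in the world. This package
implements a complete simulation-and-analysis pipeline for a 2IFC
speed-change discrimination study that compares the two stimulus regimes,
from the stimulus kinematics through synthetic observers, psychometric
fitting and repeated-measures statistics.

## Viewing geometry and trajectory placement

The scene is fixed by a `viewing_geometry()`: screen distance $D = 97$ cm,
refresh rate 85 Hz, a pair of vertical lines at world lateral offsets
$\pm x_w$, and an interpupillary distance of 6.5 cm for the per-eye
projections. Two of these constants deserve comment because they are
*recovered*, not given:

* **Line half-separation $x_w = 3.0$ cm.** Inverting the kinematics from
  the Fast standard interval's published onset/end retinal speeds
  (30.1 and 69.5 arcmin/s at 40 cm/s over 1 s) yields $x_w \approx 3.0$ cm
  (`recover_geometry()`); we fix this as the default.
* **Trajectory placement.** Start/end distances are chosen symmetric
  about the screen plane: total travel $d$ gives $z_0 = D + d/2$,
  $z_1 = D - d/2$, i.e. Fast 117→77 cm and Slow 107→87 cm. This placement
  uniquely reproduces the published per-condition speed landmarks and the
  117 cm starting distance, and it keeps the stimulus centred on the
  plane where disparity is zero.

```{r geometry}
geom <- viewing_geometry()
traj <- build_world_interval(speed_change_interval(40, 40), geom)
c(traj$z0_cm, traj$z1_cm)
trace_speeds(trace_retinal(traj, geom))
```

**Speed convention.** A "speed" at a time point is always the exact
instantaneous derivative above, converted once to arcmin/s
($\times 180/\pi \times 60$), never a frame difference. Ten of thirteen
published speed cells are reproduced to $\pm 0.1$ arcmin/s under this
convention; three cells (57.6, 121.4, 33.1) differ by up to 0.2,
consistent with the source values having been computed under a slightly
different (frame-based) convention. Positions are defined in continuous
time and sampled at frame onsets $i/85$ s; the step change happens at
exactly $t = 0.5$ s even though that instant falls between frames, so the
design's conservation properties hold exactly rather than to frame
precision.

## The speed-change design

Each trial presents a *standard* interval (constant speed for 1 s) and a
*variable* interval (speed $v_b$ for 0.5 s, then $v_a$), preceded by a
250 ms static image. The 7-level ladders (`level_ladder()`) step
$v_{b,k} = v_{std} - (k-1)s$, $v_{a,k} = v_{std} + (k-1)s$ with $s = 5$
cm/s (Fast) or 2.5 cm/s (Slow), so **every level travels the same total
distance in the same duration** — the observer cannot use distance or
duration cues, only the speed change itself. Task difficulty is indexed
by the proportion speed change at the changepoint,

$$\frac{c - b}{c},$$

with $b, c$ the retinal speeds immediately before/after the step
(denominator $c$, the post-change speed). For World stimuli both $b$ and
$c$ are evaluated at the same depth, so the proportion reduces to
$(v_a - v_b)/v_a$.

**Retina-condition speeds.** The constant-retinal-speed stimuli replace
each World level with a piecewise-constant trace. The standard's speed is
the time-averaged cyclopean World speed (total angular displacement over
duration, `derive_retina_speed()`: 45.74 arcmin/s Fast, 22.14 Slow).
Levels 2–7 use the per-half time averages of the matching World level,
which conserves total angular displacement across levels *exactly*; level
1 uses the whole-interval mean so the no-change interval coincides with
the standard. The source study's own published constants (47.6, 22.3,
7.6/87.4, …) are slightly higher than any averaging of the cyclopean
trace we tried; they are carried verbatim in
`published_speed_constants()` and in the config file so analyses can be
replicated against either set. The derived level-7 proportion speed
change (0.906) is within 0.01 of the value implied by the published
constants (0.913).

```{r ladders}
retina_speed_ladder("Fast")
```

## Synthetic observers and cohorts

An `observer_model()` answers each 2IFC trial correctly with probability

$$p(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - \alpha}{\sigma}\right),$$

with guess rate $\gamma = 0.5$ and lapse rate $\lambda = 0$ fixed (a
lapse up to 0.06 is exposed for sensitivity analyses). Trials are
independent Bernoulli draws — no learning or sequential effects, which
matches a no-feedback main experiment and keeps the generative model
identical to the fitted one.

`generate_cohort()` emulates a full study: 9 participants × 8 conditions
(World/Retina × main/Control × Fast/Slow) × 7 levels × 3 blocks × 10
trials. True thresholds are drawn per participant and condition from a
normal population truncated below at 0.01; defaults (means 0.30, between-
participant SD 0.08, observer spread $\sigma = 0.5\alpha$) sit inside the
0.20–0.37 range reported for speed-change tasks with naive observers.
Three scenarios fix the qualitative population pattern: `null` (all
conditions equal), `suppression` (Control means 0.7× main — lateral
motion easier than motion in depth), and `speed` (Fast 0.75× Slow for the
Retina pair only).

What the generator does *not* emulate: psychometric-model mismatch
(real observers lapse, drift, and are not exactly cumulative-normal),
block-order and fatigue effects, and correlations between a participant's
thresholds across conditions. Passing tests therefore certify the
pipeline's statistical machinery — calibration, bias, power at the
simulated effect sizes — not the behaviour of human data.

## Psychometric fitting

`fit_psychometric()` maximises the product-binomial likelihood of the
constrained model over $(\alpha, \log\sigma)$ (log-space keeps the spread
positive without constraints), initialised at the level whose empirical
accuracy first crosses 75% and at half the level range, refined by
Nelder–Mead (relative tolerance $10^{-12}$). With $\gamma = 0.5$,
$\lambda = 0$, the 75% threshold *is* $\hat\alpha$ — `threshold_75()` is
closed-form, not an inversion. Fits are pooled per condition (210
trials), matching the per-condition trial budget. Degenerate data — no
level above chance, or all levels perfect — are flagged non-identifiable
and the threshold reported as `NA`, never extrapolated; a spread
collapsing to a bound likewise voids convergence.

Monte-Carlo properties at the study's trial counts (7 levels × 30
trials), verified in the test suite: recovery of $\alpha = 0.30,
\sigma = 0.15$ over 500 replicates shows $|\mathrm{bias}| < 0.01$, and
the optimiser's likelihood meets or beats a 0.001-resolution grid search
on every random fixture tried.

## Statistics

The three planned comparisons are separate 2×2 within-subject ANOVAs
(`rm_anova_2x2()`): World vs Retina, World vs World Control, Retina vs
Retina Control, each crossed with Fast/Slow. Each effect is tested
against its own participant-by-effect interaction mean square with
$df = (1, n-1)$; no sphericity correction is needed for 2-level factors.
The reported effect size is partial eta squared,
$SS_e/(SS_e + SS_{err})$, which for these designs equals $F/(F + df_2)$.
Zero error variance yields an infinite $F$ with a warning rather than an
error. Between-condition error bars are t-based between-subject intervals
(95% by default; the level is configurable since figure captions often
leave it unstated).

`jzs_paired_bf()` gives a default Bayes factor for each family contrast:
a zero-centred Cauchy prior of width 0.5 on the standardised effect size
(the JZS prior), computed via the equivalent inverse-gamma mixture over
the $g$ scale — substituting $g = r^2 q$ makes the mixing density
parameter-free, so the 1-D adaptive quadrature (relative tolerance
$10^{-8}$) is stable for any prior width. This is deliberately a
*paired-contrast* Bayes factor: the model-averaged Bayesian RM-ANOVA used
by point-and-click software involves sampler-specific model averaging and
is out of scope; the JZS contrast is the transparent, reproducible
analogue.

```{r stats-demo}
trials <- generate_cohort(cohort_spec(scenario = "suppression", seed = 42))
th <- fit_thresholds(trials)
res <- planned_comparisons(th)
tidy(res$world_vs_control$anova)
res$world_vs_control$bf$bf10
```

## Calibration and power, and a known limitation

With null cohorts (i.i.d. normal cells) the ANOVA's type-I rate at
$p < .05$ is within Monte-Carlo error of 0.05 over 10,000 simulated
tables. Under the `suppression` scenario (Control 0.7× main, $n = 9$) the
World-vs-Control effect is detected in well over half of replicate
cohorts. The Retina-vs-Control contrast is reliably in the right
*direction* but has distinctly lower per-cohort power (~0.3): the Retina
conditions' proportion-speed-change ladder jumps from 0 at level 1 to
≈0.49 at level 2, so thresholds near 0.2–0.3 fall in a gap with no
stimulus support and are estimated with more noise. That is a property of
the study's own ladder design, not of the fitting code; simulations that
need more power there should raise the trial count or interpolate levels.

Other limitations: the per-eye channels of Retina-family stimuli are not
modelled (their speeds are defined directly at the retina; only the
cyclopean channel is produced); rendering concerns (pixels, luminance,
anti-aliasing) are entirely out of scope; and the published Retina speed
constants are reproduced as configuration values rather than derived,
since their exact averaging rule is not recoverable from the printed
values.

## Problem sizes used in the test suite

Deterministic kinematics are tested exactly. Monte-Carlo checks use 500
replicate psychometric fits, 10,000 null ANOVA tables, 100
random-fixture ANOVA comparisons against base R's `aov()` Error-stratum
decomposition, 40,001-point trapezoid grids for the Bayes-factor oracle,
and 12 replicate cohorts per scenario for the end-to-end pattern checks —
sizes chosen so the full suite completes in a few minutes while leaving
Monte-Carlo error well below each assertion's margin.
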