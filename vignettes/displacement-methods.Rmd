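---
title: "Models and methods for line-transect displacement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for line-transect displacement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Offshore wind farms may displace marine top predators from the habitat
inside and around the development footprint. A standard monitoring
design surveys a study area by boat along parallel line transects across
the development's phases (preconstruction, construction, operation) and
asks whether relative abundance inside the footprint changed between
phases. `marinedisp` implements that analysis end to end: segmentation
of survey logs into fixed-length effort units, hierarchical Bayesian
spatial count models, posterior prediction surfaces per phase, and
cell-wise change maps with a credible-interval overlap rule. A synthetic
survey generator with known ground truth makes every stage testable
without any field data.

# From survey logs to the modelling table

The raw inputs are GPS track points (one fix every 30 s), timestamped
sighting records, Beaufort sea-state records (start of each transect,
then every 15 min), a survey-to-phase lookup and the footprint polygon.
Coordinates are projected to UTM zone 30N with an in-package
Karney/Krüger-series transverse Mercator (exact to well below a metre
within the zone; validated against an independently coded series in the
tests).

Each transect's polyline is divided by cumulative chainage into
half-open intervals `[kL, (k+1)L)` with `L` = 600 m for the seabird
analysis and 1 km for the cetacean analysis. Decisions the field
protocol leaves open are resolved as follows and are part of the
package's contract:

* the final partial segment is retained with its true effort length and
  the model uses `log(effort / L)` as an offset, rather than discarding
  partial effort;
* a sighting exactly on a segment boundary belongs to the next segment
  (deterministic half-open tie-break);
* sighting positions are interpolated linearly in time between the
  bracketing fixes of the transect whose time span contains the record;
  records outside every span are excluded and counted;
* each segment takes the most recent sea-state record at or before its
  midpoint time (carry-forward, not interpolation), classed good
  (Beaufort 0-2) or poor (3-5);
* footprint membership of a segment or a prediction cell is decided by
  its midpoint/centre falling inside the polygon;
* encounter rates in the effort ledger are means over per-survey rates
  with a standard error across surveys, because a ratio of pooled totals
  does not define a dispersion. With a single survey the SE is reported
  as not available.

# The two count models

Counts per segment `y_i` are modelled as

* seabird: `y_i ~ NB(mu_i, theta)` with `Var = mu + mu^2 / theta`
  (mean-dispersion parameterization, stated explicitly because
  "negative binomial" alone is ambiguous);
* cetacean: `y_i ~ ZIP(mu_i, pi0_i)` with
  `P(0) = pi0 + (1 - pi0) exp(-mu)` and
  `logit(pi0_i) = gamma0 + gamma_cond [condition_i = poor]`. The binary
  part absorbs excess zeros from sampling error, availability (animals
  underwater) and detectability, the last being sea-state dependent.

Both share the count-part linear predictor

```
log mu_i = beta_phase(i) + f_phase(i)(x_i, y_i)
           + b_survey(i) + b_transect(i) + log(effort_i / L)
```

with preconstruction as baseline, a distinct two-dimensional smooth per
phase, and nested random effects (survey, transect within survey) that
absorb the spatio-temporal dependence between segments of one survey.
Month/season effects are not identifiable in this design (collinear with
phase) and are out of scope.

Reported contrasts are preconstruction vs construction
(`beta_con`), construction vs operation (`beta_op - beta_con`, a derived
quantity from the draws) and preconstruction vs operation (`beta_op`).
A contrast is called significant when its 95% credible interval on the
link scale excludes zero. Response-level columns are the elementwise
inverse link (exp, or inverse-logit for the zero part) of the raw
columns.

# The spatial smooth

Each phase smooth is a low-rank thin-plate radial basis: column `j` is
`eta(||s - kappa_j||)` with `eta(r) = r^2 log r` on `k = 25`
space-filling knots (farthest-point design over the observed segment
midpoints), plus unpenalized linear terms `(1, x, y)` carried in the
fixed effects. The penalty is the kernel Gram matrix on the knots, which
is positive semi-definite only orthogonally to degree-1 polynomials, so
penalized coefficients live in that null-space complement (projection
`N`). A sum-to-zero centering over the observed rows keeps the smooth
identifiable next to the phase intercepts; the discarded column means
are stored so predictions are reproducible. For sampling, the penalty is
diagonalized and absorbed into the design ("whitening"), giving iid
normal coefficients with one smoothing SD per phase smooth — the
Bayesian random-effects representation of a penalized spline. Distances
are computed in km for conditioning; the basis is translation-equivariant
by construction.

Default rank 25 per smooth resolves structure down to roughly the
2 km transect spacing over a 360 km^2 area while keeping desk-scale
fits fast; tests that need to localize a ~13 km^2 footprint dip raise it
to 30.

# Priors and sampling

Priors (proper, weakly informative): Normal(0, 10^2) on the intercept,
phase contrasts, linear smooth terms and zero-part coefficients;
half-Normal(0, 2^2) on the survey SD, transect SD and smoothing SDs;
Gamma(0.01, 0.01) on the NB dispersion `theta`.

The sampler is Hamiltonian Monte Carlo within Gibbs, written for this
model family:

* the HMC block updates all coefficients jointly under a *non-centred*
  parameterization — standardized smooth coefficients and random effects
  with iid N(0, 1) priors, multiplied inside the linear predictor by
  their group scales. Non-centring removes the funnel between
  coefficients and scales in the weak-signal regime, which this design
  (few surveys, modest counts) occupies;
* leapfrog integration with a jittered step count around `L = 10-12`,
  dual-averaging step-size adaptation (target acceptance 0.8) and a
  diagonal mass matrix estimated from a mid-warmup window;
* group scales and `theta` are updated by univariate slice sampling on
  the log scale; each scale update is interweaved (ASIS): a non-centred
  update against the data likelihood is followed by a centred update
  holding the natural-scale coefficients fixed, so mixing is good
  whether the data are weakly or strongly informative about the group;
* exact Gaussian Gibbs moves are made along the likelihood-invariant
  shear directions created by the nesting: a phase-level coefficient
  against a common shift of its surveys' effects, and a survey effect
  against a common shift of its transects' effects. These directions are
  the slow ridges of the posterior (e.g. intercept vs the mean survey
  effect) and the moves decorrelate them at negligible cost;
* the ZIP zero-inflation indicators are marginalized out of the
  likelihood so the posterior stays smooth;
* likelihood terms constant in the parameters are dropped (they cancel
  in Metropolis ratios and slice comparisons); the `theta` conditional
  accumulates `lgamma(y + theta)` over the tabulated distinct counts.

Defaults are 3 chains, 1,000 warmup and 1,000 retained draws per chain;
all randomness flows from one integer seed (per-chain seeds are derived
from it), and a fit is exactly reproducible given the seed. Convergence
is summarized by between-chain R-hat and effective sample size (via
`coda`) on the scalar reportable parameters; a fit with any monitored
R-hat above 1.1 is returned flagged `converged = FALSE` (degraded), not
discarded. Gradients of both likelihoods are verified against finite
differences in the test suite, and the pmfs are checked to normalize to
one.

# Prediction and the displacement rule

Prediction surfaces are population-level relative abundance: random
effects at zero, full nominal effort, and (for ZIP) good sea state. The
grid uses square cells with side equal to the segment length (0.36 km^2
or 1 km^2 cells) and is clipped to the convex hull of the surveyed
midpoints because radial smooths extrapolate poorly off-support. For a
pair of phases the change map reports the difference of posterior means
and flags a cell when the two phases' marginal 95% credible intervals
are disjoint. This is deliberately the literal interval-overlap rule:
it is conservative relative to a test on the per-cell difference (two
non-overlapping 95% intervals imply far more than 95% confidence in the
difference), and the difference-CrI variant is exposed as
`change_map(..., method = "difference")` without claiming either is the
original study's choice. Footprint summaries average member cells per
draw and summarize across draws.

# The synthetic generator

`scenario_config()` defaults encode the monitored design: ten parallel
north-south transects, 18 km long, 2 km apart (20 km x 18 km = 360
km^2), a centred 3.6 km x 3.6 km (~13 km^2) footprint, a vessel at 5 m/s
with a 30 s fix interval, sea state from a persistent Markov chain on
Beaufort 0-5 recorded at transect starts and every 15 min, and 24/16/21
surveys in the three phases (the per-phase effort of a representative
decade-long monitoring programme at ~180 km per survey). Latent log-intensity surfaces
are drawn once per species and phase from a squared-exponential Gaussian
process (SD 0.5, range 5 km — smooth hotspots a rank-25 spline can
track), and each surface is centred to mean zero over the species'
segment midpoints so that phase intercepts remain identified; an
optional shared-surface mode gives a spatially stable population for
null and displacement scenarios. Displacement enters as a multiplicative
intensity factor inside the footprint per phase;
`displacement_scenario(base, r)` sets the construction factor to
`1 - r`.

Species effect sizes (`beta` contrasts of -0.5/-0.9, `theta = 2`,
`gamma0 = -1`, `gamma_cond = 1.2`, survey/transect SDs 0.15/0.10) are
test settings chosen for desk-scale statistical power, not estimates of
any real system; real encounter rates for the cetacean are an order of
magnitude lower than these defaults. Sightings are emitted as
timestamped records with group sizes of `1 + Poisson(0.7)` placed
uniformly within their segment's time window, so the analysis exercises
the same time-interpolation path as real data; a configurable fraction
of extra in-flight seabird records exercises the behaviour filter.

What the generator does *not* emulate: animal movement and vessel
avoidance, double counting between transects, tidally driven
availability, heterogeneous detection with distance (the analysis is
explicitly of relative, not absolute, abundance), and real group-size
distributions. Passing recovery tests therefore demonstrates that the
pipeline estimates what the generative model defines, not that the model
is adequate for any particular field system.

# Test and validation problem sizes

The replicated studies in the test suite use scaled survey programmes so
a full run stays desk-sized: recovery replicates use the full ten-transect
layout with 9 km (seabird; 900 segments) or 6 km (cetacean; 360
segments) transects and two surveys per phase, 2 chains x (600 warmup +
400 draws), and check that 95% CrIs cover the generating contrasts and
the sea-state coefficient in at least 80% of 20 replicates. The
displacement study uses eight surveys per phase, a shared surface, equal
phase intensities and a 70% construction-phase reduction inside the
footprint, 30 knots, and requires a significant negative footprint cell
in the preconstruction-construction map and none in the
preconstruction-operation map in at least 80% of 10 replicates. The
surface-shape check uses a scenario with pronounced spatial structure
(log-scale surface SD 1) because rank correlation against a nearly flat
surface realization measures noise, not fidelity.

# Numerical choices and edge cases

* Sub-millimetre terminal slivers from floating-point chainage are
  folded into the previous segment so efforts partition the polyline
  exactly.
* Knot placement rejects `k` larger than the number of distinct
  midpoints; coincident knots are rejected.
* Penalty eigenvalues are floored at `1e-10` of the largest before
  whitening; eigenvalues below `-1e-8` (relative) abort basis
  construction.
* A zero-mean prediction cell makes the SD/mean uncertainty ratio
  undefined; such cells are flagged rather than silently dropped.
* `exp(0.0005)` and similar near-zero contrasts are reported at full
  precision internally; rendered tables round to 3 decimals and counts
  use thousands separators.

# Known limitations

* The zero part of the ZIP model carries only an intercept and the
  sea-state condition — no phase or spatial terms — so phase effects on
  detectability are absorbed by the count part.
* The interval-overlap change rule is conservative; cells with real but
  modest change will not be flagged at desk-scale effort.
* The convex-hull clip leaves no predictions beyond the surveyed
  envelope; the method says nothing about displacement outside it.
* With two surveys per phase the survey-level SD is weakly identified;
  its posterior is prior-influenced, which is why it is monitored in the
  diagnostics rather than reported as an effect.
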