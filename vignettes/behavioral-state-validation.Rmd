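---
title: "Validating behavioral-state inference against known dyadic events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating behavioral-state inference against known dyadic events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tendr` asks a simple question with an involved answer: when two GPS-collared
animals of opposite sex are demonstrably together, do the space-use and
movement-state models that ecologists fit to *one* animal's track show
anything distinctive at those times? This vignette documents the models, the
tunable parameters, the synthetic data used to test everything, and the
design decisions taken where several defensible choices existed.

## The dyadic ground truth: interaction events

Given two tracks from the same study area, `align_dyad()` pairs fixes whose
timestamps differ by at most `tolerance` seconds (default 300 s). Nominal
schedules are hourly, but acquisition drifts by minutes; 300 s accepts that
drift while never pairing fixes from different nominal slots. Matching is
globally nearest-in-time with each fix used at most once, so the result is
symmetric in the two animals.

`detect_events()` implements the two-threshold delineation rule:

* paired fixes at distance &le; `dist_threshold` (100 m) are *close*;
* successive close fixes separated by more than `gap_hours` (2 h) start a new
  candidate event, so a far excursion strictly longer than two hours splits
  events, while shorter far stretches are absorbed into the event;
* a candidate is kept if it contains at least `min_run` (2) consecutive close
  fixes *and* its mean distance over all event fixes (close and absorbed far
  ones) stays &le; the distance threshold.

The mean-distance acceptance check resolves an ambiguity in the verbal rule
"within 100 m on average": we require both a sustained close run and a
per-event average within the threshold, which is the only reading consistent
with allowing 2-hour far gaps inside one event. `detect_events()` is tested
against an independent brute-force oracle (transitive closure over close
fixes plus an exhaustive window scan) on randomized distance series.

The dynamic interaction statistic is computed per simultaneous step as
`DI_t = cos(θ_a − θ_b) · (1 − (|d_a − d_b|/(d_a + d_b))^α)` with `α = 1`.
Two conventions handle degenerate steps: both animals stationary scores 1
(perfectly matched rest), exactly one stationary scores 0. An event's
`mean_DI` is the arithmetic mean over its steps, computed on raw paired
fixes (not regularized estimates), and `conservative_filter()` retains
events with `mean_DI` strictly above 0.5. DI is invariant to translating or
jointly rotating both tracks, and bounded in [−1, 1]; both properties are
tested.

## Space-use route: Brownian bridges and volume contours

`fit_motion_variance()` estimates the Brownian motion variance σ²ₘ
(m²/h — time is in hours throughout) by leave-one-out likelihood: every
second interior fix is scored under the bridge spanned by its neighbours,
whose per-coordinate variance is α(1−α)T·σ²ₘ + ((1−α)² + α²)δ², with δ the
GPS error SD (10 m, fixed, matching collar field testing). Whether the
even- or odd-indexed fixes are scored is configurable (`leave_out`); the two
differ negligibly and the default is `"even"`. The 1-D likelihood is
maximized by bounded search on the log scale. On a single triplet with
δ = 0 the estimator has the closed form r̄²/(α(1−α)T), which the test suite
checks to 1e-6; simulation recovery at 500 hourly fixes and the deer-scale
value σ²ₘ = 10⁴ m²/h achieves a mean absolute relative error well inside
15% across seeds (individual seeds fluctuate by a few percent; the
leave-one-out construction also carries a small upward bias of order
2δ²·(α(1−α)T)⁻¹, negligible at this movement scale).

`compute_ud()` rasterizes the UD at `cell_size` 30 m: each bridge's
bivariate normal law is evaluated at `n_integration` (10) equally spaced
interior time points, bridges are weighted by duration, and the grid is
renormalized. The grid pads the track's bounding box by
`buffer = max(300 m, 3.5 × max bridge SD)` so clipped mass is negligible
(a warning fires if a user-supplied buffer is smaller). Contributions are
truncated beyond six SDs from each integrand mean purely for speed; at the
default resolutions the truncation error is far below the 1e-6 mass
tolerance asserted in tests. Long gaps can be excluded with `max_lag`; the
default keeps every bridge because the analysis contract makes no claim
about gap handling.

`ud_volume()` is the percent-volume transform: cells ranked by density,
each cell assigned 100 × the cumulative mass of all cells at least as
dense; tied densities share one inclusive value, matching the
"greater than or equal" contour semantics. This makes the UD mode the cell
with the minimum volume and the p% contour the cells with volume &le; p.
`volume_at()` uses half-open cells `[edge, edge + cell)`, so a point on a
shared edge belongs to the cell on its upper side; points outside the grid
return `NA` with a warning rather than failing, since events can in
principle wander outside a phase-specific grid.

## Movement route: regularization and hidden Markov models

HMMs need regularly spaced locations. `interpolate_hourly()` produces them
with a deterministic Gaussian smoother: at each observation time the true
position estimate precision-weights the observed fix (variance δ²) against
the Brownian-bridge prediction from its neighbours (variance α(1−α)T·σ²ₘ,
using the animal's own fitted motion variance); hourly times between
observations take the bridge conditional mean between the smoothed
endpoints. With δ = 0 this reduces to exact linear interpolation, and as δ
grows each estimate moves monotonically toward the neighbour interpolant —
both tested. This smoother deliberately replaces a Bayesian continuous-time
functional movement model with the same contract (hourly posterior-mean
locations under 10 m error): it is deterministic, dependency-free, and the
downstream HMM consumes only the hourly point estimates, so posterior
spread would be discarded anyway. No uncertainty is propagated into the
HMM, and hourly points inside observation gaps longer than `max_gap`
(12 h) are flagged `imputed` rather than dropped.

`make_series()` turns hourly locations into step lengths and turning
angles (signed azimuth differences wrapped to (−π, π], positive = left
turn; angles are undefined at the series start and next to zero-length
steps). `fit_hmm()` then maximizes the joint forward log-likelihood — the
sum over individuals, each entering with the stationary initial
distribution of the shared transition matrix — directly with BFGS on an
unconstrained working scale: log step means and SDs, logit zero-step mass,
the angle mean as a (κ cos m, κ sin m) pair recovered by `atan2` (which
also encodes log-free κ ≥ 0 as the pair's length), and multinomial-logit
transition rows. Emissions are zero-inflated gamma steps — the point mass
at zero is needed because GPS data genuinely contain zero steps where the
gamma density is undefined — and von Mises angles (density written from
`besselI`; the sampler in the test harness uses Best-Fisher rejection).
Multi-start (default 25 seeded perturbations of a data-driven start; the
pipeline uses fewer since the data-driven start is reliable there) guards
against local optima, and states are relabelled by ascending step mean so
reports never label-switch. `viterbi_decode()` computes the exact joint-MAP
path in log space with ties broken toward the lower state index.

Correctness anchors: the forward likelihood and Viterbi path are tested
against exhaustive enumeration over all state paths at T &le; 8; parameter
recovery at 2,000 simulated steps returns means and SDs within 15% and
transition probabilities within 0.05, with decoding accuracy above 90%.

## The evaluation layer

All hourly locations between an event's start and end (inclusive) are event
locations. The UD route summarizes, per event and sex, the volume of the
cell under each of that animal's event fixes — averaging over fixes, so a
cell crossed twice counts twice (the alternative, averaging over unique
cells, is ambiguous when events revisit cells; per-fix averaging weights
time, which is what a detection rule would see). The HMM route summarizes
the decoded state mix per event and its modal state (ties to the lower
index).

`consistency_report()` condenses both routes into the patterns a successful
detector would show: the span of event-location volumes with a threshold
sweep over v ∈ {5, …, 95} (fraction of locations ≤ v under the male/core
convention and ≥ v under the female/periphery convention), and a
modal-state agreement index (largest fraction of events sharing one modal
state) with the mean within-event majority proportion. The threshold sweep
and agreement index are artifact extensions — they operationalize patterns
that are otherwise judged from histograms — and the reports label them as
summaries, not tests. A *usable* volume threshold must be selective as
well as inclusive: capturing 95% of event locations below v = 95 is
vacuous, so the acceptance analyses require a capturing threshold to sit
in the core half (≤ 50%) for males or the periphery half (≥ 50%) for
females before calling the UD route successful.

Because agreement can be high for trivial reasons (one state may dominate
the whole decoded sequence), `modal_agreement_permutation()` provides the
missing null reference: windows with the observed events' lengths are
placed at random positions in the decoded sequence 999 times and the
agreement recomputed. Only an observed agreement in the upper tail of that
null indicates a genuine event signature.

## What the generator emulates — and what it does not

`scenario()`/`simulate_pair()` produce hourly fixes for one dyad over a
9-week season with 10 m GPS error. Both animals follow discrete
Ornstein-Uhlenbeck home-range dynamics (attraction 0.05/h, diffusion SD
100 m/h), chosen so season-scale 95% contours are on the order of 1-3 km²
and hourly displacements around 100 m — realistic deer scales, set once as
defaults and not validated quantities. Scheduled events place one event in
each equal block of the season with log-normal durations (median 7 h,
truncated to [1, 79] h, matching the observed range of real MFIE
durations). During events the male is tethered to the female through an
AR(1) offset with stationary SD 25 m and coefficient 0.95. The slowly
drifting tether matters twice over: it keeps the dyad within 100 m
(P &ge; 0.99, tested) *and* keeps the male's displacement vector aligned
with the female's, so that genuinely tending pairs score high DI — an iid
offset of the same size would add ~35 m of fresh noise to every step and
make even perfect tending look incoherent at this movement scale.

The three modes separate the two things a detector might key on:
`cohesive-distinct` scales the pair's step SD by 0.5 during events
(proximity *plus* a movement change; 0.5 keeps steps large enough that DI
survives measurement error while remaining clearly distinct),
`cohesive-null` leaves the female's movement untouched so the tethered
male's marginal step distribution matches his non-event hours (verified by
two-sample tests across seeds) — proximity with *no* signature, the
configuration that reproduces the negative result in silico — and
`stationary-female` parks the female with the male orbiting within 50 m.
All randomness flows from one scenario seed through fixed per-stage
sub-seeds (schedule, female path, male path, GPS error), so any stage can
be regenerated independently and outputs are bit-identical per seed.

What the generator does not emulate: habitat or landscape structure,
multi-male competition for the same female, fix loss and irregular duty
cycles, hunting-induced behavior change, or heavy-tailed step
distributions. Passing tests therefore demonstrate internal correctness
of the pipeline and the logical structure of the positive/negative
controls, not that real deer behave like the generator.

## Problem sizes, numerics, degenerate inputs

The test suite and acceptance analyses run at desk scale chosen for
coverage per compute: detector oracles on 100 random 20-fix series;
exhaustive HMM enumeration at T &le; 8; motion-variance recovery at 500
fixes over 20 seeds; HMM recovery at 2,000 steps over 5-10 seeds with 2
optimization starts; full-season evaluations (1,512 hourly fixes per
animal) for two seeds per mode with a 999-permutation baseline. Numerical
choices worth knowing: the σ²ₘ search runs on the log scale with interval
tolerance 1e-8; non-finite gamma densities during HMM line searches are
treated as zero likelihood rather than errors; empty dyad overlap yields an
empty series, not an error; duplicate timestamps within an animal are a
validation error naming the animal; events outside a regular track's span
are an error, while fixes outside a volume grid are reported as missing.

## Known limitations

The smoother is a point estimator — no multiple imputation, no
uncertainty propagation into the HMM. The HMM shares all parameters across
individuals (no random effects), fits no covariates on transitions, and
deliberately performs no model selection between 2 and 3 states: both are
fit and reported, since state-count selection is unreliable for these
models. The UD/volume machinery produces contour masks, not polygon
geometry, and the package performs no coordinate reprojection — inputs
must arrive projected in meters because every threshold is metric.
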