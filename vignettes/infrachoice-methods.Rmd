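---
title: "Methods: infrasound-informed movement decisions in albatrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrasound-informed movement decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infrachoice)
```

## The question and the modelling strategy

Wandering albatrosses commute over thousands of kilometres of open ocean
with few visual landmarks. Microbarom infrasound — the quasi-continuous
0.06–1 Hz signal radiated where counter-propagating ocean waves interact —
travels far enough to be a plausible long-range cue for sea state and wind.
`infrachoice` asks whether, at the moments a bird commits to a bout of
directed flight, it preferentially heads into the direction where received
sound pressure is high, over and above its response to the wind it is
experiencing.

The analysis is a matched discrete-choice design. Each qualifying flight
bout contributes one *decision point*: the disc of 2,000 km radius around
the bird is tiled into six 60° sectors, the sector containing the realised
bearing is the chosen alternative, and the other five are the available but
unchosen alternatives. Conditioning on exactly one choice per stratum gives
the conditional-logit likelihood, which cancels everything that is constant
within a decision point — including overall soundscape loudness, weather,
season, and the bird itself. This is why sector sound pressure must be
z-standardised *within* the choice set and why wind speed (identical for
all six sectors) can enter only through interactions.

## Behavioural segmentation

The three movement modes are modelled as a hidden Markov chain over fixes at
15-min intervals with gamma step lengths and von Mises turning angles —
the standard emission families for this kind of telemetry. Fitting is direct
numerical maximisation of the scaled forward likelihood under working-scale
transforms (log for step shape/scale and turn concentration, a half-angle
tangent for the turn mean, multinomial-logit rows for the transition
matrix), with random restarts; the initial distribution is tied to the
stationary distribution of the transition matrix, which is appropriate for
tracks that begin mid-behaviour. Decoding is by Viterbi with ties broken
toward the lower state index. States are mapped to behaviours by ranking
mean step length (fast = travel, slow = rest), with each state's turning
concentration reported as a sanity check: travel should be by far the most
concentrated. Steps below 1 m are floored to 1 m so the gamma density stays
finite, and gaps longer than twice the nominal interval split the series
into independent likelihood segments.

## Decision points and sector covariates

Pipeline constants (all configurable in `run_config()`):

| parameter | default | units | role |
|---|---|---|---|
| `depart_km` | 10 | km | trip starts at first departure beyond this |
| `buffer_km` | 10 | km | shelf buffer trimmed from trip ends |
| `min_bout_km` | 20 | km | minimum within-bout path length for a decision point |
| `radius_km` | 2000 | km | sector radius; chosen because sources within it dominate the received signal |
| `aperture` | 60 | degrees | sector width; must divide 360; `aperture_sensitivity()` sweeps it |
| `match_tol_h` | 1 | h | max gap between a fix and its soundscape field |

"At least 20 km" is read as cumulative within-bout path length, not net
displacement, and the bout must follow a search or rest fix — a travel run
that opens the trip has no observed decision context and is excluded. The
shelf buffer is a distance to a configurable shelf centre point. A decision
point whose sectors intersect land (tested on the cells of the integration
grid against the land mask) is excluded rather than integrated over a
truncated disc, keeping the six alternatives comparable.

Sound pressure is computed on a spherical polar grid centred on the bird
(default 100 radial × 120 azimuthal cells to 2,000 km; cell areas are exact
cap-area differences, so they sum to the closed-form disc area). Received
pressure from each source is `A (r_ref/r)^γ 10^(−α r / 20000)` with
spreading exponent γ = 1 and absorption α = 1 dB/1,000 km by default — a
deliberately simple single-path propagation law that produces the long-range
spatial gradient the choice analysis needs, in place of full atmospheric
duct modelling. Only this propagating component is represented; the
evanescent near-field component, detectable only above the source, is
excluded. All computation is in pascals; decibels (re 20 µPa) are for
display only. The sector integral is the un-normalised area-weighted sum
(Pa km²); since the values are z-scored within the choice set immediately
afterwards, the normalisation convention cannot affect the fit, and the
z-scores are invariant to any gain or offset in the raw field. The sample
(n−1) standard deviation is used; a degenerate all-equal choice set maps to
all zeros. Wind covariates use the vector-heading convention
("direction-to"), so a relative wind direction of 0° is a pure tailwind —
this sign convention is what makes a negative `windDir` coefficient mean
"prefers tailwinds". Wind is evaluated at the bird, not per sector, because
wind speed is treated as stratum-constant.

## The choice model and its inference

`choice_fit()` maximises the conditional-logit likelihood by Newton
iterations with step halving from the null start β = 0 (the likelihood is
concave; convergence is declared at gradient norm < 1e−8, and a coefficient
pushed beyond ±8 on standardised covariates triggers a separation error
naming the column). `windDir` and `windSp` are centred and scaled by their
global mean and standard deviation over all rows before interactions are
formed (the scaling constants are stored in the fit for prediction and
audit); sound pressure enters as its within-stratum z-score. The naive
covariance is the inverse observed information; the robust covariance sums
per-stratum scores within each bird before forming the sandwich, which is
what "decision points clustered within bird identity" means operationally.
QIC uses the trace penalty `tr(Î V̂ᵣ)` (inverse naive covariance times
robust covariance), which collapses to the parameter count K when clustering
is ignorable, and QIC weights are the usual `exp(−Δᵢ/2)` normalisation.
Concordance counts, over the five (chosen, unchosen) pairs per stratum, the
fraction in which the chosen sector has the strictly larger linear
predictor, ties (within 1e−12) counting one half. Because wind speed is
constant within strata it is rejected as a main effect at design-build time.
Sexes are fitted separately (`sex_stratified_run()`), since sex, like any
stratum constant, cannot be estimated within the matched design.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions: 15-min fixes; three states
ordered travel/search/rest with gamma mean steps of 10, 3 and 0.3 km per fix
and turn concentrations 8.5, 0.7 and 1.5 (κ = 8.5 puts the central 90% of
travel turning angles at roughly ±0.56 rad, the shallow turning that defines
directed flight); a persistent transition matrix; a Crozet-like colony; a
10 m/s westerly wind field with smooth, divergence-free perturbations from
sinusoidal streamfunction modes (speeds capped at 3× the mean); and four
drifting storm-like sources of 0.05 Pa (at the 100 km reference distance)
drifting at 30 km/h. Storms are compact isotropic sources — a point
approximation of a Gaussian amplitude bump, adequate because the analysis
only needs a spatially structured pressure gradient, not wave-interaction
source physics. At each entry into the travel state the generator draws the
new heading's sector from the conditional-logit law with the configured
coefficients (β = SP 0.3, windDir −0.4, SP:windDir −0.2, SP:windSp 0.15,
windDir:windSp −0.25, on the fitter's covariate scale), and the bout's first
step leaves exactly along the chosen sector's centre — so the extractor's
focal sector coincides with the generator's chosen sector by construction.

Passing tests on these data show that the pipeline recovers a known
selection process embedded in realistic movement noise. They do not show
that real albatross tracks satisfy the model's assumptions: real tracks have
irregular sampling, wind-drifted rest periods, behavioural states that are
not cleanly gamma/von Mises, and a soundscape whose source physics
(wave-interaction spectra, bathymetry, ducted propagation) is far richer
than the spreading law used here. Quantities that depend on those real-data
properties — expert-agreement percentages, real QIC tables and odds ratios —
are therefore not targets for the synthetic study.

## Numerical choices and degenerate inputs

* Earth model: sphere of radius 6371.0088 km; haversine distances;
  forward-azimuth bearings, degrees clockwise from true north.
* Sector membership: half-open bearing interval [centre − a/2, centre + a/2)
  so the six sectors tile the disc; the origin (bearing undefined) belongs
  to the focal sector by convention.
* Turning angles: counterclockwise (left) positive, wrapped to (−π, π].
* Field/fix matching: nearest hourly field within 1 h, ties to the earlier
  field; unmatched decision points are dropped with a logged reason.
* Ties in longest-trip selection go to the earlier trip; ties in Viterbi go
  to the lower state index.
* Coincident consecutive fixes make the bearing undefined: such bouts are
  skipped with a warning rather than guessed.
* The 100 × 120 integration grid was convergence-tested: doubling the
  resolution moves smooth-field sector integrals by well under 1%.

## Problem sizes and validation design

The test suite validates each stage against an independent oracle: law-of-
cosines distances and `geosphere` for the geometry, exhaustive path
enumeration for the HMM forward likelihood and Viterbi (all series up to
length 6 with 2–3 states), a 10⁻³-step grid search for the conditional-logit
MLE, and `survival::clogit` (Breslow ties, which are exact for one case per
stratum) for coefficients and cluster-robust standard errors. Calibration
uses 100 replicate studies of 60 birds × 30 decision points — large enough
that robust CIs are in their asymptotic regime, small enough that the whole
suite runs in minutes on one CPU; the bundled end-to-end demonstration uses
6 birds × 5 days of simulated track. Realised coverage of nominal-95%
robust CIs at these sizes scatters binomially around 95 of 100 (standard
deviation ≈ 2.2 replicates), so individual replicate counts in the low 90s
or high 90s are expected behaviour, not miscalibration; the ±3 SE coverage
criterion (≥ 95/100) and the ~5% type-I error of the likelihood-ratio test
are the stable summaries.

## Known limitations

* The propagation law is parametric (spreading + linear absorption), with no
  stratospheric duct, wind-dependent asymmetry, or bathymetry.
* Transition probabilities are covariate-free; three states are assumed, not
  selected.
* The shelf buffer is a circular approximation around a centre point.
* One trip per bird (the longest) is analysed; repeated trips would need an
  extra clustering level.
* Global (not per-sex) scaling constants are used for `windDir` and
  `windSp`; the scaling report in every fit makes the alternative auditable.
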