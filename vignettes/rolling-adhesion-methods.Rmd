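---
title: "Quantifying spheroid rolling adhesion under ascitic shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid rolling adhesion under ascitic shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measurement problem

Ovarian cancer disseminates through the peritoneal cavity: multicellular
cancer-stem-cell spheroids (70–100 µm across) are carried by ascitic flow
over the mesothelial lining and must tether, roll and firmly adhere to it
before invading. Ascitic wall shear stress is low — on the order of
0.03–0.15 dyn cm⁻², at least tenfold below vascular levels — so the
adhesion biology resembles leukocyte rolling on selectins more than it
resembles firm integrin capture. The measurement instrument is a
parallel-plate microfluidic channel whose floor carries a mesothelial
monolayer: fluorescently labeled spheroids are perfused at a controlled
wall shear stress and imaged at one frame per second for 30 s per field
of view, and every transiting spheroid is assigned one of four behaviors.

`rollflow` implements that assay end to end as testable code: channel
hydrodynamics, a stochastic bond-kinetics simulator that stands in for
the raw videos, spheroid detection and tracking on rendered image stacks,
motion classification, and the cohort statistics used to compare
conditions.

## Hydrodynamics

For a wide rectangular channel (width $w$ much larger than height $h$)
the wall shear stress follows the plane-Poiseuille relation

$$\tau = \frac{6 \mu Q}{w h^2},$$

with viscosity $\mu$ (0.9 cP by default, the viscosity of the binding
buffer and within the measured range of ascitic fluid) and volumetric
flow rate $Q$. `wall_shear_from_flow_rate()` and `flow_rate_from_shear()`
are exact inverses; all internal computation is CGS/SI and interfaces use
the assay's units (dyn cm⁻², cP, µm, µL min⁻¹).

A non-interacting spheroid close to the floor translates at

$$u_h = k_\mathrm{wall}\,\frac{\tau}{\mu}\,\frac{d}{2},$$

the linear-shear fluid velocity at its center height scaled by a
near-wall drag correction. The default $k_\mathrm{wall} = 0.5676$ is the
classical translation factor for a sphere in contact with a plane wall
in shear flow; $k_\mathrm{wall} = 1$ (the undisturbed fluid velocity) is
available because the assay's "hydrodynamic velocity" is not defined more
precisely than "the speed of a free spheroid". At
$\tau = 0.05$ dyn cm⁻², $\mu = 0.9$ cP, $d = 85$ µm this gives
$u_h \approx 134$ µm s⁻¹ — a free spheroid crosses a 3.3 mm field in
about 25 s, which is why a 30 s acquisition catches essentially every
transit.

Channel cross-section and field size are not fixed by the assay
description; the defaults (1000 × 100 µm channel, 3.3 × 2.5 mm field,
matching a 4× objective) are plausible PDMS-chip values and everything
downstream reads them from the geometry object.

## The synthetic cohort generator

No raw perfusion videos are available, so the generator produces
trajectories (and optionally rendered stacks) with the statistical
structure the analysis assumes. Each spheroid enters the upstream field
edge at a random frame and transverse position and evolves by a
discrete-time Markov chain at the 1 s frame interval over
{free, tethered, rolling, adherent}, with per-interval transition
probability $1 - e^{-k\,\Delta t}$ from competing exponential rates:

* free → tethered at the bond-formation rate $k_\mathrm{on}$;
* tethered → free at $k_\mathrm{rel} + k_\mathrm{off}(\tau)$,
  tethered → rolling at $k_\mathrm{on}$ (rolling is sustained
  re-engagement of new bonds at the formation rate),
  tethered → adherent at $k_\mathrm{arrest}$;
* rolling → free at $k_\mathrm{off}(\tau)$, rolling → adherent at
  $k_\mathrm{arrest}$;
* adherent is absorbing at assay-scale shear.

The tether-scale off-rate is a two-pathway catch–slip law with shear as
the force proxy,

$$k_\mathrm{off}(\tau) = a\,e^{-\tau/f_c} + b\,e^{\tau/f_s},$$

which produces the signature of a catch bond: capture is inefficient
below a threshold shear (fast catch-pathway rupture), peaks at an
intermediate shear, and declines again as the slip pathway and the
shorter field residence time take over. The assay reports its capture
optimum at 0.05 dyn cm⁻² within the 0.03–0.15 dyn cm⁻² sweep, so the
default rates were calibrated once — semi-analytically, then confirmed
with one simulation sweep — to put the adhesion argmax there, and then
frozen. **All kinetic rates are calibration artifacts of this package**:
no rate constants are available for the real spheroid–mesothelium
system, and none of the defaults should be read as measured biology.

Free spheroids advance $u_h \Delta t$ per frame, rolling spheroids
$\rho\,u_h \Delta t$ ($\rho = 0.3$ by default, putting rolling
velocities in the few-tens of µm s⁻¹ range), and stationary states get
Gaussian positional jitter (σ = 1 µm) so the stationarity threshold has
something realistic to reject. Arrival counts default to a Poisson draw
tied to the suspension density (1500 spheroids mL⁻¹ × field throughput);
analyses override them with explicit counts because the density-derived
default yields very few arrivals per field at these low flow rates.

Firm adhesion is multivalent: many engaged bonds share load. A single
catch–slip law cannot simultaneously suppress capture at
0.1–0.15 dyn cm⁻² and let firm bonds survive to several dyn cm⁻² in a
detachment ramp, so ramp-driven rupture of the adherent state uses a
separate, much slower slip law
$k_\mathrm{off}^\mathrm{firm}(\tau) = b_f\,e^{\tau/f_{s,f}}$, with
per-step survival $e^{-k_\mathrm{off}^\mathrm{firm}(\tau)\,t_\mathrm{hold}}$.
The defaults give complete detachment only near the 4 dyn cm⁻² ramp end;
the EDTA mode (calcium chelation abolishes selectin bonds) multiplies
off-rates by 10³ and zeroes $k_\mathrm{on}$, collapsing survival at the
first ramp steps, below 1 dyn cm⁻².

Two generator modes exist deliberately. The mechanistic chain above is
the default; `simulate_cohort_from_probs()` is a scripted mode whose
track-level class probabilities are exact inputs, used to validate the
measurement pipeline against known generative fractions (optionally with
`exact_fractions = TRUE`, which fixes class counts at their expectations
so the validation isolates measurement error from the multinomial
sampling coin).

What the generator does **not** emulate: margination and vertical
dynamics, spheroid deformation or disaggregation, receptor-level bond
mechanics (individual bond positions, torque balance), mesothelial
monolayer texture, and photobleaching. Passing tests therefore show the
analysis is correct *given* the assay's own model of the data, not that
the biology is as modeled.

## Detection, tracking, rendering

Rendering draws each spheroid as a 2D Gaussian spot whose FWHM equals
its diameter, on a constant background with Poisson photon noise, 16-bit,
at 3.25 µm px⁻¹ by default (a 4× objective with 2×2 binning; a 70 µm
spheroid is ~22 px across). Detection is median background subtraction,
Otsu thresholding floored above the background noise, and watershed
labelling on the masked intensity so spheroids passing close to each
other are split at their intensity saddle. Diameters are estimated from
the integrated spot mass with a truncation correction
($M = 2\pi\sigma^2 P$ above a threshold fraction $t$ leaves mass
$M(1-t)$), which is far less biased at the 70/100 µm gate edges than a
thresholded-area estimate; the assay's size gate then discards
components outside 70–100 µm. Deeply overlapping spheroids (centers
closer than about one σ) coalesce into a single intensity peak and are
irrecoverable in principle; at the assay's densities (≲ 10 per field)
this costs a few percent of links.

Linking is greedy nearest-neighbor between consecutive frames with a
flow-directional gate (downstream advance within
$[-d,\ 1.5\,u_h\,\Delta t]$, lateral within one diameter) and one missed
frame of memory. Because a free spheroid moves 1–3 diameters per frame
at 1 fps, raw positional distance is a poor cost; the cost is the
distance to the nearest of three motion hypotheses — stationary, free
convection at $u_h$, and the track's last observed velocity — which
links free transport, rolling and arrest without identity switches in
practice.

## Motion classification

The behavioral definitions are operationalized with precedence
**adhesion > rolling > tethering > free**, making the four classes a
partition of the cohort:

* **adhesion** — at least `min_stationary_frames` (2) consecutive
  observed frames with per-frame displacement below ε = 5 µm,
  persisting to the end of the track's observation (an "anywhere-arrest"
  variant exists behind a flag);
* **rolling** — a maximal contiguous run of intervals all below
  $c\,u_\mathrm{ref}$ whose summed path exceeds one track-median
  diameter; the rolling velocity is the mean speed over the qualifying
  run with the longest path;
* **tethering** — at least one sub-threshold interval followed by a
  return to at least $c\,u_\mathrm{ref}$ (transient capture and
  release);
* **free** — none of the above.

$u_\mathrm{ref}$ is the free-transport reference velocity: analytic
($u_h$ at the cohort median diameter) or empirical (90th percentile of
all observed per-interval speeds, robust to a minority of interacting
tracks). The threshold fraction $c$ defaults to 0.5, the
leukocyte-rolling convention; $c = 1$ reproduces the literal "below the
hydrodynamic velocity" reading but misclassifies free spheroids at 1 fps
with noise. ε = 5 µm per frame is ~6% of a spheroid diameter and five
times the simulator jitter. Cohort percentages divide class counts by
the total number of spheroids that transited the field during the 30 s
acquisition, pooling counts (never percentages) across fields;
single-frame tracks count toward the denominator by default, with the
exclusion policy behind a flag, because the assay's counting rule for
spheroids visible in a single frame is not specified.

Ground-truth track classes are derived from the latent states by the
same observational rules (a spheroid stationary through the end of
recording is adherent regardless of what it would have done later), so
classifier validation measures measurement error, not censoring
semantics. An exhaustive brute-force segment-scan oracle re-implements
the rules independently in the test suite and agrees with the
implementation on 100% of 1000 randomized speed patterns.

## Statistics

Categorical outcomes (adherent vs not, tethered vs not) are compared by
Pearson chi-square without continuity correction (the Yates variant is a
flag); rolling velocities by the classical pooled-variance one-tailed
unpaired Student t (Welch behind a flag); shifts are reported as median
fold changes, with a Katz log-ratio interval available for proportion
ratios. Significance labels use strict thresholds: `ns` ≥ 0.05, `*`
< 0.05, `**` < 0.01, `***` < 0.001. No multiple-testing adjustment is
applied by default, matching per-comparison reporting practice for this
assay; a Holm adjustment can be applied by the user. Degenerate inputs
are explicit: zero-variance equal-mean samples give p = 0.5 by
convention (flagged), zero marginals are errors, and empty cohorts
produce a flagged empty summary rather than division by zero.

## Numerical and design choices

* Problem sizes: validation runs use 300–800 spheroids per shear level
  (2 fields of 150–400), 3 rendered fields of 8 spheroids for the
  imaging round trip, and 50 adherent spheroids per detachment ramp —
  large enough that binomial noise does not mask the effects under test,
  small enough to keep every analysis interactive.
* Seeds: one master seed per experiment; per-field and per-condition
  child streams are derived with a fixed integer map so sub-experiments
  are independently reproducible. Identical configuration and seed give
  byte-identical tables.
* Tie-breaks: when several rolling runs qualify, the longest path wins;
  ramp schedules always end exactly at the maximum shear; the last
  linking hypothesis update uses the most recent observed interval.
* Degenerate inputs: zero shear is allowed (no transport, warning);
  single-frame tracks classify as free and are flagged; detachment with
  an indestructible firm bond returns survival ≡ 1.

## Known limitations

The simulator's two-pathway catch–slip parameterization is the minimal
standard form with shear as a force proxy — it reproduces the assay's
qualitative optimum, not measured kinetics. Tracking is not a
multi-hypothesis tracker: permanently co-travelling spheroids merge.
The classifier sees only 1 fps centroids, so sub-second tether events
are invisible by construction, and the tethering/rolling boundary
inherits the path-length threshold of one diameter. None of the
package's outputs should be compared quantitatively to the original
assay's cohort counts; the reproducible claims are the structural ones
(capture optimum location, detachment ordering, fold-change directions,
statistical machinery).
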