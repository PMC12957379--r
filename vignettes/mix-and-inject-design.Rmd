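---
title: "Designing segmented-droplet mix-and-inject experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing segmented-droplet mix-and-inject experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixinject)
```

Time-resolved serial femtosecond crystallography (TR-SFX) with
mix-and-inject sample delivery initiates an enzymatic reaction by mixing a
microcrystal slurry with a substrate solution a defined time before the
crystals cross the X-ray beam. Segmented droplet injection wraps the mixed
aqueous stream into oil-separated droplets so that crystal-laden liquid
reaches the interaction region only when X-ray pulse trains arrive, cutting
sample consumption by an order of magnitude. `mixinject` implements the
quantitative machinery a beamline scientist needs to design and diagnose
such an experiment: reaction time points from device geometry and flows,
the diffusive mixing model and its time spread, the pulse-train-spanning
droplet-volume condition, a triggered droplet-synchronization simulator
with waterfall diagnostics, and sample-consumption accounting.

## Reaction time points

A mixer/droplet-generator device is modelled as three channel sections. In
section A (length $A$, aqueous cross-section) the crystal stream $Q_X$ and
substrate stream $Q_S$ co-flow and mix by diffusion; in section B the oil
stream $Q_O$ joins and forms droplets; section C is the remaining device
and capillary to the nozzle orifice. With mean velocities $v = Q/S$ per
section (aqueous flow $Q_{aq} = Q_X + Q_S$ in A, total flow
$Q_T = Q_{aq} + Q_O$ in B and C), the reaction time point is

$$t_R = t_A + t_B + t_C, \qquad t_i = L_i \, S_i / Q_i.$$

Droplet slugs in the capillary are assumed to travel at the section mean
velocity $Q_T/S$, and acceleration by the focusing gas inside the nozzle is
excluded — $t_R$ ends at the orifice. The two shipped presets use a section
C of 15.4 mm of 100 µm bore capillary; device drawings elsewhere quote the
capillary as "2 cm", but only the 15.4 mm figure is consistent with the
published per-section residence times at the stated flows, so the presets
adopt it.

```{r residence, eval = FALSE}
dev <- preset_device("DG300-Y")
fl <- flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3)
glance(residence_breakdown(dev, fl))
#>   device    t_A    t_B   t_C   t_R
#> 1 DG300-Y 0.792 0.0200 0.378  1.19
```

One published table entry does not reproduce exactly: for the faster
device at $Q_T = 28.1$ µL/min the capillary residence time computes to
0.2583 s where 0.259 s is printed; all seven other entries agree at the
printed precision. The package reports the computed value.

## The mixing model

Mixing in section A is transverse diffusion across a laminar co-flow.
The solver integrates the parabolized advection–diffusion equation

$$u(y)\,\frac{\partial c}{\partial x} = D\,\frac{\partial^2 c}{\partial y^2}$$

with the plane-Poiseuille profile $u(y) = 6 \bar v (y/w)(1-y/w)$, zero-flux
walls, and a step inlet: substrate at $c_0$ above the interface position
set by the flow split under the parabolic profile (cumulative flow fraction
$3\eta^2 - 2\eta^3$, solved by bisection). Axial diffusion is dropped; this
is valid for Péclet numbers $\bar v w / D \gg 1$ and the solver refuses
below $Pe = 50$ (the DG300 operating point sits near $Pe \approx 800$).
The axial march is implicit (backward Euler in $x$), which makes the
scheme unconditionally stable; the step matrix is an M-matrix, so the
march preserves positivity and the bound $0 \le c \le c_0$, and with
trapezoidal quadrature the advective flux $\int u c \, dy$ is conserved to
round-off. The default grid is 512 × 257 nodes over 528 × 150 µm; halving
both spacings moves the equimolar distance by well under 5%, and the
plug-flow variant of the march agrees with the closed-form
complementary-error-function profile to an RMS below 0.1% of $c_0$.

Substrate diffusivities are tabulated in water; the working liquor (18%
PEG 3350, measured viscosity 5.39 mPa·s) is far more viscous, so
diffusivities are rescaled by the Einstein relation
$D\,\eta = D_\mathrm{ref}\,\eta_\mathrm{ref}$ with water taken as
1.00 mPa·s at room temperature. For NADH
($D_\mathrm{ref} = 6.7\times10^{-6}$ cm²/s) this gives
$1.2\times10^{-6}$ cm²/s.

Mixing is deemed complete for a crystal where the surrounding substrate
concentration reaches the protein concentration inside the crystal (the
equimolarity criterion; 23 mM for NQO1, an input parameter whose
space-group derivation is out of scope). Because crystals of ~20 µm cannot
approach the wall closer than their size, the criterion is evaluated on a
line 20 µm from the crystal-side wall. The streamline spread of the
initiation time over the mixing distance $L$ follows from the velocity
ratio between the centerline, $u(w/2) = 1.5\bar v$, and the offset line:

$$\Delta t_m = \frac{L}{u(y_\mathrm{offset})} - \frac{L}{u(w/2)},$$

and the total initiation spread adds the intra-crystal diffusion time
(~15 ms for shoebox crystals) and is expressed as a fraction of $t_R$.

### What the single-phase model does and does not capture

The model covers the co-flowing aqueous streams only. In the real device a
droplet pinches off at the oil junction, and the associated two-phase
vortex convects substrate toward the crystal side of the channel ("upward
concentration drift"). That drift is what brings the 20 µm offset line to
equimolarity within section A in full two-phase simulations and in
fluorescence imaging; pure transverse diffusion at
$D = 1.2\times10^{-6}$ cm²/s cannot do so over 528 µm (the substrate would
have to diffuse ~60 µm in ~1 s, against a diffusion length of ~16 µm).
`equimolar_distance()` therefore faithfully reports "not reached" for that
configuration, and the derived mixing distances are approximations
whenever pinch-off drift matters. The streamline velocity-ratio analysis
(2.16 between centerline and the 20 µm line) is geometry-only and agrees
with the published residence-time ratio (0.363 s / 0.161 s = 2.25) within
5%. Two further published numbers are deliberately not reproduced: the
5.6 ms spread quoted for the faster device does not follow from a
center-versus-offset computation over section A with the stated
quantities, and neither does the projected 46 ms spread for a shortened
mixer; `mixing_spread()` stays generic instead of being tuned to either.

## Droplets and pulse trains

The European XFEL delivers trains of $n$ pulses spaced by $\Delta$
(202 × 1.77 µs here) at 10 Hz. The train duration is taken as
$n\Delta = 357.5$ µs (not $(n-1)\Delta$; the distinction is below the
rounding in use). While jetting, a droplet stretches into a rod of the jet
radius $r$ (default 5 µm) moving at the jet velocity $v_j$ (default
25 m/s), so spanning the train requires

$$V_\mathrm{min} = \pi r^2 v_j \, n\Delta \approx 700\ \mathrm{pL},$$

with no end-cap correction. Note the rod length itself is
$v_j\, n\Delta \approx 8.9$ mm. Droplet volumes follow from the flow
balance $V = Q_{aq}/f$: 2.5 nL at 1.5 µL/min and 10 Hz, comfortably above
the threshold (margin ≈ 3.3).

## Synchronization simulator

The droplet generator is abstracted as an integrate-and-fire oscillator:
pinch-off recurs with mean period $1/f_0$, Gaussian period jitter
(default SD 2 ms), and optional slow drift. The electrical trigger is a
phase-resetting capture, not an electro-hydrodynamic model: when a
scheduled firing lies within the capture half-width (default 20 ms) of a
trigger onset (reference tick + delay), and the amplitude reaches the lock
threshold (default 150 V), the firing is reset to the trigger onset,
zeroing accumulated phase error. Sub-threshold amplitudes capture with
probability amplitude/threshold, which reproduces the observed qualitative
ladder — 180 V locks immediately, 110 V locks intermittently, 40 V fails
to hold lock, 0 V free-runs. These defaults are behavioral calibrations,
chosen once so the ladder ordering emerges; they are not measurements of
the electrode physics.

Diagnostics mirror beamline practice: the detector trace (or event series)
is folded into 100 ms reference windows and stacked into a waterfall
matrix; each window's phase is the first droplet time modulo the window;
lock is flagged where the rolling circular SD over 5 windows drops below
1 ms. Detector traces are synthesized as rectangular pulses plus Gaussian
noise at a default 10 kHz sampling rate (the real digitizer rate and pulse
shape are not public; both are parameters), and event detection is a
rising-edge threshold crossing with a refractory hold-off equal to the
pulse width. The per-pulse hit rate uses patterns / (trains × pulses per
train); for 1631 patterns over 2018 trains of 202 pulses this gives 0.40%.

Simulated runs in the test-suite and acceptance script use 60 s of events
(600 reference windows) and 30 s ladder segments — long enough for locked
fractions to stabilize, short enough to keep the whole suite under ten
seconds. Triggered scenarios start the oscillator near the trigger phase,
mirroring the experimental start-up procedure in which triggering is
activated only after droplet generation has stabilized near the target
rate; a cold-started oscillator instead reaches lock by random-walking
into the capture window, which takes tens of seconds at 2 ms jitter —
also the behavior the sub-threshold regimes show.

## Sample consumption

Only the crystal stream counts as sample: a run consumes
$V = Q_X \times$ time, yielding indexed patterns per µL (reported rounded
to integers, with the exact ratio retained) and protein mass
$V \times c_\mathrm{protein}$. The comparator is a continuous gas-focused
jet at the same total flow rate for the same duration, so for equal
durations the savings reduce to flow ratios:

$$\mathrm{savings} = 1 - Q_X/Q_T,$$

83% at the 0.3 s operating point and 97% at the 1.2 s point. The
published protein-mass column is not exactly reconcilable with its own
flow, duration, and concentration inputs (3.35 mg computed vs 3.2 mg
printed for the fast point; 1.09 mg vs 1.7 mg for the slow point, which
likely aggregates runs at other flow rates); `consumption_report()`
computes strictly from its inputs.

## Synthetic data

`make_scenario()` generates every input the package's tests consume:
locked, free-running (10.2 Hz), intermittent, and amplitude-ladder event
series with traces and hit series, and an analytic plug-flow erfc field
for solver validation. Hit series gate on droplet phase: only windows
whose first droplet sits within 5 ms of the trigger delay can score a
Bernoulli hit. All bundles are bit-for-bit reproducible from
(scenario, seed). The generator emulates phase behavior and detector
signals, not beam or crystal physics: real hit rates are orders of
magnitude lower than the default Bernoulli probability, real detector
pulses are not rectangular, and real jitter need not be Gaussian —
passing tests validate the diagnostics pipeline, not those physical
details.

## Known limitations

* Flows are inputs; no pressure-driven flow or capillary compliance.
* Mixing is single-phase and 2D with the plane-Poiseuille profile; the
  full rectangular-duct series solution would change the 20 µm offset
  velocity by under 10% and is not used.
* The trigger model is behavioral; it cannot predict which amplitudes
  lock a new device, only reproduce regimes around a given threshold.
* Structural outcomes (occupancies, resolutions, electron density) are
  entirely outside the package's scope.
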