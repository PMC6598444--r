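---
title: "The mtpattern model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mtpattern model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtpattern` simulates a rate-based network from primary visual cortex (V1)
to the middle temporal area (MT) in which the balance of three V1 input
streams — not a hierarchy within MT — determines whether MT units signal
*component* motion (each oriented element's aperture-limited direction) or
*pattern* motion (the coherent global direction of a plaid-like stimulus).
This vignette documents the model equations as implemented, the parameters
that matter, the synthetic stimuli, the numerical choices, and the design
decisions that were genuinely open.

## Stimuli

The reference stimulus is a pair of dark bars on a white background,
slanted ±45° from horizontal and moving horizontally in opposite
directions, so that their crossing point — the *extrinsic terminator* —
moves straight upward. Human observers perceive the occluded version of
this stimulus (bar ends hidden) as a single pattern moving up.

Defaults (chosen once as the study conditions; the source model reports no
stimulus dimensions): a 64×64 lattice, bar length 40, width 3, contrast 1,
speed 0.5 lattice steps per frame, 32 frames at `dt_frame = 0.01` time
units. Bars are rendered with hard edges; sub-pixel displacement
accumulates and is rounded per frame. Overlapping pixels take the darker
luminance (a "saturated" crossing), or the low-contrast bar's luminance
when contrasts differ (it is perceived in front). A speed of 1 step/frame
would be equally natural but drives the bars out of a 64-px frame before
the recurrent MT dynamics (hundreds of Euler steps, below) can settle;
0.5 steps/frame keeps the crossing inside the frame for the whole movie.

Occlusion of the intrinsic terminators ("pattern" preset) restricts the
*simulated field* to a rectangular window around the crossing that excludes
every bar end in every frame. All V1 interactions (motion-energy filtering,
the end-stopped inhibition sums, the ECRF surrounds) are computed on the
full, unoccluded frames and only then cropped to the window. Cropping the
luminance first would cut the bars at the window border and fabricate new
line ends, which the end-stopped population would misread as intrinsic
terminators — the very signal occlusion is meant to remove.

## V1 stage

**Complex cells.** Classical opponent motion energy: per orientation, a
quadrature Gabor pair (carrier along the motion axis, frequency
`f = 1.1` cyc/deg, isotropic envelope σ = 0.5°, sampled at `px_per_deg = 4`
lattice steps per degree) is combined with two multi-stage temporal
filters

$$g_n(t) = (t/\tau_g)^n e^{-t/\tau_g}
  \left[\tfrac{1}{n!} - \tfrac{(t/\tau_g)^2}{(n+2)!}\right],
  \qquad n = 6 \text{ (fast)}, \; 9 \text{ (slow)},\; \tau_g = 0.01,$$

into four separable space-time responses; the two direction-selective
quadrature pairs are squared, summed, opponent-subtracted, and rectified.
The kernel `g_n` is zero at `t = 0` and changes sign at
`t = τ_g·√((n+1)(n+2))` (≈ 0.075 for n = 6). Energies are normalized by the
peak response to a full-contrast calibration drifting bar and scaled by
`energy_gain = 0.3`, so a high-contrast edge drives a complex cell to
roughly 0.15 and the strongest 2-D features to ~0.3. This calibration
places edge drive just above the end-stopped gating threshold
(`c_cx = 0.12`) and leaves headroom for the recurrent MT competition; it is
the model's only free scale, fixed once (the source equations treat the
complex activity as a bounded quantity without printing its scale).
Convolutions zero-pad beyond the lattice; temporal filtering is causal with
zero history. One speed tuning only.

**End-stopped cells** follow the shunting equation
`dv/dt = (1−v)(G_escx1·v_cx) − v(τ_es + G_escx2·Γ)` with `Γ` a
discretized-Gaussian weighted sum (patch ±4, σ = 2, unit peak, centre
excluded) of same-direction complex activity, gated per location: `Γ` is
nonzero only where the maximum complex activity over the inner ±3
neighbourhood exceeds `c_cx`. The printed summation bounds of the source
(±8 patch described as "8×8", inner condition ±3) are inconsistent; we use
a ±4 inhibition patch with the ±3 gate, both configurable. Along an
extended edge the neighbourhood sum is large and the cell is silenced; at a
line end half the patch is empty and activity survives. With a weak drive
(a crossing whose same-direction neighbours sit below `c_cx`) the gate
stays closed and the cell relaxes to the shunting fixed point
`G¹v_cx/(G¹v_cx + τ_es)` — effectively saturating for any appreciable
input, which is what makes terminators, not edges, the dominant V1 output.

**ECRF cells** convolve the *reversed* luminance `I = background − frame`
with oriented difference-of-Gaussians kernels (centre `A_C = 1`, surround
`A_S = 0.72`; σ values per the constants table, in degrees), saturate the
result to [0, 1], and are recomputed per frame (the defining equation has
no dynamics, so the population is memoryless). Their surrounds integrate
dark area: at the crossing of two bars the surround is doubly stimulated
and the cell is suppressed, while along isolated edges and at true bar ends
it stays active. The motion gate `κ` passes complex activity only where the
ECRF cell of the orientation orthogonal to the motion direction is active
(`> 10⁻⁶` rather than `> 0`, for float robustness) — so `κ` silences the
motion signal exactly at the extrinsic terminator.

## MT stage

Two populations per lattice site and direction, integrated jointly by
forward Euler with `dt = 0.01`:

$$\Delta v^{ig} = dt\,\big(G_{igcx} v^{cx} + G_{iges} v^{es}
 + G_{igig2}\,\lambda + G_{igcs}\,\kappa
 - G_{igig1}\,\gamma(t{-}T_{ig}) - G_{igig3}\,\zeta(t{-}T_{ig})
 - G_{igsg} v^{sg} - \tau_{ig} v^{ig}\big)$$

$$\Delta v^{sg} = dt\,\big(G_{sgcx} v^{cx} - G_{sges} v^{es}
 + G_{sgig}\,\eta + G_{sgsg1}\,\chi_e - G_{sgsg2}\,\chi_i
 - \tau_{sg} v^{sg}\big)$$

followed by saturation of the *activity* to [0, 1]. The source prints the
saturating function around the derivative itself; taken literally that
makes the derivative non-negative and activity could never decay, so we
follow the function's stated role ("constrains the level of activity
between 0 and 1") and clamp the updated state instead. The delay
`T_ig = 0.1` (10 steps) applies to γ and ζ only, with a zero-initialized
ring buffer.

MT receptive-field *areas* are 7× the V1 RF area (surrounds 10×), so
kernel diameters scale with √7 and √10 of the nominal V1 RF diameter
(`v1_rf_px = 5`), giving a centre radius ≈ 6.6 and surround annulus out to
≈ 7.9 lattice steps. The lateral terms are threshold-gated kernel sums
(only units above `c_ig`/`c_sg` contribute):

* λ — same-direction integration activity under the Gaussian centre kernel
  (σ = radius/2, self excluded), total weight `lambda_mass = 2.65`;
* γ — *inter-directional* inhibition: delayed activity of the other seven
  directions pooled over the centre neighbourhood, total weight
  `gamma_mass = 0.4` (uniform weighting; cosine available);
* ζ — delayed same-direction activity over the surround annulus, total
  weight `zeta_mass = 0.35`;
* η — integration activity summed over all directions under the centre
  kernel (unit weight), driving segmentation cells;
* χₑ/χᵢ — segmentation surround activity in the same/opposite direction
  (unit weight).

The source model defers the functional forms of λ, γ, ζ, η, χ to its
predecessor and prints only their roles, so their kernel shapes and total
weights are design decisions of this package. Three of them deserve
comment. (1) γ pools over the centre neighbourhood rather than acting
purely at a point: for terminator-driven activity to "win over the other
directions" as it propagates, the inter-directional competition must reach
across the MT receptive field; with a strictly local γ a unit already
saturated in a component direction could never be challenged by upward
activity arriving nearby, and dominance could not spread. (2) The weights
were chosen once so that the network sits in the bistable regime the
described behaviour requires: λ strong enough that a contiguous region of
upward activity recruits its neighbours (total weight ≳ 2.5 at these
kernel sizes), yet weak enough that a 3-px-wide ribbon of component
activity is *not* self-sustaining without feedforward support; γ placed so
that the κ contribution (`G_igcs` high vs. low) decides whether component
ribbons survive the upward wave. (3) ζ is kept small — long-range
same-direction inhibition acts against propagation, and its annulus
geometry punishes the spreading (2-D) pattern signal roughly threefold
relative to ribbon-shaped component activity, so a large ζ forbids exactly
the propagation the model exists to show; its role here is to temper
runaway spread, not to contain it completely.

## Simulation protocol

`simulate_network()` steps the end-stopped and MT populations once per
movie frame with the time-varying V1 drive, then holds the final frame's
drive and continues for `n_settle` further steps (default 2500 in the
experiment drivers) so the recurrent dynamics reach steady state; final
maps are the mean of the last 10% of steps, which damps residual
oscillation from the delayed inhibition. The full run for the standard
experiments is 2532 Euler steps of 0.01 time units on the occluded window
(≈ 23×37 lattice); a 3×3 gain sweep shares one V1 front end across its
nine MT runs and completes in a few minutes on one CPU. The network is
fully deterministic given the stimulus and configuration.

## Pattern index

Ideal templates are unit activity over the stimulus footprint in the
pattern direction (up), and over each bar's footprint in that bar's
aperture direction (up-left/up-right). For each sweep cell the summed
absolute deviation between the final integration map and each template is
computed *over the template's footprint*; the deviations are min-max
normalized over the sweep ensemble (`S = 1 − N(D)`), and
`P_I = S_P − S_C`. Absolute deviation makes the sum a distance (a bare
difference would let over- and under-shoot cancel); footprint restriction
keeps the measure about stimulus coverage — recurrent activity also spreads
somewhat beyond the stimulus, and penalizing that spread cancels the
coverage signal almost exactly, leaving the statistic dominated by
round-off. The normalization ensemble is the full gain grid of one
experiment; the contrast experiment normalizes all its sweeps jointly so
pattern indices are comparable across contrast pairs. A degenerate
ensemble (all deviations equal, e.g. a 1×1 sweep) maps every deviation to
`S = 1` with a message.

The end-stopped confinement statistic measures the distance from
supra-threshold (half-peak) end-stopped activity to the junction's overlap
region across all frames: the terminator is an extended image feature, and
end-stopped activity outlives the moving junction (τ_es = 0.01 gives a
decay constant of ~100 time units), so its trace marks where the
terminator has been.

## What the synthetic stimuli do and do not show

The generator emulates the geometry that matters to the mechanism —
oriented dark bars, their aperture-limited edge motion, intrinsic
terminators, and an upward-moving crossing — plus contrast asymmetry. It
does not emulate sinusoidal gratings or additive plaids, luminance noise,
multiple speeds, or natural-image statistics; passing tests therefore show
that the implemented mechanism produces the described selectivity regimes
on bar stimuli, not that it quantitatively matches primate physiology.
Time is a single abstract unit: the source model itself notes that its
small integration step rescales the temporal axis, so crossing times and
delays are meaningful relative to each other, not in milliseconds.

## Known limitations

* The regime boundary depends on the motion-energy calibration
  (`energy_gain`) and the interaction weights; these were fixed once
  against the described behaviours and are exposed in the configuration
  rather than hidden, but other stimulus families may need recalibration.
* No switching between integration and segmentation configurations, no
  MST/V4 feedback, no attention, one speed tuning — all outside scope.
* Upward activity in the pattern regime spreads somewhat beyond the
  stimulus footprint (nothing in the wiring ties the propagating signal to
  the luminance pattern once the ECRF gate is bypassed); the footprint-
  restricted pattern index is the honest summary under that behaviour.
* On a 1-CPU machine the full acceptance run takes on the order of ten
  minutes; larger lattices scale roughly with the FFT cost of the
  per-step convolutions.
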