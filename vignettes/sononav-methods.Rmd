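---
title: "Modeling acoustic microbubble-swarm navigation in vessel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acoustic microbubble-swarm navigation in vessel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sononav)
```

## The physical picture

Lipid-shelled, gas-filled microbubbles (1.1–1.4 µm) circulating in blood
respond to a 490 kHz ultrasound field in two ways. Secondary Bjerknes
forces pull oscillating bubbles toward each other, so a small responding
fraction (about 3% of the injected population) aggregates into clusters of
1–40 µm. Primary radiation force then pushes each cluster along the
direction of wave propagation with a force proportional to the cluster's
volume. Clusters settle against vessel walls, where Poiseuille flow is
slowest, and the volume-scaling of the radiation force against the
diameter-scaling of Stokes drag lets sufficiently large clusters hold
position or move upstream. Turning the field off disassembles the
clusters within a frame interval.

`sononav` models this chain — field, per-vessel response, swarm dynamics,
activation planning — on vessel graphs extracted from images or generated
synthetically.

## Per-vessel response model

Each transducer is treated as a **point source**: the wave reaching a
vessel travels along the line from the element's center to the vessel's
arc-length midpoint. A vessel is summarized by its distance `r` to the
source and the incidence angle `α = arccos |u·w|` between that line `u`
and the endpoint-to-endpoint vessel axis `w`. The point-source convention
(rather than the face normal) reproduces the observed radial away-motion
on the frustum rim, where trajectory azimuths sit exactly 180° from the
transducer azimuths; the face-normal alternative is selectable.

The speed model is multiplicative:

$$v(\alpha, r, V) = v_0\, g(\alpha)\, (r_0/r)^n\, (V/V_0)^q.$$

* **Angular law** `g(α) = (1 + 2cos²α)/3`. Only the two endpoints of the
  angle–velocity relation are available as anchors (1.2 mm/s head-on,
  0.4 mm/s parallel, a 3:1 ratio). This smooth form hits both exactly, is
  strictly decreasing, and needs no fitted parameter. The shape between
  the endpoints is an interpolation choice, not a validated fit — a
  cosine-power alternative is available behind the `angular_law` key.
* **Distance law** `(r0/r)^n`, `n = 2`: the inverse-square law for a point
  source. The package also fits effective exponents from (distance, speed)
  pairs by log–log regression; the measured channel pair (32.2 µm/s at
  2.15 mm, 2.8 µm/s at 15.25 mm) yields an effective exponent ≈ 1.25,
  i.e. shallower than 2, consistent with additional material damping on
  top of geometric spreading. The model default remains 2; the fitting
  routine documents the discrepancy rather than resolving it.
* **Voltage law** `(V/V0)^q`, `q = 2`: radiation force scales with acoustic
  intensity (pressure squared), and pressure is proportional to drive
  voltage. The speed–voltage relation is an assumption of this package —
  only the size–voltage relation is anchored by observation.
* A **near-field guard** rejects `r < 0.1 mm`, where the point-source
  scale diverges.

Skull transmission is plain amplitude arithmetic on a measured
depth–pressure profile (100 kPa beneath the skull, 85 kPa below the pia,
70–80 kPa in the 0.5–0.6 mm two-photon band, tapering to the 16 mm
measurement extent). Both the amplitude convention `p/p_ref` and the
energy convention `(p/p_ref)²` are exposed: the energy fraction at the
pia is 0.7225, but applied to the imaging band it gives 0.49–0.64, which
sits below the claimed "more than 70% of energy" if that claim is read as
squared-amplitude at depth. The discrepancy between conventions is
documented, not resolved; `transmitted_fraction()` lets the caller pick.

## Swarm dynamics

`dynamics_params()` collects the tunables (units in parentheses, defaults
in brackets):

| parameter | meaning |
|---|---|
| `v_min_vpp` (V_PP) [20] | formation threshold: no swarms below it |
| `size_slope_um_per_vpp` (µm/V_PP) [0.25] | median cluster size per drive volt |
| `d_cap_um` (µm) [40] | largest observed cluster diameter |
| `growth_rate_per_s` (1/s) [0.05] | logistic growth rate |
| `u50_mm_s`, `width_mm_s` (mm/s) [5, 2] | formation-sigmoid midpoint and width |
| `responder_fraction` [0.03] | fraction of injected bubbles that respond |
| `attach_flow_max_mm_s` (mm/s) [4] | flow ceiling for wall attachment |
| `kappa` [4] | von Mises concentration of directional noise |
| `sigma_log` [0.5] | log-sd of the cluster-size sampler |

The slope 0.25 µm/V_PP puts the median cluster at 8.75 µm for the 35 V_PP
working point — inside the observed 3–15 µm majority band — and gives the
observed exact halving of cluster size from 40 to 20 V_PP (any uncapped
linear law halves; the anchor fixes the scale). The growth rate 0.05 1/s
puts saturation on the minutes timescale of the observed growth curves;
no rate is printed, so this is a package default. The formation sigmoid
(midpoint 5 mm/s, width 2 mm/s) makes formation common below ~2 mm/s and
rare near the 10 mm/s ceiling; its parameters are package defaults chosen
once, not fitted.

**Growth saturation.** The logistic update `d ← d + k d (1 − d/d_sat) dt`
defaults to `d_sat = max(median size at V, current d)`. The growth
scenario at 44 V_PP (`dynamics_params("growth44")`) instead saturates at
the 40 µm cap: the observed growth curves track the upper envelope of
cluster sizes, which plateaus at the largest observed cluster rather than
at the median size–voltage law. This is a deliberate reading of two
individually-anchored but mutually-inconsistent observations (median
linear in V vs. growth to 40 µm at 44 V_PP); both anchors are kept, each
in its own scenario.

**Force balance.** The net velocity combines advection at the local
Poiseuille speed (sampled one swarm radius off the wall when attached,
at the centerline when free) with the radiation slip
`F_rad/(3πμd)`. The radiation coefficient `C` is a **runtime calibration**
to the headline upstream anchor (1.5 µm/s for a 10 µm swarm in a 30 µm
venule against 10 mm/s centerline flow at 35 V_PP); the vertical-channel
variant is likewise anchored (165.1 µm/s downward at 10 V_PP for a
mid-band 1.25 µm bubble, with buoyancy from the gas-filled sphere and
Stokes rise when the field is off). These are anchorings, not
predictions: the model then predicts how speed varies around the anchor
(with `d²`, with `V²`, with angle and distance). Because the balance
scales as `d²`, exact size-independence of upstream speed — which was
observed — is *not* reproduced; the package documents this tension and
asserts only order-of-magnitude stability across the 3–15 µm band.
Viscosity defaults: blood 3 mPa·s in vivo, water 1 mPa·s in vitro; the
calibration makes the anchor speeds independent of this choice.

**Wall attachment.** Newly formed swarms attach to the wall only where
the centerline flow is below `attach_flow_max_mm_s` (4 mm/s): above it,
wall shear sweeps clusters along before they can anchor. Combined with
the synthetic networks' faster arterial flows, this reproduces the
observed pattern that flow-independent navigation happens in veins and
venules, while arterial clusters advect downstream.

**Directional noise.** Per-swarm heading noise is von Mises with
concentration κ about the away-from-source direction, sampled with a
Best–Fisher rejection sampler written for this package (no circular-
statistics package is assumed) and verified in tests against numerical
integration of the von Mises density. At the default κ = 4 the mass on
the away half-plane is ≈ 0.99, comfortably above the observed "at least
80% move away".

## Synthetic networks and phantoms

The generators are pure functions of spec + seed and define the study
conditions:

* **cylinder** — one straight 400 µm channel; nine transducers, eight on
  the side wall at axial offsets `R/tan α` chosen to reproduce the
  documented incidence-angle set {22.5°, 45°, 67.5°, 90°} (the exact
  angular positions are inferred from the device figures, not printed),
  plus one on top aligned with the channel (α = 0).
* **frustumB** — a plus-shaped network of 400 µm channels with two side
  spurs in the frustum midplane; 18 transducers in two rows of nine at
  heights 3 and 6 mm. The 40° azimuthal spacing is an even-spacing
  assumption (counts and heights are documented, spacing is not).
* **invivo_like** — two quasi-planar trees (venous and arterial) grown by
  binary branching at leaves, so every interior node is a detectable
  branch point (no degree-2 pass-through nodes, which no skeleton can
  recover). New segments must clear all non-adjacent segments by at least
  three tube diameters — the non-degeneracy condition under which lattice
  round-trips are exact. Terminal branches draw diameters uniformly
  (venous 10–20 µm, arterial 10–13 µm) and interior trunks follow
  Murray's law (cubes add at bifurcations).
* **flows** — terminal edges take `u = m·d` (slope 0.25 (mm/s)/µm anchors
  40 µm to the observed 10 mm/s ceiling; the underlying flow–diameter fit
  is not printed, so the slope is a package default); interior edges
  carry the speed implied by volumetric conservation of their children,
  which the Murray-law diameters make exactly consistent with the linear
  law. Venous circuits are slowed (×0.5) and arterial sped up (×1.8),
  keeping veins/venules slower than arteries at matched caliber.
* **phantom images** — tubes of the edge diameters rasterized at the spec
  voxel size, Gaussian blur, additive Gaussian noise, seeded.

What the synthetic data does *not* emulate: curved vessels (polylines are
straight between nodes), pulsatile or non-Newtonian flow, out-of-plane
vasculature, imaging artifacts beyond blur + Gaussian noise, and bubble-
level acoustics. Passing round-trip and navigation tests on these
phantoms therefore demonstrates correctness of the pipeline's geometry,
bookkeeping and force balance — not segmentation robustness on real
angiograms.

## Lattice extraction choices

Binarization defaults to Otsu's threshold (the same intensity-based
thresholding used for swarm masks). Skeletonization is Guo–Hall
two-subiteration parallel thinning: its min(N1, N2) condition protects
two-pixel diagonal tips that simpler schemes erode or disconnect. Nodes
are skeleton pixels whose 8-neighborhood crossing number differs from 2,
clustered over a radius-2 dilation because thinning fragments one
physical junction into nearby branch pixels. Centerlines are traced
pixel-by-pixel between node blobs; short intra-junction bridges are
discarded and their pixels released so genuine branches can still be
traced. Spur branches shorter than their own estimated diameter are
pruned, and nodes left with exactly two incident edges are dissolved.
Edge diameter is `2 ×` the mean distance-transform value along the
centerline — robust to boundary noise, and within 20% of truth on
rendered phantoms across seeds (accuracy limited by blur widening thin
tubes and by staircase centerlines sampling off-ridge pixels). Cluster
diameter for detections is the equivalent-circle diameter
`sqrt(4A/π)`; a maximum-Feret alternative is available. Tracking is
greedy nearest-neighbor linking with a hard distance gate.

## Planning

`best_transducer()` scores elements by predicted speed gated on direction
match; `plan_route()` chains per-edge winners greedily — matching the
manual per-vessel procedure used in practice — with durations
`edge length / predicted speed × 1.5` (the safety factor covers
stochastic formation delays; in-experiment durations were operator-
controlled and unrecorded, so durations here are model-derived). Because
one element is active at a time, per-edge choices are independent and
greedy selection is optimal per edge; an exhaustive mode audits this on
small problems. Plans are validated by kinematic forward simulation
before being returned.

## Numerical and degenerate-input policy

* Distances at or below 0.1 mm (near field), transducers coincident with
  an edge midpoint, blank or constant images, empty masks, and paths with
  no feasible transducer raise errors naming the offending input.
* Exactly orthogonal vessels (projection below 1e-9) get direction 0 and
  keep the `g(90°) = 1/3` speed scale: transport there is symmetric and
  bidirectional, and the simulator assigns a seeded random sign.
* Growth-to-saturation integrates with 5 s steps and a 0.01 µm per-step
  stop rule, terminating within 0.04 µm of the asymptote.
* All stochastic entry points take explicit seeds; event logs record the
  seed in their header, and identical seeds give byte-identical logs.
* Problem sizes in the test-suite: phantoms of ~500×500 px at 2 µm/px,
  six-edge networks, 30-step simulations, 1000-swarm direction
  experiments — each chosen to exercise every code path at desk scale.

## Known limitations

* The angular law between its two anchored endpoints is unvalidated.
* `C` calibration absorbs all unmodeled acoustics (standing waves, skull
  scattering, shell dynamics); transferring a calibration across devices
  is not supported — each preset carries its own anchor.
* The skeleton cannot distinguish touching vessels from junctions;
  crossing vessels in a 2D projection will merge. In vivo use would need
  the non-degeneracy margins stated above.
* Flow assignment is kinematic (no pressure solve); it is exact on trees
  and falls back to the per-edge law on graphs with cycles.
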