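---
title: "Single-heartbeat 3D electromechanical wave imaging: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-heartbeat 3D electromechanical wave imaging: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`ewi3d` implements a complete high-volume-rate 3D echocardiography chain for
a 2D matrix array, together with a synthetic phantom that generates channel
data with a known electromechanical ground truth:

1. **Acquisition model** — a 32x32-element, 0.3 mm pitch, 3.6 MHz matrix
   array firing five diverging-wave transmits per compounded volume at a PRF
   of 4200 Hz, i.e. 840 volumes/s. Two transmit schemes are provided: five
   unsteered 16x16 sub-apertures (four quadrants plus center), and five
   full-aperture transmits steered to (±16°, ±16°) and (0°, 0°).
2. **Delay-and-sum beamforming with coherent compounding** — every channel of
   every transmit is delayed by the diverging-wave forward delay plus the
   return delay and summed, without apodization or normalization, onto a
   pyramidal grid (90° sector, one line per degree, 32.1 µm axial step at
   full scale).
3. **RF speckle tracking** — inter-volume axial displacement by 1-D
   zero-normalized cross-correlation of beamformed RF (4.9 mm windows, 90%
   overlap), with cosine-fit subsample refinement.
4. **Strain** — axial (≈ longitudinal in apical views) strain as the local
   least-squares slope of displacement versus depth, implemented as an
   order-1 Savitzky-Golay gradient; inter-volume displacements accumulated
   over systole give end-systolic strain.
5. **Activation mapping** — the local onset of shortening (first
   positive-to-negative zero crossing of the inter-volume strain curve after
   the ECG reference) detected at 200 randomly sampled myocardial voxels and
   interpolated to the whole myocardium; atrial voxels are referenced to the
   P onset, ventricular voxels to the QRS onset.
6. **Chamber strain** — end-systolic strain averaged over the atria (AGLS)
   and the ventricles (VGLS), split at the atrio-ventricular junction.

# Conventions

* Right-handed coordinates, array centered at the origin in the z = 0 plane,
  z pointing into the body. Azimuth is rotation in the x–z plane, elevation
  in the y–z plane; the ray of line (az, el) is along `(tan az, tan el, 1)`.
* Transmit t = 0 is the instant the earliest active element fires. The
  diverging wavefront of a virtual source at distance d behind the array is
  realized by firing element e at `(|p_e − p_src| − min_e' |p_e' − p_src|)/c`;
  simulator and beamformer share this convention, so the two cancel exactly.
* Displacement is stored positive toward the transducer (the inward motion of
  an apical view). Axial strain is the depth-gradient of the z-signed
  displacement, so shortening is negative and lengthening positive.
* All lengths are meters, times seconds, angles degrees at interfaces.
* The speed of sound defaults to 1540 m/s (standard soft-tissue value) and is
  configurable everywhere.

# The phantom

The phantom is a set of point scatterers drawn uniformly (Poisson counts,
seeded) inside ellipsoidal chamber walls, each wall the region between an
outer ellipsoid and a concentric inner one. A prescribed activation wave
spreads at constant conduction velocity from a regional origin: atria from
`p_onset`, ventricles from `q_onset = p_onset + av_delay` (defaults: atria
1.0 m/s, ventricles 1.5 m/s, AV delay 80 ms). After its local activation a
ventricular point ramps its strain linearly from 0 to `s_es_vent` (default
−0.15) over `tau` (60 ms) and holds; atrial tissue instead *lengthens* to
`s_es_atrial` (default +0.25) during ventricular systole (reservoir
stretch), starting shortly after the QRS onset. Because the atria never
shorten in this model, atrial onsets are undetectable by the
positive-to-negative rule — the map reports them unset, which mirrors
non-color-coded regions in practice — while atrial GLS remains fully
testable.

Motion is purely axial. The displacement of a point is the integral of the
local strain state along z from the *apical anchor* — the shallowest
myocardial depth of the point's vertical column. We deliberately anchor
apically (not basally): in an apical view the apex sits near the probe and
is nearly stationary relative to it, and anchoring at the base would make
shortening move tissue *away* from the transducer, contradicting the sign
convention above. The integral is discretized at 0.25 mm and stored as a
table of clamped ramps, so displacing the cloud to any time is exact to the
discretization and fast; un-activated tissue distal to activated tissue
translates rigidly, as it must.

# Numerical choices

* **Pulse**: Gaussian-enveloped cosine, −6 dB fractional bandwidth 0.6;
  sampling at 4 f0 = 14.4 MHz (the receive rate is not dictated by the
  reconstruction grid; it must only satisfy the pulse band). The simulator
  evaluates the pulse from a 1/32-sample lookup table (relative error < 1e−3).
* **Fast-time interpolation** in the beamformer is linear; out-of-range
  delays contribute zero rather than clamping, avoiding edge bias.
* **Subsample peak refinement** uses the cosine fit by default. The RF
  correlation function oscillates at the carrier; sampled at 4 f0 it carries
  only ~3.7 samples per period, and fitting a parabola through the peak and
  its neighbours is then biased by up to ~0.06 samples, while the cosine
  model (peak phase of a sampled cosine) is the matched estimator and stays
  below ~0.02 samples. Parabolic and no refinement remain available. When
  the integer-lag peak is exactly 1 (bit-identical segments) refinement is
  skipped: a perfect match needs no refinement and the fit would only
  amplify round-off — truly static tissue tracks to exactly zero.
* **Window bookkeeping**: windows are laid from the first depth sample with
  hop `window_length * (1 − overlap)`; windows whose ±max_lag search segment
  would leave the recording are flagged invalid rather than silently
  dropped, so `n_windows = floor((n_depth − window)/hop) + 1` always.
* **Savitzky-Golay window**: 3.2 mm by default (unstated in the source
  method; chosen as roughly two thirds of the tracking window — a
  smoothness/variance trade-off), order fixed to 1 because the estimator is
  a local slope. Boundary samples use truncated one-sided fits.
* **Accumulation** over systole is Eulerian (fixed lattice) by default. With
  ~1 mm of cumulative motion and ~0.5 mm lattice spacing the Lagrangian
  drift is a second-order effect; an optional Lagrangian mode
  (`accumulate_displacement(..., lagrangian = TRUE)`, or
  `strain: lagrangian: true` in the configuration) follows each site by the
  nearest lattice sample of its accumulated displacement.
* **Onset detection** automates a rule that was applied manually in the
  source method, so it needs a noise policy the manual operator provided
  implicitly. A crossing is accepted only if it is the last
  positive-to-negative crossing before the curve's first *significant*
  negative excursion, where significant means below
  `−crossing_significance × median(|one-step change|)` — a scale-free gate
  (invariant under positive rescaling) that reduces to the literal
  first-crossing rule when `crossing_significance = 0`. The fallback for
  curves that never cross (slightly negative, then rapidly and strongly
  decreasing) dates the activation at the sample before the first one-step
  drop exceeding `fallback_drop_factor ×` the same scale.
* **Scattered interpolation** of detected onsets to the whole myocardium
  uses an exact linear radial-basis interpolant (φ(r) = r plus an affine
  term), per region. It reproduces affine fields exactly and equals the
  detections at their sites; "3D linear interpolation" is otherwise
  underdetermined, and the environment's numerical stack offers no 3D
  Delaunay triangulation to hang a barycentric scheme on.
* **Systole selection** takes the first volume at/after QRS onset and ends
  with the longest contiguous run of volume pairs whose median valid
  ventricular displacement is positive (inward motion); a manual interval
  always wins. End of systole has no operational definition in the source
  method, so this automated rule, plus the manual escape hatch, is ours.

# The validation study (what the tests actually run)

Recovery tests run a scaled-down but complete study; the choices below are
the package's own and are stated here once:

* probe 8x8 elements at **0.9 mm pitch** (7.2 mm aperture). At 8 elements the
  original 0.3 mm pitch would give a 2.4 mm aperture and ~10 mm lateral
  resolution — useless — while pitches ≥ 1.07 mm put a grating-lobe ghost of
  sector-edge scatterers back *inside* the ±10° sector. 0.9 mm keeps every
  ghost outside the sector with ~3 mm lateral resolution at 50 mm.
* full-aperture steered transmits at ±8° (the ±16° of the 90° sector scaled
  to the 20° sector), virtual sources 10 mm behind the array.
* 20° sector, one line per degree (21 × 21 lines), axial grid at the native
  RF sampling c/(2 fs) ≈ 53.5 µm, depths 24–72 mm.
* a two-chamber phantom: a thick-walled "LV" (outer semi-axes 7/7/13 mm,
  wall 5.5 mm, centered at 40 mm depth) and an "RA" (6.2/6.2/7.5 mm, wall
  5 mm, at 61 mm), 1 scatterer/mm³. Walls are deliberately thick and
  cavities small so that the paper-fixed 4.9 mm tracking window fits inside
  a wall; thin-walled chambers at this scale would put every window across a
  boundary.
* ventricular conduction velocity 1.0 m/s in this study (the recovery
  criteria are stated at 1 m/s); all other kinematics at the defaults above.
* 160 volumes at 840 volumes/s (190 ms): P at 8 ms, QRS at 88 ms, the wave
  crosses the ventricle in ~26 ms, the last ramp ends by ~174 ms.
* volumes acquired before the earliest mechanical onset are bit-identical in
  a noise-free simulation, so the pipeline computes the first one and reuses
  it — a pure speed optimization with no numerical effect.

What passing these tests shows — and what it does not. The phantom exercises
the whole chain (diverging-wave physics, compounding, speckle tracking on
fully coherent RF, accumulation, onset detection, interpolation) with exact
ground truth. It does **not** emulate reverberation clutter, nonlinear
propagation, attenuation (available but off by default), out-of-plane or
lateral myocardial motion, electrophysiological realism (no
bidomain/monodomain model, no torsion or circumferential mechanics), or
probe motion. Recovery numbers on real hearts will be worse, in the
directions the source method's own discussion anticipates (angle dependence
of axial-only tracking, lower SNR regions).

Known quantitative limitation: tracking windows and SG windows overlapping a
wall boundary dilute the strain toward zero. At desk scale the walls are
only ~15–26 mm long, so this boundary zone is a sizable fraction of the
myocardium and chamber means underestimate the prescribed magnitudes by a
couple of percentage points; at adult-heart scale the same effect is small.
The recovery tolerances (±3 points VGLS, ±5 points AGLS) absorb this bias
without hiding a sign or scale error.

# Reproducibility

Every random element (scatterer sampling, reflectivities, activation voxel
sampling, channel noise) derives from the single `seed` in the run
configuration. Identical configuration and seed reproduce the results JSON
bit for bit; this is itself a test. The command-line front end
(`inst/cli/ewi3d.R`) writes a provenance block (config checksum, seed,
package version) with every run.
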