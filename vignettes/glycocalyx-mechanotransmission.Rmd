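---
title: "Modelling glycocalyx mechanotransmission of pulsatile wall shear stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycocalyx mechanotransmission of pulsatile wall shear stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxmech)
```

## The problem

The endothelial glycocalyx shields the apical cell membrane from direct
fluid shear: blood velocity decays almost to zero inside the dense layer,
so essentially all of the haemodynamic shear force arrives as drag on the
luminal tips of the heparan-sulfate (HS) chains and reaches the cell as a
*bending-mediated reaction force* at the syndecan core proteins anchoring
each chain. gcxmech models one such glycocalyx unit as a clamped dynamic
Timoshenko beam, drives it with pulsatile wall-shear-stress (WSS) vector
histories, and quantifies — per vertex of a surface mesh — how the
transmitted anchor force `F_mem(t)` differs from the stimulus
`F_shear(t)` in magnitude (`F_ratio`, `TAF`), directionality (`OSI`
vs `OFI`) and frequency content (`SPR`, `DHR`).

## The beam model and its parameters

One unit is a solid circular cantilever with translational displacement
`w(x, t)` and cross-section rotation `phi(x, t)` in each of two uncoupled
tangent-plane bending directions:

$$\rho A \,\ddot w - q(x,t) = \partial_x\!\left[\kappa A G (w' - \phi)\right],
\qquad
\rho I \,\ddot\phi = \partial_x (E I \phi') + \kappa A G (w' - \phi).$$

Axial stretch and torsion are omitted (the drag load is purely transverse),
and the isotropic circular section keeps the two planes exactly uncoupled,
which the tests assert.

Parameters (`beam_params()`), with units and defaults:

* `L = 50` nm, `d = 1` nm — the HS-equivalent geometry recovered by
  calibrating a continuum beam against molecular-scale deflection data
  (see the diameter calibration below).
* `EI = 100` pN nm² — flexural rigidity. `E = EI/I` and
  `G = E/(2(1+\nu))` are derived from it, so rescaling `EI` rescales
  `E` and `G` together and static deflections scale exactly as `1/EI`.
  Reported rigidities for this system are printed in pressure units in
  parts of the literature; a flexural rigidity cannot carry pressure
  units, and all values here are interpreted as pN nm², consistent with
  the continuum work this model family replicates.
* `nu = 0.3`, `kappa = 0.8864` — Timoshenko shear coefficient of a
  circular section at this Poisson ratio.
* `f_load = 1/6` — the drag acts on the top sixth of the beam: the
  velocity profile inside the layer decays so fast that the tip segment
  carries ~90% of the drag and ~96% of the bending moment.
* `A_cap = 2` μm² — capture area converting WSS (Pa) to total drag force
  (pN) per unit (1 Pa × 1 μm² = 1 pN). No measurement pins this mapping
  down; the default is a documented calibration chosen so physiological
  WSS of 0.4–2.5 Pa produces anchor forces of order 1–10 pN, the range
  where transmembrane mechanotransductors (e.g. the vinculin–talin
  complex) switch conformational state.
* `rho_b = 4e15` kg m⁻³, `alpha_R = 50` s⁻¹, `beta_R = 8e-4` s — an
  *effective* density and Rayleigh damping pair. Neither quantity is
  measurable for this composite, fluid-immersed structure; the defaults
  are a one-time modelling choice placing the first natural frequency of
  the default unit near 40 Hz — inside the analysed 0–125 Hz cardiac
  band, so that dynamic filtering of the stimulus is representable at
  all — with ≈20% modal damping at that mode. `rho_b = 0` (or
  `quasi_static = TRUE` in the pipeline) gives the inertia-free limit in
  which `F_mem` tracks `F_shear` exactly; that limit is the backbone of
  the cross-module tests.

```{r natfreq}
p <- beam_params()
natural_frequencies(p, 2)
```

## Discretization and numerical choices

* **Elements.** 100 three-node quadratic elements, fields `(w, phi)` per
  node; 3-point Gauss for bending and mass, 2-point reduced integration
  for the shear term. Reduced shear integration avoids shear locking: at
  slenderness `L/d = 200` the tip deflection matches the closed-form
  Timoshenko cantilever value to 0.1%.
* **Statics in extended precision.** The slender-beam stiffness matrix is
  ill-conditioned (~1e9 at 100 elements), and double-precision assembly
  alone perturbs its rigid-body null vector enough that anchor reactions
  extracted from the constrained-row residual lose the equilibrium
  identity at the ~1e-9 level. The static path therefore runs in a
  compiled long-double kernel (assembly, banded Cholesky, residual),
  restoring equilibrium to ~1e-12: the anchor reaction equals the applied
  load, and the anchor moment equals load × `(1 - f_load/2) L`.
* **Dynamics.** Implicit Newmark (beta = 1/4, gamma = 1/2), load repeated
  periodically over `n_cycles = 3` cycles from rest, final cycle
  reported; the cycle-to-cycle reaction change at that point is below 1%.
  The first cycle's load is brought in under a cosine ramp: a hard step
  from rest seeds the marginally damped Nyquist mode of the
  average-acceleration scheme (a period-2Δt sawtooth in the acceleration
  recursion), which otherwise pollutes the reported cycle at the ~1e-6
  level; the periodic steady state is unaffected.
* **Pipeline fast path.** The beam is linear and time-invariant with a
  single spatial load pattern, so the per-vertex anchor response is the
  discrete convolution of the input force sequence with the Newmark
  scheme's unit-response kernel — computed once per run. A test pins this
  path to `dynamic_solve()` at 1e-8.
* **Integrals and spectra.** Cycle integrals use the trapezoidal rule
  with the periodic closing sample (the rectangle sum on a uniform
  periodic grid). Spectra are one-cycle DFTs — no window, no padding;
  the signal is periodic by construction — normalized so harmonic 0 is
  the signal mean; Parseval (`sum |X_n|^2 =` mean squared signal) holds
  to 1e-9 and is asserted. The dominant harmonic is taken over `n >= 1`
  (the DC term would otherwise always dominate and force DHR ≡ 1), with
  ties — to relative round-off — broken toward the lowest harmonic.
* **Degenerate directions.** The local frame (`zeta` along the
  time-averaged WSS vector, `eta = zeta × n`) is undefined where the mean
  WSS magnitude falls below `eps_dir = 1e-6` Pa; such vertices are
  flagged and excluded from frame-dependent maps, never interpolated. A
  run aborts if more than 10% of vertices are degenerate. Similarly,
  `F_ratio` excludes instants with `|F_shear| < eps_F = 1e-6` pN and
  renormalizes over the retained instants, reporting the excluded
  fraction.
* **Percentile regions.** Percentiles are *surface-area weighted* (the
  percentile of a field on a surface, not of a vertex list) with linear
  interpolation between order statistics; whether to weight by area is
  genuinely open, and the choice is recorded in the summary metadata.
  Values within 1e-9 (relative) of the threshold count as at the
  threshold and are never selected — without this guard band, tied values
  sitting exactly on the percentile make region membership unstable under
  round-off-level differences between analytically identical maps.

## Calibration procedures

`calibrate_load()` inverts the linear static problem (one solve plus
scaling) to find the total load reproducing a target tip deflection —
needed because published deflection studies omit their load magnitudes.
`replicate_deflection_study()` applies it: calibrate at a reference
rigidity, then report deflections across rigidities under the same load.

`calibrate_diameter()` recovers an equivalent HS diameter from
load–deflection pairs with `EI` held fixed, exploiting that `d` then
enters only through the shear compliance (`A/I = 16/d^2`): the tip
compliance is monotone in `d` and the least-squares optimum has a closed
form in compliance, so bisection on `[0.01, 100]` nm to 1e-4 nm suffices.
In the bending-dominated regime the shear term is a fraction of a percent
of the compliance, so the recovered diameter is weakly identified; the
result carries a `shear_fraction` and an `identifiable` flag (threshold:
shear ≥ 2% of compliance) rather than a silent answer.

## The synthetic WSS generator

The generator stands in for the image-based CFD stage, emulating its
outputs statistically rather than solving any flow. Defaults follow the
study conditions: cardiac period `T = 1` s, `dt = 4` ms (250 samples per
cycle, 250 Hz FFT sampling). Two canonical phenotypes:

* *athero-protective* (`protective_spec()`): magnitude
  `1.2 + Fourier(4 harmonics)` Pa peaking at ≈2.5 Pa, unidirectional;
* *athero-prone* (`prone_spec()`): mean 0.08 Pa, peak < 0.4 Pa,
  direction-oscillation amplitude 0.8 with the flow-aligned component
  reversed for 30% of the cycle.

Direction oscillation rotates the WSS vector in the tangent plane by
`theta(t) = pi * A_dir * sign(sin) |sin|^p` plus seeded band-limited
noise (harmonics 5–12), where the sharpening exponent `p` is chosen so
the fraction of the cycle with `|theta| > pi/2` equals the requested
reversal fraction (possible only when `A_dir > 0.5`). Per-vertex fields
blend the two phenotypes linearly along a logistic axial ramp. Everything
is seeded and bitwise reproducible.

What the generator does *not* emulate: spatial flow structures
(recirculation, separation), inter-cycle variability, and any WSS spectral
content above the modelled harmonics — near-wall noise spectra are not
characterized in the data this package draws on, so the noise band is a
modelling choice. Passing tests therefore demonstrate correctness of the
*mechanics and descriptor pipeline* under controlled stimuli, not fidelity
to any specific artery.

## Problem sizes

The default test and pipeline configurations use patches of 80–2000
vertices with 250 samples per cycle and 3 integration cycles; the
quasi-static end-to-end check runs the full pipeline on a 2000-vertex
field. The deflection studies use the standard 100-element discretization
(402 DOFs per bending plane), with an 800-element solve only in the mesh
convergence check.

## Known limitations

* One beam per vertex: no mechanical coupling between neighbouring
  glycocalyx units, and no brush/porous-layer hydrodynamic screening
  beyond the top-sixth loading rule.
* Linear elasticity throughout — no large-deflection geometry, no
  glycocalyx degradation or remodelling.
* The effective density, damping and capture area are calibrations, not
  measurements; conclusions that depend on the absolute position of the
  resonance within the cardiac band inherit that uncertainty.
* The quantitative descriptor maps of any real artery require the actual
  CFD surface data; the synthetic generator reproduces value ranges and
  phenotype contrasts, not anatomy.
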