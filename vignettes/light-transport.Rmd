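---
title: "Modelling light delivery from micro-LED probes and fibers into cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light delivery from micro-LED probes and fibers into cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(optomc)
```

`optomc` estimates the fluence-rate field produced in neural tissue by
two implantable light sources — a micro-LED pixel emitting through its
sapphire substrate, and a multimode fiber above the cortical surface —
by Monte Carlo simulation of radiative transport. This vignette is the
package's account of the model: its physics, its tunable parameters and
their defaults, the choices made where the design was genuinely open,
and what the simulations do and do not say about real tissue.

## Transport model

Light at 450 nm in grey matter is strongly multiply scattered
(µ_s = 11.7 mm⁻¹, one interaction every ~85 µm) and weakly absorbed
(µ_a = 0.07 mm⁻¹), with strongly forward-peaked single scattering
(g = 0.88). In this regime radiative transport has no useful closed
form near a structured source, and Monte Carlo with weighted photon
packets is the standard estimator.

Each packet carries a statistical weight starting at 1 and is moved
between interaction sites with step length `-log(u)/mu_t` — the
inverse-CDF of the Beer–Lambert law. At each site the fraction
µ_a/µ_t of the weight is deposited and the packet is deflected. In
transparent media (sapphire, saline: µ_t = 0) packets travel
boundary-to-boundary.

**Phase function.** Tissue optical constants of the kind used here are
reported as (µ_a, µ_s, g); *g* alone does not determine a phase
function. We adopt Henyey–Greenstein, the de-facto standard companion
to such constants in tissue optics; its first moment equals *g*
exactly, which the test suite verifies empirically. Sampling uses the
closed-form HG inverse CDF; at g = 0 the cosine is uniform on [−1, 1].

**Boundary optics.** Interfaces (layer planes, the lateral cylindrical
faces of the probe, the domain edge) are resolved with the unpolarized
Fresnel reflectance, averaged over s- and p-polarization, with total
internal reflection returned as R = 1 beyond the critical angle
(sapphire→tissue: 50.2°). Reflection events are decided
*probabilistically* — one deviate compared against R — rather than by
weight splitting. This keeps one packet per history, which is what
makes the scalar reference engine (below) a line-for-line check of the
production engine; the variance cost is negligible at the photon counts
used.

**Termination.** The classical recipe terminates packets below a
weight threshold, which silently destroys weight and makes energy
balance untestable. We instead play Russian roulette below the
threshold (default 10⁻⁴, survival probability 0.1, survivor weight
boosted ×10): unbiased by construction, so

    launched − (absorbed + escaped + back-plane + edge + capped) − roulette_net = 0

holds to floating-point rounding on every run, and the test suite
asserts it. A `strict_termination` switch restores plain threshold
termination (with the discarded weight still tallied) for comparison.
Runaway histories are cut at a configurable step cap (default 10⁵) and
tallied as capped, never dropped silently.

## Geometry

The domain is a cylinder (default radius and depth 5 mm) aligned with
the emission axis; z = 0 at the probe/tissue (or saline/tissue)
interface, tissue at z > 0, lengths in mm, half-open bins.

* **µLED probe**: a 100 µm sapphire slab (n = 1.77, transparent)
  bounded laterally at the 150 µm probe width, with tissue both below
  and beside it. The reflecting p-contact behind the pixel is modelled
  as an absorbing plane by default — the contact's reflectivity is not
  characterised, and absorbing is the conservative, parameter-free
  choice; a specular reflectivity is available as a config switch.
  Bounding the sapphire laterally matters: an unbounded lossless slab
  would trap TIR light forever, whereas the real probe is embedded in
  tissue and its lateral faces leak trapped light into it (with the
  same Fresnel optics as every other interface).
* **Fiber**: the tip sits in a 300 µm saline standoff (n = 1.34,
  transparent) above semi-infinite tissue.
* **Inserted probe**: `tissue_above` adds cortex above the probe plane
  so that illumination of the shallow layers can be interrogated when
  the emitter sits 1 mm deep.

Sapphire and saline indices are handbook values at 450 nm and live in
the shipped YAML configs together with the tissue constants — nothing
physical is hard-coded.

## Sources

**µLED**: launch positions uniform over the 30 µm disc, directions
cosine-weighted (Lambertian) about +z, entering the sapphire directly;
the few-µm GaN epilayers are not modelled as a distinct medium.

**Fiber** (105 µm core, NA 0.22): the device description leaves two
things open, and both are explicit parameters:

* the radial width of the Gaussian launch weighting — default
  σ = core radius/2, truncated at the rim by rejection, putting ≈86% of
  the untruncated mass inside the core, a typical multimode near
  field;
* whether the NA bound applies in air or in the launch medium —
  default `na_reference = "medium"`: the cone half-angle is
  asin(NA/n_saline) = 9.45°, since divergence in saline is physically
  reduced by refraction (`"air"` is a config switch).

Directions are uniform in *solid angle* within the cone — the
conventional reading of an NA-bounded launch; uniformity in polar angle
would over-weight the axis.

## Scoring and derived quantities

Fluence is estimated with the track-length estimator: every traversed
segment credits each voxel it crosses with weight × in-voxel length,
split exactly at voxel boundaries (conservation to 10⁻¹² relative is a
tested invariant). Unlike the absorption-weighted collision estimator,
this works in the transparent layers and has lower variance per photon.
Fluence rate per voxel is value/(voxel volume × N) × source power.

The default grid (Δr = Δz = 10 µm, r ≤ 1.5 mm, z ∈ [−0.4, 2] mm)
resolves the 30 µm pixel with three radial bins at ~360k voxels.

Derived quantities mirror how stimulation experiments are planned:

* `activation_volume(map, threshold)` — total volume of tissue voxels
  (voxel centre in tissue) at or above a fluence threshold;
* `penetration_depth(map, threshold)` — deepest such voxel centre;
* `interface_profile(map)` — radial irradiance in the first tissue bin
  and its half-maximum diameter, which for the µLED exceeds the
  physical pixel because of spreading in the sapphire;
* `activation_report(map, thresholds)` — the threshold sweep.

**ChR2 threshold.** The literature convention of ~1 mW/mm² for
ChR2(H134R) is the default, but no published threshold is exact, so
every threshold-dependent result in the tests and reports carries a
sweep over 0.5–2 mW/mm² rather than standing on one constant.

**Current calibration.** Bench anchors map drive current to interface
irradiance (0.1 mA → 0.5, 4 mA → 40, 6 mA → 52 mW/mm²), interpolated
piecewise-linearly with no extrapolation. Interface irradiance is
stored directly and never derived from the µLED *surface* irradiance:
the printed surface↔interface pairs imply attenuation factors that
differ by ~5× across the operating range, so a single conversion
factor would be wrong somewhere. Simulated maps are scaled by choosing
the source power that makes the peak first-tissue-bin irradiance match
the calibrated value (`scale_power_to_interface()`).

## Reproducibility and the reference engine

Randomness comes from a counter-based splitmix-style generator keyed by
(seed, photon index): every photon owns an O(1)-addressable substream,
so runs are reproducible, independent of execution order, and any
single history can be replayed from R. The production engine is C++
(Rcpp); a deliberately naive scalar R engine implements the same
physics one photon at a time and must reproduce the compiled engine's
event stream and tallies *bit-for-bit* on shared substreams
(`reference_engine_equivalence()`). Two build details make bitwise
agreement possible rather than approximate: floating-point contraction
is disabled for the C++ code, and both engines call the same C-library
transcendental primitives (glibc `sincos`, `log`) — R's own `cos()`
differs from libm by one ulp on some builds, and GCC silently fuses
adjacent sin/cos calls into `sincos`, which differs again.

Other numerical choices: boundary hits closer than 10⁻¹² mm are
ignored (the surface the packet sits on); positions are snapped onto
the crossed surface to stop drift; z-plane candidates are examined
before lateral ones, a measure-zero tie-break; the local-frame rotation
switches to a stable branch within 10⁻⁹ of the z pole; directions are
renormalized after every rotation and refraction, keeping |d| = 1 to
10⁻¹² over arbitrarily long histories; voxels straddling the tissue
boundary count as tissue iff their centre is in tissue.

## Validation

`run_oracles()` anchors the engine with checks that are independent of
any published figure: Beer–Lambert transmission of a pencil beam in a
pure absorber against exp(−µ_a z) within 3 binomial standard errors;
exact energy balance; the HG first moment; Fresnel closed forms to
10⁻¹²; reference-engine equivalence; byte-identical grid files for
identical config and seed. A diffusion-limit check — the fitted
far-field decay of fluence × distance against
µ_eff = sqrt(3 µ_a (µ_a + µ_s(1−g))) = 0.556 mm⁻¹, within 15% — is
advisory only, because diffusion theory is itself approximate at these
constants and fit-range dependent.

Problem sizes: the full-scale scenario checks use 10⁶ photons (the
headline runs take tens of seconds each); unit and property tests use
10³–10⁵ photons, and the scalar reference engine is exercised at up to
10³ photons.

## What the simulations do not capture

The model is incoherent radiative transport in homogeneous layered
media. It does not represent: optical heterogeneity of real cortex
(vasculature, layered scattering differences, blood absorption
hot-spots); coherent interference in the thin sapphire and saline
layers (only incoherent multiple reflection is modelled, so
interference fringes in those layers are absent by design); wavelength
spread of the LED (single 450 nm design point); polarization;
fluorescence; tissue heating; or the opsin's photocycle — "activation"
here means exceeding a fluence threshold, not a channel-current model.
Passing tests therefore validate the transport engine and the device
geometry model, not the biological response; threshold sweeps are the
honest way to read every activation-volume or depth number the package
produces.
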