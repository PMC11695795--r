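---
title: "Circumnutating penetrometers: models, synthetic data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circumnutating penetrometers: models, synthetic data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment this package models

Growing root tips circumnutate: they trace a helical path whose radial
extent (amplitude) and number of turns per unit penetration (frequency)
vary among species and conditions. `circumpen` analyses a laboratory
emulation of this behaviour: a cone penetrometer acting as a root
analogue (cone base radius $r_c = 2.5$ mm, semi-opening angle
$\beta_c = 15^\circ$, recessed shaft of length $l_s = 45$ mm) is driven
into remoulded arable soil ($\rho_b = 1.4$ g cm$^{-3}$, gravimetric water
content 0.22 g g$^{-1}$) at 1 cm h$^{-1}$ while the sample performs an
orbital motion of 1 mm radius at 0, 1, 5 or 10 oscillations per cm of
penetration. Two shaft materials set the bending stiffness, and thereby
the amplitude the cone can actually realise: steel
($k = 6.96$ N mm$^{-1}$, stiff) and brass ($k = 2.96$ N mm$^{-1}$,
flexible). The package implements three analysis stages — deflection
kinematics, a cavity-expansion force decomposition, and X-ray CT
pore-structure morphometry — plus a seeded synthetic-data generator that
stands in for the physical rig, and the treatment-level statistics.

## Deflection kinematics

The camera sees the projected deflection angle of the shaft to the
vertical. Within oscillation $i$ the angle range
$\Delta\alpha_i = \max\alpha - \min\alpha$ yields the average horizontal
cone deflection

$$\delta_c = \frac{l_s}{R} \sum_{i=1}^{R} \sin\frac{\Delta\alpha_i}{2},$$

the circumnutation amplitude $= r_o - \delta_c$ (orbit radius minus the
deflection the shaft absorbs), the corrected axial force
$F_a = F_z \left[\tfrac1R \sum_i \cos(\Delta\alpha_i/2)\right]^{-1}$ and
the relative measurement error
$e_\mathrm{rel} = 100\,(F_a - F_z)/F_z$.

Design choices here:

* **Angles are stored in degrees** (what an image measurement produces)
  and converted to radians only inside trigonometric calls; every
  interface documents the unit.
* **$\Delta\alpha_i$ is a max–min range**, not a fitted sinusoid
  amplitude, matching how the quantity is measured on time-lapse images.
  With additive measurement noise the range estimator has a small
  positive bias (the expected maximum of the noise at the samples
  competing for the extremes), which for the default noise level of
  0.01° biases $\delta_c$ by roughly +0.01 mm — well inside the
  tolerance of every recovery check.
* **Oscillation windows come from the nominal frequency and the
  penetration speed**, not from signal detection: the rig imposes the
  period exactly, and window detection would only add failure modes.
  `segment_oscillations()` splits the observed span into $R = f \times
  \mathrm{depth}$ equal contiguous windows.
* **Stationary treatments** ($f = 0$) carry $\delta_c = 0$ and a
  *missing* amplitude: without orbital motion the amplitude is
  undefined, and reporting 1 mm would be wrong.
* We assume windows aligned with the oscillation phase (penetration
  starts at a phase extreme); the generator enforces this, and for
  measured data a misalignment only redistributes ranges among windows
  without changing their mean materially.

## Cavity-expansion force decomposition

Axial penetration force is the sum of a cavity-expansion component and
interfacial friction. For stationary samples, with radial stress
$\sigma_{r,s}$ on the cone flank:

$$F_{r,s} = \pi r_c^2 \cot\beta_c\, \sigma_{r,s}, \qquad
  F_{c,s} = F_{r,s}\tan\beta_c = \pi r_c^2 \sigma_{r,s}, \qquad
  F_z = F_{c,s}\,[1 + \mu\cot\beta_c],$$

so the mean stationary force inverts to
$\sigma_{r,s} = \bar F_z / (\pi r_c^2 [1 + \mu\cot\beta_c])$ and
$F_{f,s} = F_z - F_{c,s}$ exactly. Orbital motion adds a unidirectional
radial force $F_{ro} = \delta_c k$ from the bent shaft, giving the
asymmetric distribution $F^*_r(\gamma) = F_{r,s} + \cos\gamma\,F_{ro}$
(valid for $F_{ro} \le F_{r,s}$), the asymmetry index
$I_\mathrm{asym} = F_{ro}/F_{r,s} \in [0, 1]$ and the circumnutation
intensity $CI = I_\mathrm{asym}\, f/f_\mathrm{max}$. Under the
assumption that net cavity size is unchanged by orbital motion
($F_{c,m} = F_{c,s}$), the moving friction force is the residual
$F_{f,m} = F_z - F_{c,s}$, and the total force rescales to other
friction coefficients as
$F_z'(\mu') = F_z [1 + \mu'\cot\beta_c]/[1 + \mu\cot\beta_c]$.

Choices:

* $\cot\beta_c = 1/\tan\beta_c$ with $\beta_c$ validated in
  $(0^\circ, 90^\circ)$; degenerate cone geometry is refused rather than
  propagated.
* $F_{c,s}$ for moving treatments is inherited from the stationary
  decomposition of the *same shaft material*, averaged over its
  stationary replicates — the same pairing the stationary calibration
  uses.
* A negative $F_{f,m}$ (moving force below the stationary
  cavity-expansion force) is **returned with a warning, not clipped**:
  it would indicate a violated model assumption, which is worth seeing.
* $f_\mathrm{max}$ defaults to 10 cm$^{-1}$, the largest frequency in
  the emulated design, and is configurable.

## The synthetic generator

The generator defines the study conditions; its defaults are fixed once.

**Force traces** (`gen_force_traces()`), 1 Hz at 1 cm h$^{-1}$ to 10 mm,
$n = 5$ replicates per cell, in two modes:

* *table mode*: each treatment fluctuates around its mean mechanical
  resistance. The default table encodes the emulated campaign: 0.79 MPa
  stationary (both materials), 0.71 MPa for steel at $f \in \{1, 5\}$
  (a 10% reduction that the flexible brass shaft does not show), and
  0.67 MPa for both materials at $f = 10$ (a 15% reduction).
* *mechanistic mode*: $F_z = F_{c,s} + F_{f,s}(1 - a\,CI)$, with
  $\sigma_{r,s}$ calibrated by inverting the stationary balance at
  0.79 MPa and a friction-attenuation coefficient $a = 2$
  (dimensionless). $a$ is a free calibration: with the strongest
  realised intensity ($CI \approx 0.10$ for steel at $f = 10$) it
  attenuates friction by about 20%, the order of magnitude the
  treatment table implies, while keeping $F_{f,m} > 0$ everywhere.

The noise model is invented — the physical traces are smooth with small
standard errors but no noise statistics are printed — so we use Gaussian
noise with sd 0.02 MPa per sample (an optional AR(1) with configurable
$\rho$ is available for serially correlated traces). Replicate-to-
replicate variance is nominal for the same reason.

**Deflection series** (`gen_deflection_series()`): a cosine with
peak-to-peak angle $\Delta\alpha = 2\arcsin(\delta_c/l_s)$ — the exact
inverse of the deflection formula — sampled at 1 min intervals starting
at $t = 0$, so every window contains its extremes exactly and noise-free
round trips recover $\delta_c$ to machine precision. Angle noise
defaults to sd 0.01°, the scale of sub-pixel manual measurement at the
camera's 10.8 µm pixel pitch over a 20 mm lever. The per-treatment
deflection defaults (steel 0.19 / 0.22 / 0.30 mm at $f = 1 / 5 / 10$;
brass 0.30 mm throughout, i.e. amplitudes 0.70–0.81 mm) are explicit
calibrations consistent with the amplitude range the rig produces, not
measured facts.

**CT phantoms** (`gen_ct_phantom()`): a cylindrical volume with

* a cone-plus-channel void whose radius is solved from the target
  imprint volume (default: the 40 mm$^3$ reference imprint scaled by the
  domain/reference volume ratio) at the configured tip depth;
* a Boolean random-sphere pore field (default radius 80 µm) with the
  sphere count set from the Boolean-model identity
  $\varepsilon = 1 - e^{-\rho v}$ to hit the background visible
  porosity (default 0.17);
* a compaction halo: sphere centres at distance $d$ from the imprint
  survive with probability $1 - A e^{-d/\lambda}$. Defaults $A = 0.85$,
  $\lambda = 1.25$ mm give a mean compactness increase of about 55%
  over the first half cone radius and measurable compaction beyond
  2.5 mm, the deformation pattern the analysis is meant to resolve.

The default phantom is 6 mm diameter × 6 mm height at 40 µm voxels
(~3.4 × 10$^6$ voxels), chosen so that the full generate–isolate–profile
cycle runs in seconds on one core; all lengths are specified in physical
units, so finer resolutions (e.g. 12 µm) are a configuration change, not
a code change. Reference (unpenetrated) phantoms omit the void and halo
and play the role of the unpenetrated control samples.

## CT morphometry

All 3D morphology (labelling, erosion/dilation, Euclidean distance
transform, morphological reconstruction, watershed, majority filtering)
is compiled code in `src/`, deterministic by construction: labels follow
raster-scan discovery order and priority-queue ties resolve to the
lowest linear index.

`isolate_imprint()` finds the cone imprint as the dominant pore cluster
while detaching granular pores that touch it through necks:
downscale ×0.5 → 3D majority filter (window 5³, suppressing pores below
~5 downscaled voxels diameter, i.e. most of the granular network) →
distance-transform watershed with markers from h-maxima ($h = 2$
voxels) → cut confirmation by 2 iterations of 6-neighbour erosion then
dilation → largest 26-connected cluster → upscale → one repeat of the
watershed/opening pass at full resolution on the pore components the
selection touches. The final imprint is the **union of watershed
catchment basins** backing the selected cluster, so the erosion/dilation
pairing decides only *which* basins belong and the imprint volume is
preserved up to the severed basin boundary (≤ 1% on phantoms). The
watershed parameters are documented defaults of this implementation, not
claims about any particular physical protocol; connectivity is
26-neighbour for labelling and the radius-1 cross for erosion/dilation,
both exposed.

`radial_porosity_profile()` builds shells by dilating the imprint with a
*spherical* structuring element in 5-voxel steps, implemented as
thresholds of the Euclidean distance transform. An iterated 6-neighbour
(cross) dilation would measure city-block distance, stretching the
radial axis by up to $\sqrt 3$ along diagonals and inflating any fitted
decay length; the Euclidean shells remove that metric artefact.
Compactness per shell is $\Delta c = 1 - \varepsilon'_\mathrm{vis} /
\varepsilon_\mathrm{vis}$ against the mean visible porosity of the
reference volumes, and the porosity/bulk-density chain is

$$\varepsilon' = \left(1 - \rho_b/\rho_p\right) -
  (\varepsilon_\mathrm{vis} - \varepsilon'_\mathrm{vis}), \qquad
  \rho'_b = (1 - \varepsilon')\rho_p,$$

with $\varepsilon = 1 - \rho_b/\rho_p = 0.4531$ kept at full precision
(not a rounded 0.45) so that an unchanged visible porosity returns
$\rho_b = 1.4$ exactly.

`fit_halo_decay()` estimates the halo parameters by weighted nonlinear
least squares of the *exact* Boolean-model compactness
$\Delta c(d) = 1 - [1 - (1-\varepsilon_\mathrm{ref})^{1 - A e^{-d/\lambda}}]
/ \varepsilon_\mathrm{ref}$: porosity is a concave function of placement
intensity, so a log-linear fit of $\Delta c$ itself is biased steep. The
innermost shell is excluded by default (`skip_bins = 1`): pores
straddling the imprint surface are truncated when the imprint is
subtracted, depressing the first shell's porosity. With these choices
the decay length is recovered to within a few percent on average, with
seed-to-seed scatter of roughly ±10% at the default phantom size.

"Mean pore diameter" is the volume-weighted mean equivalent-sphere
diameter of the labelled pore clusters — a definition chosen for
determinism and testability; a local-thickness variant would be a
drop-in alternative but is not implemented.

Region masks: the volume below the imprint tip extends the full domain
cross-section downward in whole voxel layers until the target volume
(1000 mm$^3$ at reference scale) is reached; the volume around the
imprint accumulates voxels at or above tip depth in order of distance
until its target (2000 mm$^3$). Both targets scale with the
domain/reference volume ratio for reduced phantoms, and both can be
overridden.

## Statistics

* ANCOVA: `Q ~ f + material + f:material` with frequency continuous and
  material categorical, **type-II** F-tests (`car::Anova`); the design
  is balanced, so the type choice does not alter the conclusions, but
  type II is the stated convention.
* LSD letters: pairwise $t$ tests with the pooled residual variance of
  the one-way layout over the eight treatment cells; the letter display
  is derived from the maximal cliques of the non-significance graph,
  ordered by descending group mean — this makes the display invariant
  to input order and reproduces the classic "a / ab / b" overlap
  patterns. Per-material lettering is available by subsetting before
  the call.
* Regressions are ordinary least squares with the two-sided $t$ test on
  the slope; a constant response returns slope 0, $R^2 = 0$, $p = 1$
  rather than an unstable fit.
* Analyses operate on per-replicate means of mechanical resistance
  (each replicate's trace averaged over the full depth) — the natural
  experimental unit.
* A Shapiro–Wilk residual check is provided as a convenience
  diagnostic, never as a gate.

## What the tests do and do not show

Every pipeline stage has a recovery test against generator ground truth,
and the test suite includes property-style checks (exact force
conservation, quadrature of the radial force distribution, equivalence
of the compiled component labelling with a brute-force flood fill,
uniformity of ANCOVA p-values under a simulated null). Passing them
shows the *computational chain* is faithful: it does not validate the
physics on real data. In particular, real CT volumes bring grey-value
drift, beam hardening and partial-volume effects that the phantom does
not emulate (grey normalisation and filtering of real scans are out of
scope here), real force traces may be serially correlated beyond the
optional AR(1), and the true replicate variance of the physical
experiment is not in the generator.

Problem sizes used by the default test and analysis runs, chosen as
desk-scale package defaults: 3600-sample traces × 8 treatments × 5
replicates; 60-sample angle series; 150³-voxel phantoms; 1000 null
simulations for the p-value calibration.

## Known limitations

* The deflection model treats the projected angle as fully informative;
  a single camera cannot observe the 3D orbit, and the formulae are
  applied as defined for the projection.
* The cavity-expansion decomposition assumes unchanged cavity geometry
  under orbital motion; the CT stage can check cavity size but the
  assumption itself is not testable from forces alone.
* The halo-decay estimate carries ~±10% seed-to-seed scatter at the
  default phantom size; finer voxels tighten it at cubic cost in
  runtime.
* The friction-attenuation coefficient of the mechanistic generator is
  a calibration, so the strength (not the sign) of the friction–
  intensity association is a modelling choice.
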