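---
title: "Modelling the angular response of a 2D chamber array as a moving measurement plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the angular response of a 2D chamber array as a moving measurement plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dempqa)
```

## The problem

Planar 2D ionization-chamber arrays (the MatriXX family and its peers) are
designed to measure beams incident perpendicular to their face. In *true
composite* IMRT verification the plan is delivered at its original gantry
angles, and the array's response becomes angle dependent: biases of several
percent have been reported for oblique and posterior fields, bad enough that
composite verification traditionally falls back on radiochromic film.

`dempqa` implements a mechanistic correction. Instead of multiplying the
measurement by empirical per-angle correction factors, the model asserts
that the *effective measurement plane* (EMP) of the array — the plane
containing the effective points of measurement of all 1020 pixel chambers,
nominally 3.5 mm below the detector surface — is displaced along depth by an
angle-dependent offset $\Delta d(\theta)$, and that the thin (0.75 mm)
high-density anode layer beneath the chambers acts on the dose with an
effective density $\rho$. The calculated planar dose that should be compared
with the array is then the treatment-planning dose extracted at the
*displaced* plane, summed per beam:

$$D_{\text{composite}}(x, y) \;=\; \sum_{b}\; D_b\!\left(x,\, y,\,
  d_{0} + \Delta d(\theta_b)\right),$$

with $d_0 = 3.5$ mm the reference (gantry-0) depth, depth positive toward
the detector bottom, and $D_b$ the per-beam 3D dose computed with the anode
region overridden to density $\rho$. Symmetry about the sagittal plane is
assumed: $\Delta d(\theta) = \Delta d(360^\circ - \theta)$, so the table is
stored on $[0^\circ, 180^\circ]$ in $10^\circ$ steps (19 values).
Between tabulated angles the offset is interpolated linearly, except
strictly inside $(80^\circ, 100^\circ)$ and $(260^\circ, 280^\circ)$, where
the angular response is known to fluctuate erratically; queries there are
refused by default (`policy = "error"`), while exact grid angles (90 among
them) are always served.

## Model parameters and calibration

The free parameters are the 19 offsets plus $\rho$ (20 in total). They are
determined from 19 single-beam calibration plans — one per grid angle, each
a static 4 cm × 10 cm jaw aperture on a slab phantom (7 cm buildup, 8 cm
backscatter, source-to-plane distance 100 cm) — by bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm` drives the damping;
the cost, caching and Jacobian are this package's):

* cost: for each plan, extract the calculated planar dose at
  $d_0 + \Delta d(\theta_i)$, sample it at the chamber centers, and take the
  mean squared difference to the measured chamber grid; the total cost is
  the sum over plans (`calibration_cost()`);
* Jacobian: forward finite differences, 0.1 mm steps for the offsets and
  0.05 g/cm³ for $\rho$. An offset column only requires re-extracting one
  plane from the cached per-plan 3D dose; only a change of $\rho$ re-runs
  the engine. Bounds are $\Delta d \in [-20, 20]$ mm,
  $\rho \in [1, 9]$ g/cm³; the fit starts at $\Delta d \equiv 0$,
  $\rho = 2$;
* stopping: relative cost decrease below `relative_cost_tolerance`
  (default $10^{-4}$) or `max_iterations` (default 50). The diagnostics
  carry the cost trace, per-plan residuals, the convergence reason, and the
  Jacobian column norms at the solution as a parameter-sensitivity report.

$\rho$ is identifiable only from posterior beams whose rays traverse the
anode before reaching the extraction plane — in practice the beams near
$90^\circ$–$100^\circ$, where the slant path through the 0.75 mm layer
scales as $1/|\cos\theta|$. A fit on anterior-only data leaves the $\rho$
column of the Jacobian at zero, and the sensitivity report shows it.

At exactly $90^\circ$ the offset is structurally unidentifiable in the
synthetic setup: a horizontal beam through a laterally uniform water column
deposits the same plateau dose above and below the anode notch, so the cost
is flat in $\Delta d(90^\circ)$. This mirrors the field experience that the
response near $90^\circ$ is erratic; recovery tests therefore assert
parameter recovery outside the excluded interiors only.

## The surrogate dose engine

The plane-displacement method is engine-agnostic: any system able to
compute per-beam 3D dose and extract planes can drive it. Rather than
depend on a commercial collapsed-cone engine, the package ships a
documented primary-only surrogate (`compute_beam_dose()`):

$$D(p) = \mathrm{MU}\cdot k \cdot T(p)\cdot
  f\!\big(r(S \to p)\big)\cdot \left(\frac{\mathrm{SAD}}{\lVert S - p
  \rVert}\right)^{2},$$

* $r(S \to p)$ — radiological path (areal density, g/cm²) from the source
  through the voxelized phantom, by exact Siddon-style traversal (C++);
* $f(d) = (1 - e^{-\beta d})\,e^{-\mu d}$, normalized at its maximum
  $d^\ast = \ln((\mu + \beta)/\mu)/\beta$; the defaults
  $\mu = 0.046$ cm²/g and $\beta = 2.8$ cm⁻¹ put $d^\ast$ at 1.47 cm,
  6 MV-like;
* $T(p)$ — separable error-function penumbra of the back-projected
  rectangular aperture, $\sigma = 3$ mm at the isocenter plane, scaling
  with divergence;
* $k$ = 0.01 Gy/MU at calibration conditions.

Two numerical choices matter:

* **Partial-volume slabs.** Voxel densities are exact z-overlaps of the
  slab profile, so the anode keeps its exact areal density at any grid
  spacing and no divisibility condition between spacing and slab thickness
  is needed (the constructor only refuses spacings above 4× the anode
  thickness, where the region of interest becomes unresolvable).
* **Dose grid decoupled from the density grid.** `grid_spacing_mm` lets the
  dose be evaluated on its own lattice — anchored to the volume frame, as a
  TPS dose grid is — while rays always traverse the fixed density
  voxelization, the way a planning system keeps CT-derived density at its
  native resolution. This is what makes the 1 mm vs 0.8 mm grid-robustness
  check measure interpolation error rather than density-quantization noise.

## Planar operations and gamma

Planar doses are extracted from the 3D dose by trilinear interpolation at
the stated depth, sampled at chamber centers bilinearly, and measured
chamber grids are bilinearly resampled to 1 mm with no extrapolation beyond
the outer chambers (cells touching the four unpopulated corner positions
are NA). Calculated planes are convolved with an isotropic Gaussian
(default $\sigma = 2$ mm, configurable) representing the volume-averaging
response of the 4.5 mm chambers; the virtual detector applies the same
kernel, so noiseless self-consistency holds by construction. The
convolution is applied once, to the final composite calculated plane,
before comparison.

Gamma evaluation follows the global (Van Dyk) convention: dose differences
normalized to the reference maximum, a low-dose threshold of 10% of that
maximum, criteria 3%/3 mm and 3%/2 mm, the measurement (resampled) as
reference. The minimization over displacements is exhaustive on a sub-pixel
lattice (pitch DTA/10) within a disc of radius 3×DTA, with the evaluated
dose bilinearly interpolated and an early exit once the distance term alone
exceeds the current minimum. A pixel-only search was tried first and
rejected: with 3% tolerance and penumbra gradients near 6%/mm the evaluated
dose changes by about twice the tolerance between neighbouring 1 mm pixels,
which overstates gamma by up to ~0.5 and breaks noiseless self-consistency.
The test suite keeps an independent plain-R brute-force oracle.

Passing rates of paired modalities are compared with a one-sided paired
t-test (`paired_one_sided_t()`, `stats::t.test` underneath); zero-variance
differences resolve to p = 0 or 1 by the sign of the mean, and identical
samples give 0.5.

## The virtual detector and its truth table

`simulate_measurement()` is the forward model: per beam, 3D dose with the
truth $\rho$, planar extraction at the truth EMP depth, Gaussian volume
averaging, chamber sampling, beam summation, then seeded Gaussian noise
(default 0.5% of the maximum chamber dose; negatives clipped to zero). The
seed is isolated from the session RNG stream.

The default injected truth table (`demp_truth_model()`) is a fixture chosen
once from the mechanism's geometry, not a measured property: offsets creep
up to ~2 mm across the anterior quadrant, flip sign past horizontal, and
deepen to −10 mm at 180°. The negative posterior branch is what reproduces
the deep correction-factor valley toward 180° — the array under-responds to
posterior fields, so the plane must move *away* from a posterior source —
and it keeps the plane above the anode for all posterior angles, making the
$\rho$ mechanism strongest near 90° (the $1/|\cos\theta|$ slant path) and
negligible for anterior beams, whose rays never reach the anode before the
plane. The CF curve itself (`cf_curve()`) is the ratio of central-axis dose
at the EMP to that at the reference plane from the same 3D dose; CF(0°) = 1
whenever $\Delta d(0) = 0$, and the left-right symmetry is inherited from
the model.

**Engine limitation worth knowing:** on a finite-width slab stack a
primary-only engine shows a sharp CF transition at the angle where
posterior rays switch from side-face to bottom-face entry (about 129° at
the physical 30 cm slab width). A scatter-capable engine softens this, and
the measured curves locate their strongest angular sensitivity between
100° and 120°; here the largest CF derivative sits at that entry
transition instead. Tests assert the valley, the symmetry, and the
dominance of posterior-side derivatives over anterior ones — the features
the surrogate genuinely reproduces.

## What the synthetic studies do and do not show

The simulator emulates plane displacement, anode attenuation, volume
averaging, finite 7.62 mm sampling, and per-chamber Gaussian noise. It does
not emulate scatter, couch attenuation, MLC leaf effects, energy response,
array drift, or setup error beyond the explicit plane-shift study — so a
100% self-consistency gamma says the *pipeline* is coherent end to end, not
that a physical array would achieve it. Conversely the uncorrected-vs-
corrected contrast (e.g. 3%/3 mm dropping from 100% to ~64% for a 4×4 cm
beam at 130° with a 5 mm true offset) shows the size of the error the
correction removes under the stated geometry.

## Problem sizes

All studies run on one CPU in minutes: slab phantoms are built at 1 mm
spacing with lateral extents of 120–200 mm (multiples of 4 mm, so the 1 mm
and 0.8 mm dose grids tile the same physical slab; near-horizontal beams
need ≳40 mm of lateral material beyond the outermost sampled chamber to
keep entry buildup and anode-edge clipping off the chamber area), chambers
restricted to the covered region, and per-beam doses computed on thin
z-slabs around the extraction depths. Grid-robustness and density-effect
studies use the 18 calibration plans outside the excluded interval;
recovery studies fit all 19 (90° stays in the fit, unasserted). These sizes
are the package's defaults for its own studies; the functions accept full
detector-sized volumes as well.

## Known limitations

* Primary-only engine: no scatter kernel, no electron contamination, no
  MLC transmission; apertures are rectangles (segments are weighted
  rectangles).
* The excluded intervals are honoured, not modelled; finer sampling of
  $\Delta d$ inside them is out of scope.
* Global normalization only in the gamma module.
* DICOM I/O is not implemented; doses, plans, models and chamber grids use
  the package's text formats.
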