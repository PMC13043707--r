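---
title: "Modelling corneal iontophoresis: electrical-thermal simulation and spectroscopic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling corneal iontophoresis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcorneal iontophoresis drives charged and neutral molecules across the
cornea with a small constant current. Two questions dominate protocol
design: how much Joule heat the current deposits in each corneal layer
(thermal safety), and whether the delivered macromolecule and the tissue
itself remain structurally intact (quantification and spectroscopy).
`corion` implements both arms: a coupled electrical–thermal simulator of a
four-layer cornea, and the downstream fluorescence, FTIR and statistical
analyses, with seeded generators providing every input synthetically.

## Electrical model

The cornea is treated as an electrical series stack: tear film
(0–12 µm, σ = 1.5 S/m), epithelium (12–62 µm, σ = 4×10⁻⁴ S/m), stroma
(62–492 µm, σ = 0.25 S/m) and endothelium (492–512 µm, σ = 6.6×10⁻³ S/m).
For a constant current `I` over cross-sectional area `A`:

* current density `J = I/A`, identical in every layer (series circuit);
* per-layer resistance `R = L/(σA)` and Ohmic drop `ΔV = I·R`;
* volumetric Joule source `Q = s·J²/σ`, constant in time and piecewise
  constant in depth, with a dimensionless source scale `s` (see
  *Calibration* below; `s = 1` is the raw physical value).

The epithelium carries ~96 % of the total resistance, so it is both the
transport barrier and the dominant heat source. No shunt or limbal
pathway is modelled, and impedance is purely resistive (DC).

The cross-sectional area is not reported directly in the source study;
the stated disc radius of 0.6 is only dimensionally consistent with
centimetres, giving the default `A = π·0.6² ≈ 1.131 cm²`.
`back_derived_area()` inverts the nine printed (current, current-density)
pairs at their printed precision and returns the unique consistent
interval's midpoint (≈ 1.13093 cm²); the two areas differ by < 0.01 %.
All interfaces accept mA and cm² and convert to SI internally.

## Thermal model

Temperature follows the one-dimensional Pennes bioheat equation through
the stack depth `x`:

ρc ∂T/∂t = ∂/∂x(k ∂T/∂x) + ω_b ρ_b c_b (T_b − T) + Q_met + Q_joule

with anterior boundary `−k ∂T/∂x = h_conv (T − T_amb) + e_evap`
(convection plus a constant evaporative flux at the tear/air interface)
and posterior boundary `−k ∂T/∂x = h_post (T − T_body)` (perfusion-like
coupling of the endothelial face to the posterior bath). Planar 1-D
geometry is justified by the corneal radius of curvature being an order
of magnitude larger than its thickness.

### Discretization and numerical choices

* **Finite volumes** on a uniform grid (default dx = 2 µm, 257 nodes over
  512 µm), half-width cells at the boundaries, so that the discrete
  enthalpy balance is exact: on an insulated slab the total enthalpy gain
  per step equals integrated source power times dt to machine precision
  (tested at 10⁻⁶ relative).
* **Interfaces on nodes**; a node lying exactly on an interface belongs
  to the posterior (starting) layer. Face conductivities are harmonic
  means of the adjacent node values, which conserves flux across material
  discontinuities.
* **θ-scheme in time**, default θ = 1 (backward Euler), θ = 0.5
  (Crank–Nicolson) available. The protocol time step of 0.1 s at µm-scale
  resolution puts the explicit-stability number α·dt/dx² far above 0.5,
  so an implicit scheme is mandatory; the θ-family is unconditionally
  stable for θ ≥ 0.5. For oracle comparisons against stiff pinned-boundary
  (Dirichlet-like) conditions the tests use θ = 0.55: pure Crank–Nicolson
  is A-stable but not L-stable and sustains ringing on the stiffest
  boundary mode, which a small upward shift of θ damps.
* **Constant-coefficient tridiagonal systems** solved by the Thomas
  algorithm each step; 600 steps over 257 nodes run in well under a
  second, and the full nine-current sweep in a few seconds.
* **Degenerate inputs** (grid coarser than the thinnest layer, dx not
  dividing an interface, non-finite temperatures, singular systems) fail
  loudly with guidance rather than silently interpolating.
* **Run-to-steady-state mode** stops when the largest per-step change
  falls below 10⁻⁶ °C, reconciling the transient 600-iteration protocol
  with a steady-state reading of the same model.

### Calibration of the shipped configuration

The source study specifies geometry, conductivities and the protocol, but
its thermal constants and boundary coefficients live in supplementary
material that the package does not reproduce. The shipped configuration
(`inst/extdata/cornea_default.yaml`) therefore carries a single
*calibrated effective* parameter set — per-layer k, ρ, c, the boundary
coefficients and the source scale — obtained once by a joint Nelder–Mead
fit to the published 500 mA temperature profile (surface maximum at 10 s;
epithelium, posterior-stroma and endothelium maxima at 60 s, with the
tear film required to exceed 100 °C). One set serves every current, time
and target; nothing is re-tuned per target, and the low-current
behaviour follows from the same set by the exact I² scaling of the
linear model.

Two aspects of the fitted set deserve emphasis:

* The fitted stromal conductivity (≈ 7.7×10⁻⁴ W m⁻¹ K⁻¹) is far below
  textbook soft-tissue values (~0.5). This is forced by the published
  profile itself: holding a ≈ 100 °C contrast between the epithelium and
  the endothelium across 430 µm for 60 s requires a posterior thermal lag
  that physiologic corneal diffusivity (α ≈ 1.4×10⁻⁷ m²/s, equilibrating
  the stack in ~2 s) cannot produce in one dimension. The shipped values
  are thus *effective* constants that reproduce the published predictions,
  not tissue-property measurements, and every one of them is
  config-overridable.
* The boundary baths sit at the 34 °C baseline (midpoint of the 32–36 °C
  ocular band), the reading of an ex vivo diffusion chamber; with zero
  evaporative flux this makes the uniform 34 °C initial state an exact
  zero-current equilibrium, so baseline runs are flat, surface temperature
  is non-decreasing in time and strictly increasing in current, and the
  posterior rise at ≤ 2 mA is bounded by pure Joule scaling. Set
  `T_body = 37` and a nonzero `h_post`/`e_evap` for an in vivo boundary.

A consequence of the quadratic source law is recorded openly: with the
500 mA surface rise calibrated to ≈ 48 °C at 10 s, a 3 mA run rises by
48·(3/500)² ≈ 0.002 °C and remains thermoneutral. The published account
instead places 3 mA in the physiological zone (37.3–37.6 °C), which no
single configuration of this (linear-in-T, I²-source) model can reproduce
simultaneously with the 500 mA set; the corresponding acceptance check is
left failing by design rather than patched, and the classifier is
additionally verified against the published temperatures directly.

### Surface conventions

"Surface temperature" is the anterior-region maximum (tear film +
epithelium nodes); the tear-film node at depth 0 and the tear/epithelium
interface node are selectable alternatives. The posterior stroma is the
posterior half of the stromal layer. ΔT is the surface reading minus the
configured baseline.

## Thermal safety classification

Fixed thresholds, right-closed upward: T ≤ 36 °C thermoneutral,
36 < T < 41 physiological, 41 ≤ T < 43 caution, T ≥ 43 damage (a
temperature exactly at a threshold enters the stricter zone — the
conservative reading of an unstated convention). Cumulative-dose models
(CEM43, Arrhenius kinetics) are out of scope; the study uses fixed
thresholds only.

## Fluorescence quantification

Intrinsic tryptophan emission (280 nm excitation, 290–450 nm at 10 nm
steps) is linear in albumin concentration over 0.125–2 mg/ml. The
emission maximum at 345 nm falls between grid nodes; the documented rule
reads the nearest node with ties broken toward the longer wavelength
(350 nm), with an optional local-parabola interpolation. Calibration is
ordinary least squares with a free intercept; prediction inverts the
line on the replicate-mean intensity and *flags* values outside the
validated range as extrapolated instead of rejecting them — the highest
observed group concentration (2.7 mg/ml) lies above the range, and the
flag records that fact without resolving whether the original authors
extrapolated the same line. Background subtraction is available but off
by default (unstated in the source). Inner-filter correction and
endogenous-protein deconvolution are out of scope.

## FTIR pipeline

Processing follows the published order strictly — baseline correction,
9-point Savitzky–Golay smoothing (order 2, the common spectroscopy
choice; order unstated in the source), per-group averaging (n = 10),
second-derivative transformation, band integration — and each spectrum
carries its stage so out-of-order calls fail loudly. Choices:

* **Baseline**: anchor-point piecewise-linear by default (polynomial
  optional); anchor ordinates come from local linear fits so flat and
  sloping baselines are removed exactly, including at the spectrum edges.
* **Second derivative**: Savitzky–Golay with the same window family;
  absorption maxima appear as negative peaks; the derivative of an
  average equals the average of derivatives (linearity, tested to
  10⁻¹⁰).
* **Band areas**: trapezoidal integrals of |d²A/dν²| (raw-absorbance mode
  retained). Percentages default to the full-spectrum integrated area as
  denominator — the reading under which a "total OH area" of ~38 % is
  meaningful — with the flagged reference-set denominator selectable.
* **Band limits are data**, shipped in `extdata/ftir_bands.csv`. Sub-band
  windows not printed in the source (OH components, =CH, CH₂ rocking) are
  package defaults; the amide-I integration window extends to
  1590–1720 cm⁻¹ so the full second-derivative lobe structure of
  components up to 1674 cm⁻¹ is captured, while peak *positions* are
  still searched in the conventional 1600–1700 cm⁻¹ region.
* **Secondary structure**: > 1660 cm⁻¹ β-turn, 1650–1660 α-helix (closed
  at both ends on the helix side), < 1650 β-sheet/random coil.
* The printed water combination relation ν_comb = ν_bend + ν_stretch is
  implemented as stated; its published components (1640 + 3400 cm⁻¹) sum
  to 5040 cm⁻¹, not the observed 2129 cm⁻¹ band — the discrepancy is
  documented, not silently corrected.

Curve-fitting deconvolution of amide I, ATR correction and
atmospheric-water compensation are out of scope.

## Group statistics

One-way ANOVA via `stats::aov`, with constant-group degeneracies handled
explicitly (F = 0, p = 1 when both variance components vanish). Tukey HSD
uses the studentized-range distribution (`stats::ptukey`) on the pooled
within-group variance, Tukey–Kramer standard errors for unbalanced
designs; tests cross-check it against `stats::TukeyHSD` and, for two
groups, against the pooled t test through q = √2·|t|. The study's design
— 10 eyes from 5 animals treated as n = 10 independent samples — is
reproduced without endorsing the independence assumption.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their arguments and a seed (the
caller's RNG stream is saved and restored).

* **Emission spectra**: Gaussian band at 345 nm (FWHM 60 nm), peak
  intensity linear in concentration, multiplicative Gaussian noise
  (default 2 % relative — a typical fluorimeter repeatability).
* **Calibration series**: the serial dilution {2, 1, 0.5, 0.25,
  0.125} mg/ml with a free intercept.
* **FTIR spectra**: sums of Gaussian bands on the 400–4000 cm⁻¹, 2 cm⁻¹
  grid plus a smooth curved baseline and additive noise (SD 0.002 a.u.).
  Amplitudes are calibrated so each band's analytic
  |second-derivative| area is its nominal percentage of the total; five
  group presets encode the published fingerprints (control amide I at
  1666 cm⁻¹ with OH fractions 31.1/4.7/2.2 %; strained-carbonyl and
  thiol bands only in the low-current preset; amide-I shifts to 1659 and
  1674 cm⁻¹ in the high-current and extreme presets). Band FWHMs
  (12–56 cm⁻¹ by band class) are package defaults, chosen once so that
  the full processing chain recovers the nominal fractions within the
  stated ±2-point tolerance.
* **Concentrations**: per-group normals truncated at zero, n = 10,
  SD 0.1 mg/ml, means anchored to the published pattern (indistinct low
  values at ≤ 5 mA, 1.7 mg/ml at 6–7 mA, 2.7 mg/ml at 500 mA).

The generators deliberately do *not* simulate instrument line-shape
asymmetry, scattering (Mie) baselines, inner-filter effects, detector
saturation, or correlated replicate structure. Passing tests therefore
demonstrate that the *processing chain* is correct and self-consistent,
not that real corneal spectra meet the generators' assumptions.

## Problem sizes and runtimes

The shipped defaults keep every computation interactive: thermal solves
use 257 nodes × 600 steps (< 1 s each; the 9 × 3 sweep a few seconds);
FTIR chains process 10 replicates of 1801-point spectra; statistical
null calibrations use 2000 replicates of the 10 × 10 design. The test
suite and the acceptance script each complete in a few minutes on one
CPU.

## Known limitations

* The thermal constants are calibrated effective values (see above), not
  measurements; the model reports nominal temperatures above 100 °C
  without phase change, as the source predictions do.
* Planar 1-D geometry: no radial spreading, no curved-cornea or
  axisymmetric solution, no tear-film evaporation dynamics or
  temperature-dependent properties.
* The electrical layer is DC-resistive; electrode electrochemistry, pH
  shifts and electroosmotic flow are not modelled.
* Fluorescence quantification assumes albumin is the only emitter; at
  destructive currents released endogenous proteins would contaminate
  the signal, which the range flag records only indirectly.
* The low-current thermal claims of the source are mutually inconsistent
  with its 500 mA set under a quadratic Joule source; this package
  follows the physics and documents the divergence rather than fitting
  both.
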