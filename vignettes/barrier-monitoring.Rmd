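---
title: "Equivalent-circuit TEER extraction and barrier analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-circuit TEER extraction and barrier analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(teerfit)
```

## The measurement problem

Microfluidic blood–brain-barrier (BBB) models with integrated thin-film
electrodes are interrogated by electrochemical impedance spectroscopy (EIS):
a small (10 mV) AC excitation is swept across frequencies (1 Hz–100 kHz in
the device this package targets) between an electrode in the vascular
channel and one in the parenchymal compartment, and the magnitude and phase
of the complex impedance are recorded. A mature endothelial barrier raises
the impedance magnitude at low-to-mid frequencies relative to a cell-free
control; at high frequencies every spectrum collapses onto the series
resistance of the culture medium.

Single-frequency "TEER meters" conflate the barrier resistance with
electrode polarisation and matrix capacitance. The approach implemented here
instead fits an equivalent electrical circuit to the whole spectrum and
reads the trans-endothelial electrical resistance (TEER) off the fitted
barrier resistor, normalised by the sensing area:
`TEER = R_TEER × area`, with a default area of 2.35×10⁻³ cm².

## The circuit model and its staged calibration

Two element types suffice: ohmic resistors and constant-phase elements
(CPEs), `Z = 1/(Q (jω)ⁿ)`, which model distributed (non-ideal) capacitance;
`n = 1` is an ideal capacitor. The composite device is represented by four
presets matching an incremental build-up of the biology:

| stage | system | topology |
|---|---|---|
| i | medium + cell-free hydrogel | `CPE_electrode – R_medium – [R_matrix ∥ CPE_matrix]` |
| ii | + astrocytes/microglia | stage i + `[R_cells ∥ CPE_cells]` |
| iii | + endothelium, matrix and brain cells lumped | `CPE_cells_E – R_medium – [R_matrix_cells ∥ CPE_matrix_cells]` |
| iv | complete model | `CPE_cells_E – R_medium – [R_TEER ∥ CPE_BBB] – [R_matrix_cells ∥ CPE_matrix_cells]` |

The element lists mirror what each partial system physically contains; the
wiring (which elements sit in series, which in parallel) is a design
decision of this package, chosen as the simplest ladder consistent with a
non-ideal capacitor in parallel with a resistor for the matrix and barrier
blocks, a series electrode CPE, and an ohmic medium. Alternative
wirings can be supplied via the `topology` argument of `stage_preset()`. The
barrier elements are named `R_TEER`/`CPE_BBB` internally to avoid colliding
with the stage-ii brain-cell elements that share their printed names.

Fitting is staged i → iv, mirroring how the partial systems are measured:
parameters estimated at an earlier stage become bounded priors
(estimate ± 20% by default, `propagation_width`) for every later stage that
contains an element of the same name. The width is configurable because
characterisation protocols legitimately differ on whether earlier-stage
values are frozen or merely re-anchored during later fits.

## The optimizer and its numerical choices

The objective is the *amplitude function*: the mean relative magnitude
deviation, in percent,

```
dev = 100 × mean( | |Z|_obs − |Z|_mod | / |Z|_obs )
```

Phase is reported for diagnostics but excluded from the objective. A fit is
accepted when its deviation is strictly below 2%.

Minimisation uses Powell's direction-set method (`powell_minimize()`) with
Brent line searches, in a transformed space: every parameter is positive and
box-bounded, and is mapped through a logistic on the log scale so the
optimizer works unconstrained. Three numerical points deserve note:

* **Smooth surrogate first.** The amplitude objective is an L1 mean, which
  is non-differentiable wherever a residual crosses zero; near a good fit
  this litters the valley floor with spurious stalls for a direction-set
  method. Each start therefore first minimises the squared relative
  deviation (same minimiser on well-specified data, smooth everywhere) and
  then polishes on the amplitude objective itself. The start is always kept
  as a candidate, so the returned deviation never exceeds the deviation at
  the initial values.
* **Feature-based initialisation.** `R_medium` starts at the high-frequency
  magnitude plateau (mean |Z| over the top half decade); block resistances
  split the mid-band magnitude excess equally; the series CPE coefficient
  comes from the low-frequency magnitude excess; block CPE corners start
  mid-band with n = 0.9. This makes single-start fits deterministic.
* **Block-split multimodality.** Stacked parallel R‖CPE blocks with similar
  exponents are nearly interchangeable, so the objective is multimodal in
  how the low-frequency resistance splits between blocks. Stages that add
  one new block over several carried parameters (ii and iv) are therefore
  fitted in two passes: a pre-pass fits only the new elements with all
  carried parameters pinned, scanning deterministic starts over new-block
  resistance scales (×0.5, ×1.5, ×2.5) and keeping the best deviation; the
  full fit then releases everything within the propagated bounds. On
  noiseless synthetic data this recovers all stage parameters to better
  than 0.1%.

Optional seeded multi-start jitter (`n_starts`, log-uniform ±50%) is
available for rough spectra; ties are broken by iteration count.

## What the synthetic generator emulates

`generate_staged_dataset()` produces the four spectra a staged
characterisation would acquire, from one shared ground truth
(`bbb_ground_truth()`): elements present in several stages carry identical
values. The default truth places the barrier at `R_TEER = 17.83/2.35e-3 Ω`,
i.e. a TEER of 17.83 Ω·cm² — the scale of a mature barrier in this class of
device — over a medium resistance of 500 Ω, a 5 kΩ hydrogel matrix and
electrode/interface CPEs in the 10⁻⁶–10⁻⁵ S·sⁿ range. Noise is
multiplicative log-normal on the magnitude (1% coefficient of variation by
default, chosen so stage-iv fits exercise both sides of the 2% acceptance
bound) and additive Gaussian on the phase (1°). Raw draws are stored in the
`"noise_draws"` attribute so tests can recompute deviations by hand.

The generator does **not** emulate instrument artifacts (drift, inductive
tails, mains pickup), electrode-to-electrode variability, or any biological
time evolution; passing tests demonstrate the correctness of the analysis
chain under the stated statistical assumptions, not robustness to real
instrument pathology.

`generate_permeability_assay()` inverts the apparent-permeability formula as
a forward model and passes it through a known linear calibration, so the
analysis round-trips exactly at zero noise. `generate_drug_timecourse()`
produces saturating-exponential crossing fractions
`plateau × (1 − e^(−rate·t))`; this is a shape emulation of time-dependent
drug crossing reaching a plateau within the hour, not a mechanistic
transport model. Its default rate solves `fraction(15 min) = 78%` for a 96%
plateau, giving 0.1116 min⁻¹ and a 30-minute fraction of 92.6%.

## Barrier assessment

`assess_barrier()` compares a test spectrum against the cell-free control:
the mean |Z| ratio over shared frequencies above a 50 Hz crossover, the band
where a formed barrier visibly lifts the magnitude. With the default
generator truths, a mature barrier (TEER ≈ 17.8 Ω·cm²) lifts the mean ratio
to ≈ 1.04 while a weak one (≈ 3.5 Ω·cm²) reaches only ≈ 1.01, because the
high-frequency tail — where all spectra converge — dilutes the mean. The
default classification threshold of 1.02 sits between the two populations
with a margin of more than four standard errors of the mean ratio under 1%
magnitude noise on the 51-point grid. The threshold is a device-calibration
quantity: with other geometries or electrode areas it should be re-derived
from control measurements, which is why it is a plain argument.

## Permeability

Tracer assays are summarised by the standard apparent-permeability
coefficient

```
P_app = (V_rec × ΔC_rec) / (A × Δt × C_t0)   [cm/s]
```

with calibration-curve inversion (`fit_calibration()`,
`concentration_from_signal()`) converting fluorescence signals to
concentrations. Read literally, the source formula's concentration
difference (receiver minus donor input) is negative for any barrier; the
package defaults to receiver concentration minus an initial receiver
background (zero by default), which keeps P_app in the stated units and
sign, and offers the literal signed form behind `signed = TRUE`. Inverted
concentrations below zero (blank noise under the intercept) are clipped to
zero with a warning rather than erroring. Barrier performance is reported as
the percent reduction relative to the cell-free control; mature and immature
barriers in this device class show ≈ 80% and ≈ 30% reductions respectively.
The diffusion area `A` is a required input: it is device-specific and not
derivable from the spectra.

## Hemodynamics of the perfusion channel

The perfusion channel (1 mm × 50 µm × 15 mm by default) is designed to
expose the endothelium to brain-capillary wall shear (≈ 11–13 dyn/cm²). The
package works in the fully developed laminar limit for a Newtonian
incompressible fluid (culture medium at 37 °C: ρ = 1012 kg/m³,
µ = 0.964 mPa·s):

* `mean_inlet_velocity()`: `u = Q/(wh)` (0.0133 m/s at 40 µL/min);
* `plates_wall_shear()`: `τ = 6µQ/(wh²)` (wide-channel limit; 15.4 dyn/cm²
  at the operating point — the analytic sealed-duct reference value);
* `duct_velocity_field()` / `duct_wall_shear_profile()`: the exact
  Fourier-series solution of the rectangular-duct Poisson problem, with
  overflow-safe `cosh` ratios so extreme aspect ratios evaluate cleanly.
  The series is scaled so the cross-section integral equals Q (to 0.1% at
  65×65 sampling, 101 odd harmonics);
* `reynolds_number()`: the characteristic length (hydraulic diameter
  2wh/(w+h), or channel height) is a required mode because conventions
  differ and neither reproduces sub-0.1 values at this operating point
  (hydraulic diameter gives ≈ 1.3, height gives ≈ 0.7 — laminar either
  way);
* `design_flow_rate()`: inverts the plates formula for a target shear.

Full 3-D simulations of the real device (pillar gaps, parenchymal chambers)
yield somewhat lower wall-centre shear (≈ 11 dyn/cm²) than the sealed-duct
analytic value (≈ 15.4 dyn/cm²) because the pillar openings relieve the
side-wall constraint; such mesh- and geometry-dependent values are outside
the scope of the developed-flow solver, which is validated instead against
an independent finite-difference Poisson oracle (u_max/u_mean = 2.096 for a
square duct, 1.5 in the plates limit, agreement within 1% across aspect
ratios 1–20).

## Problem sizes and runtimes

The default frequency grid is 51 points (1 Hz–100 kHz, 10/decade). A
single-stage fit takes seconds to ~40 s on one CPU depending on the stage;
the full staged calibration of four spectra runs in ~4 minutes. The
validation suite uses one shared noiseless staged dataset plus one noisy
one, 20 seeded replicate pairs for classification, and finite-difference
oracle grids of ~100×100, keeping the whole suite inside a coffee break.

## Known limitations

* Identifiability: with two parallel blocks of similar CPE exponents, a
  *standalone* stage-iv fit cannot uniquely attribute resistance to the
  barrier versus the matrix block — only the staged protocol (or external
  priors) makes R_TEER well-determined. The package mirrors the staged
  measurement design on purpose.
* The amplitude objective discards phase; strongly phase-discrepant but
  magnitude-consistent models are not penalised.
* No Kramers–Kronig validation, Warburg/diffusion elements, or three/four-
  electrode configurations.
* The drug-crossing generator is a descriptive shape, not a transport model;
  HPLC peak integration is out of scope.
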