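---
title: "Coupled heat-moisture modelling of Sichuan pepper drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled heat-moisture modelling of Sichuan pepper drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zbdry)
```

# The problem

Fresh *Zanthoxylum bungeanum* (Sichuan pepper) pericarp carries about
2.03 kg of water per kg of dry matter and spoils quickly; drying it to the
safe storage level of 0.11 kg/kg is the central postharvest step. Three
industrial routes differ in how they put heat into the tissue:

* **HAD** — hot-air drying: convective heating of the surface only;
* **PVD** — pulsed-vacuum drying: infrared panels heat the material in depth
  while the chamber alternates between a 15 min vacuum phase (10 kPa) and a
  5 min atmospheric phase;
* **MVD** — microwave-vacuum drying: volumetric dielectric heating under a
  continuous 10 kPa vacuum.

`zbdry` implements a one-dimensional coupled heat-moisture model of the
drying tissue for all three modes, thin-layer drying-kinetics estimation
(Page model and Arrhenius activation energy), and the quality-scoring chain
(CIELAB colour difference, Chauvenet replicate screening, dehiscence rate,
amide content, min-max normalisation, entropy weights, comprehensive score).
A deterministic synthetic-data module emulates the experimental design so
that every stage of the pipeline is testable without laboratory data.

# The transport model

The solver advances the energy and moisture balances of a homogenised,
rigid, isotropic porous tissue:

$$\rho_m C_p \frac{\partial T}{\partial t}
  = \nabla\cdot(k_p \nabla T) + Q_{mode} - L_v G_{evap}, \qquad
  \frac{\partial C_w}{\partial t}
  = \nabla\cdot(D_w \nabla C_w) - G_{evap},$$

with convective boundary conditions
$-k_p\,\partial T/\partial n = h_t (T_s - T_a)$ and
$-D_w\,\partial C_w/\partial n = h_m (C_s - C_e)$ and symmetry at the
centre. The domain is either a slab (bulk sample layer, half-thickness
10 mm by default) or a sphere (single berry, radius 2.5 mm). Shrinkage,
2-D/3-D geometry and airflow modelling are out of scope; the air speed
enters only through $h_t$.

## Heat sources

* HAD has no volumetric source; all heat enters through the surface.
* PVD deposits the infrared flux volumetrically with a Beer-Lambert profile
  $q(z) = \eta\kappa l_i/\delta\, e^{-z/\delta}$ whose depth integral equals
  the absorbed surface flux $\eta\kappa l_i$ exactly.
* MVD applies a spatially uniform source $\eta P_{mw}\rho_m$ (the nominal
  8 W/g power density scaled by the absorbed fraction $\eta$). The
  dielectric field expression is deliberately never evaluated — there is no
  electromagnetic solve; $\varepsilon'$, $\varepsilon''$ and the frequency
  are retained as metadata only, and $\eta$ absorbs all coupling physics.

Both volumetric sources are modulated by a smooth quintic set-point
throttle (full power half a band below the set temperature, zero half a
band above, 2 °C band by default). This emulates the apparatus'
temperature control; without it a constant calibrated source has no steady
state once the evaporative load disappears.

## Evaporation sink

Evaporation is a distributed sink driven by the deficit between the local
equilibrium vapour pressure and the reference vapour pressure of the
surroundings,
$$G_{evap} = K_{evap}\, C_w\, \max(0,\, p_{sat}(T) - p_{ref})/p_{atm},$$
tapering to zero as the local moisture approaches equilibrium. The
saturation pressure uses the Antoine correlation
$\log_{10} p = A - B/(C + T)$ with the bundled constant set, read as kPa
with $T$ in kelvin — the only reading for which $C = -166.3583$ keeps
$C + T$ positive over the operating range. The resulting curve deviates
from steam tables (its 101.325 kPa boiling point sits at 66.9 °C); it is
used as given because the sink is rescaled by the calibrated rate constant
anyway, but the deviation propagates into every dew-point-like quantity
and is listed under limitations.

The reference pressure is mode-resolved: the total chamber pressure for
the vacuum modes (the chamber gas is then essentially pure vapour — this
is what switches the PVD sink off during the atmospheric phases and
produces the pulsation signature), and the vapour partial pressure of the
9.8 g/kg drying air (≈1.57 kPa) for HAD, where the chamber is at
atmospheric pressure but far from saturated.

## Moisture diffusivity

The empirical correlation $D_w = r^2(-39.41\ln M_t - 8.247)/T$ changes
sign at $M_t \approx 0.811$ kg/kg — i.e. it is non-positive over the whole
wet regime of a material that starts at 2.03 kg/kg. The correlation is
used verbatim wherever it is positive and floored elsewhere. The floor
defaults to the effective Fickian diffusivity implied by the material's own
50 °C MVD drying time for a 2.5 mm berry (first-term sphere solution,
$D = -\ln(MR_{target})/t_{dry}\cdot R^2/\pi^2 \approx 2.8\times10^{-10}$
m²/s), which keeps wet-regime moisture migration self-consistent with the
observed kinetics and sits squarely in the literature range for
high-moisture plant tissue. The internal moisture-gradient measure ΔMR is
sensitive to this closure (the 20-min MVD value spans roughly 0.21-0.39 as
the floor spans 1-4 ×10⁻¹⁰ m²/s), which is the model's single most
influential free closure; it is exposed as `diffusivity_floor`.

## Surface moisture flux

The Robin boundary condition with $h_m = 0.025$ m/s acting on liquid
concentrations (~700 kg/m³) would admit absurd fluxes if taken literally;
the package caps the surface flux by the gas-film vapour-carrying
capacity $h_m (p_{atm}/p_{ch})(\rho_{sat}(T_s) - \rho_v)$. In dense gas
this reproduces wet-bulb pinning of an evaporating surface; under vacuum
the film transport is enhanced in proportion to $1/p$ (vapour diffusivity
scaling) and the chamber vapour density is bounded by saturation at the
condenser temperature (5 °C default — both vacuum apparatuses carry
condensate traps). Latent heat is carried by the volumetric sink only, as
in the model's printed boundary conditions.

## Thermal boundary reference

`wall_temperature` is the temperature of the gas/walls the surface
exchanges heat with: the drying-air temperature for HAD, the set
temperature for MVD (sealed cavity), and 25 °C for PVD. The PVD choice is
deliberate: the PVD chamber is heated radiatively and its walls sit near
ambient next to the condenser circuit; with walls at the set temperature
an inverted (core-hot) field could never form under a convective boundary
condition, because heat would always flow inward at the surface.

# Numerics

Cell-centred finite volumes (30 cells by default), harmonic-mean interface
diffusivities, implicit Euler with Picard iteration. The stiff temperature
feedbacks — the set-point throttle and the exponential growth of
$p_{sat}(T)$ in the sink — are linearised about the current iterate so
they land on the solve diagonal; iteration is damped after the first few
cycles and convergence is tested in the weighted norm with the configured
relative/absolute tolerances (0.01/0.001). Steps are capped at 60 s,
halved when the iteration stalls, when concentrations turn negative or
when a step moves any temperature by more than 2 °C, and grown back in
quiet phases; a step collapsing below 1 s aborts with a diagnostic state.
Both ledgers (energy and mass) are accumulated from the same discrete
quantities that enter the linear solves, so conservation closes to solver
precision on every run — the test suite asserts residuals below 10⁻³ and
typically observes 10⁻¹⁵. Against the analytic separation-of-variables
series for a conduction-only slab the solver agrees to better than 0.1 °C
for Fourier numbers above 0.05 (at 50 cells and 0.25 s steps).

Halving the mesh spacing and the step cap changes the drying time by less
than 2% (asserted in the tests). Default problem sizes — 30 cells,
50 °C runs of 110-475 min simulated time — keep a full three-mode
calibration below about a minute of CPU.

# Calibration

Following the model's stated protocol, the macroscopic source scalars are
calibrated rather than derived:

* `calibrate_source_fraction()` searches the absorbed fraction $\eta$ and
  an evaporation-rate multiplier against a reference drying curve
  (RMSE of volume-mean MR at the reference time points), optionally adding
  the normalised RMSE of a surface-temperature trace — both validation
  channels the study reports. The search is a coarse joint log-grid
  followed by walking coordinate-wise golden-section refinement (the
  window recentres while the optimum lands on its edge, so the search can
  follow the curved $\eta$-$K$ valley). A scalar pinned at a search bound
  with a decisive inward slope raises a bracket error instead of returning
  silently.
* `calibrate_thermal_signature()` tunes one scalar to the reported 20-min
  core/surface temperature difference: the evaporation multiplier for HAD
  (the distributed evaporative sink sets how far the core lags) and the
  infrared penetration depth for PVD (the deposition depth sets how
  strongly the core leads). The kinetic objective alone does not pin these
  field-level quantities.

On the calibrated 50 °C runs the model reproduces the qualitative mode
signatures: a near-uniform MVD field (|ΔT| well below 1 °C), a
surface-hot HAD field and a core-hot PVD field, with the MVD
moisture-ratio fit at R² ≈ 0.999.

# Synthetic data

The generators emulate the measurement structure, not any particular raw
data set: Page-form drying curves $MR = e^{-k t^n}$ with the rate constant
following an Arrhenius law across 40/50/60/70 °C, additive Gaussian noise
on MR (σ = 0.01 by default, gravimetric error), 5-min sampling, truncation
at the target moisture ratio; first-order-lag surface-temperature traces
(τ = 1.5 min for MVD — a power balance shows the absorbed power that
sustains the observed drying rate heats the load from 20 to 50 °C in
about three minutes, i.e. 2-2.5 time constants — 8/6 min for PVD/HAD);
and a 3-method × 4-temperature quality table with triplicate indicator
and quintuplicate colour replicates at the reference SD magnitudes, with
an optional planted colour outlier for exercising Chauvenet rejection.
Per-method defaults fix the activation energies at the reported values
and anchor the pre-exponential factors so the 50 °C drying times match a
log-interpolation of the reported drying-time ranges (110.5, 474 and
259 min for MVD, PVD, HAD). Every generator is a pure function of its
specification and seed.

What passing tests on synthetic data do *not* show: the generators assume
homoscedastic Gaussian noise, exact Page/first-order-lag ground truth and
independent replicates; real drying curves carry autocorrelated residuals,
early-transient artefacts and drift that the round-trip tests cannot
surface. Parameter-recovery accuracy is sampling-limited: at 5-min
sampling the full generate → Page → Arrhenius chain recovers the
activation energy with a median error of about 6% at σ = 0.01 (denser
sampling tightens it roughly with the square root of the point count).

# Quality scoring

The scoring chain is deliberately modular: min-max normalisation with
per-indicator direction flags (colour difference is a cost; dehiscence,
volatile oil and amide are benefits), entropy weighting
($W_j \propto 1 - E_j$ with $0\ln 0 := 0$; uniform or all-zero columns get
zero weight), and the comprehensive score $F = \sum_j d_j W_j$, reported
raw and on the 0-10 display scale on which published scores are quoted.
The published weight vector (0.21, 0.18, 0.22, 0.39) is shipped as a named
constant and used by default for reproducible ranking; entropy weights are
computed on request and the two are never silently mixed, because the
published vector is not reproducible from the published treatment means
under any normalisation convention we tested (the underlying replicate
matrix was never released). For the same reason the published F values and
colour differences (which were computed from replicate-level readings) are
not regression targets; only the formulas are asserted.

# Known limitations

* The Antoine constant set, read as kPa/kelvin, is shifted relative to
  steam tables; dew-point-like quantities inherit the shift.
* The wet-regime diffusivity floor is the single most influential closure;
  ΔMR-type outputs move materially within its plausible range.
* The HAD thermal gradient is structurally capped: with the prescribed
  $h_t = 25$ W/(m² °C) the quasi-steady surface-core difference is bounded
  by $h_t(T_a - T_s)L/2k_p$ while the interior cannot cool below the
  sink-off (dew) temperature of the drying air; the bound evaluates to
  about 4.5 °C at 50 °C, and the calibrated model realises about 3.6 °C.
* There is no electromagnetic or airflow solve, no shrinkage, and the
  1-D geometry cannot represent berry-to-berry heterogeneity.
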