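# zbdry

Coupled heat–moisture drying simulation, thin-layer kinetics and
multi-criteria quality scoring for *Zanthoxylum bungeanum* (Sichuan pepper)
pericarp.

Drying fresh Sichuan pepper from 2.03 to 0.11 kg/kg (dry basis) is the
step that decides both its shelf life and its market quality. Three
industrial routes — hot-air drying (HAD), pulsed-vacuum infrared drying
(PVD, 15 min at 10 kPa alternating with 5 min atmospheric) and
microwave-vacuum drying (MVD) — differ in *where* the heat is deposited,
and therefore in their internal temperature and moisture fields, drying
times and quality outcomes. `zbdry` is for process engineers and
postharvest scientists who want to compare those mechanisms
quantitatively.

The package provides:

* a 1-D finite-volume solver for the coupled energy and moisture balances

  ρ<sub>m</sub>C<sub>p</sub> ∂T/∂t = ∇·(k<sub>p</sub>∇T) + Q<sub>mode</sub> − L<sub>v</sub>G<sub>evap</sub>,  ∂C<sub>w</sub>/∂t = ∇·(D<sub>w</sub>∇C<sub>w</sub>) − G<sub>evap</sub>

  with mode-specific sources (none for HAD, Beer–Lambert infrared
  deposition for PVD, uniform microwave absorption for MVD), a
  pressure-deficit evaporation sink G<sub>evap</sub> = K<sub>evap</sub>C<sub>w</sub> max(0, p<sub>sat</sub>(T) − p<sub>ref</sub>)/p<sub>atm</sub>,
  convective boundary conditions, a C²-smooth vacuum pulsation schedule,
  and exact energy/mass ledgers (`simulate_drying()`);
* calibration of the absorbed-power fraction and evaporation constant
  against reference kinetics and temperature traces
  (`calibrate_source_fraction()`, `calibrate_thermal_signature()`);
* thin-layer kinetics: MR = exp(−k·tⁿ) Page fits and Arrhenius activation
  energy from ln k vs 1/T (`fit_page()`, `fit_arrhenius()`);
* the quality chain: CIELAB ΔE, Chauvenet replicate screening, dehiscence
  rate, amide content, min–max normalisation, entropy weights and the
  comprehensive score F (`score_quality()` and friends);
* deterministic synthetic-data generators emulating the 3-method ×
  4-temperature experimental design (`synthetic_spec()`,
  `generate_drying_curve()`, `generate_quality_table()`), so the whole
  pipeline runs and is tested without laboratory data;
* a command-line interface (`exec/zbdry`) with subcommands
  `simulate`, `fit`, `score`, `synth`, `validate`.

## Worked example

Generate a synthetic MVD data set, fit the Page model per temperature and
estimate the activation energy:

```r
library(zbdry)
spec <- synthetic_spec("MVD")           # 40/50/60/70 C, sigma_MR = 0.01
curves <- lapply(spec$temperatures, function(tt) generate_drying_curve(spec, tt))
fits <- lapply(curves, fit_page)
fits[[2]]
#> Page fit: k = 0.014874 1/min, n = 1.1245 (R2 = 0.9993, RMSE = 0.007398, 24 points)
fit_arrhenius(fits, spec$temperatures)
#> Arrhenius fit: Ea = 26.43 kJ/mol, k0 = 292.41 1/min (R2 = 0.9871)
```

The fitted rate constant roughly doubles from 40 to 70 °C and the
recovered activation energy (26.4 kJ/mol from noisy curves; exactly
25.3 kJ/mol at zero noise) measures that temperature sensitivity — the
energy barrier to moisture migration, lowest for MVD among the three
modes.

Score the bundled reference quality table with the published weights:

```r
sc <- score_quality(quality_table(zb_reference_quality()$table), "reference")
head(sc$scores[order(-sc$scores$F), ], 3)
#>    method temperature     F_raw        F
#> 3     MVD          60 0.9401072 9.401072
#> 7     PVD          60 0.6966746 6.966746
#> 11    HAD          60 0.6459600 6.459600
```

60 °C is the best temperature for every method and MVD at 60 °C tops the
ranking — the weighted (0.21/0.18/0.22/0.39) combination of normalised
colour retention, dehiscence, volatile-oil and amide indicators.

Simulate and calibrate a drying run:

```r
spec0 <- synthetic_spec("MVD", sigma_mr = 0, sigma_temp = 0)
cal <- calibrate_source_fraction(simulation_config("MVD"), material_properties(),
                                 generate_drying_curve(spec0, 50),
                                 temperature_reference = generate_temperature_trace(spec0, 50))
cal$result    # calibrated run: fields, summaries, ledgers
```

From the shell:

```sh
exec/zbdry synth --method MVD --seed 7 --out-dir out/
exec/zbdry fit --curves out/curves_mvd.csv --out-dir out/
exec/zbdry simulate --mode PVD --temp 50 --out-dir out/
```

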