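# flashdose

Pencil-beam-scanning (PBS) dose-rate simulation and FLASH effect
metrics for preclinical ultra-high-dose-rate (UHDR) radiotherapy
studies.

## The problem

The FLASH effect — reduced normal-tissue damage at equal tumor
response when dose is delivered at ultra-high dose rates — is reported
across murine experiments that use incompatible conventions. For
scanned proton beams, "dose rate" may mean the *field average dose
rate* (delivered dose over delivery time) or the per-point *PBS dose
rate*, which can differ by an order of magnitude on the same plan.
Biological endpoints are just as heterogeneous: crypt regeneration is
reported as percentages or absolute counts, survival at different
days, skin toxicity on lab-specific grading scales.

`flashdose` is for medical physicists and radiobiologists who need to
put such entries on a common footing. It provides:

* a 2D Gaussian spot-superposition **dose engine** on the isocenter
  plane (spot maps with rim/corner weight overrides, isodose
  contouring, field size);
* a **delivery timeline simulator** (beam-on time per spot
  `t_fixed + t_perGy · w`, spot/row transit times, repainting,
  multiple fields, serpentine or raster scanning);
* both **dose-rate metrics**: field average dose rate over a 95%
  isodose region, and the threshold-based PBS dose rate
  `(D − 2d̂)/(t₁ − t₀)`, where the window `[t₀, t₁]` is the time the
  point's cumulative dose spends between `d̂` and `D − d̂`; plus
  dose-rate–volume histograms;
* harmonized **FLASH effect metrics**:
  `Effect_crypt = (P_UHDR − P_CONV)/100` for crypt regeneration and
  survival, `Effect_M.d. = (P_CONV − P_UHDR)/100` for moist
  desquamation (sign reversed because the endpoint is adverse),
  absolute-count conversion against a 140-crypt baseline, survival
  coding (0 = alive, 1 = dead) at days 11/20, discretization to
  {−1, 0, 1}, and three-band skin-toxicity harmonization
  (light / moist desquamation / severe);
* a validated **study-record schema** (publication-year window
  1966–2024, controlled vocabularies, non-negativity of physical
  quantities), spreadsheet-style effect sheets with an exclusion log,
  and deterministic synthetic fixture generators.

## Worked example

```r
library(flashdose)

map    <- generate_spot_map(5, 5, 5, 5, w_center = 1, w_rim = 1.2,
                            w_corner = 1.5)
beam   <- beam_model(3)                       # sigma_x = sigma_y = 3 mm
timing <- timing_model(t_spot_fixed = 1, t_spot_per_gy = 10,
                       tau_x = 2, tau_y = 10)
tl   <- build_timeline(map, timing)
grid <- compute_dose_map(map, beam)

tl
#> <timeline> 25 events, 1 field(s), serpentine scan, total 399 ms (0.399 s)

field_average_dose_rate(grid, tl, level_percent = 95)
#> [1] 6.309905

pbs_dose_rate_per_spot(tl, map, beam, dose_threshold(1))
#> <pbs_dose_rate> 25 spots (0 excluded), mean 15.58 Gy/s

field_size_cm2(isodose_mask(grid, 95), grid$spacing)
#> [1] 0.81
```

The 25-spot, 1.2-rim/1.5-corner plan delivers in 0.399 s. Averaged
over the 95% isodose region the field dose rate is 6.3 Gy/s, while
the mean PBS dose rate at the spot centers is 15.6 Gy/s — the PBS
window excludes transit dead time and far-row fringes, which is why
the two conventions must never be compared across studies without
recalculation. The 95% region covers 0.81 cm².

Effect metrics work on arm-level percentages:

```r
effect_crypt(80, 30)                 # UHDR spares more crypts
#> [1] 0.5
effect_moist_desquamation(20, 70)    # fewer UHDR mice reach moist desq.
#> [1] 0.5
crypt_percent_from_count(112)        # against the 140-crypt baseline
#> [1] 80
```

`build_effect_sheets()` turns a full observation table into the named
analysis sheets (`gut_crypt_effect`, `gut_effect_percent`,
`Max_Moist_desquamation_effect01`, ...) with an exclusion log;
`validate_record()` checks study records against the schema. A thin
command-line wrapper lives at `inst/cli/flashdose`
(`dosemap`, `timeline`, `doserate`, `effects`, `validate`,
`fixtures`).

See the methods vignette (`vignettes/flashdose-methods.Rmd`) for the
model assumptions, the threshold and tie conventions of the PBS
dose-rate metric, and what the synthetic-data generators do and do
not emulate.

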