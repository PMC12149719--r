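---
title: "Methods: PBS delivery simulation and FLASH effect harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBS delivery simulation and FLASH effect harmonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashdose)
```

Preclinical FLASH studies report dose rates under at least two
incompatible conventions. For pencil-beam-scanning (PBS) proton
delivery, where dose arrives spot by spot, the *field average dose
rate* (total dose over total delivery time) and the threshold-based
*PBS dose rate* of a point can differ by an order of magnitude on the
same plan. `flashdose` implements both, on top of an explicit
simulation of the delivery, so that dose-rate entries of heterogeneous
murine UHDR-vs-CONV experiments can be recomputed under one
convention. A second group of functions harmonizes the biological
endpoints those experiments report — intestinal crypt regeneration,
survival at fixed days, and skin toxicity — into comparable effect
values, and validates the study-record schema used to catalogue the
experiments.

## Dose model

All geometry lives on the 2D isocenter plane, in millimetres. A
monoenergetic pencil beam is lateral-Gaussian with widths
$\sigma_x, \sigma_y$; a spot $s$ at $(x_s, y_s)$ with weight $w_s$
(Gy) deposits

$$D_s(x, y) = w_s \exp\!\left(-\frac{(x - x_s)^2}{2\sigma_x^2}
  - \frac{(y - y_s)^2}{2\sigma_y^2}\right),$$

and the field dose is the sum over spots. The weight is the Gaussian
*amplitude* — the dose the spot delivers at its own center — not a
monitor-unit or charge quantity; no conversion is applied. Depth
dependence (Bragg peak, SOBP), the nuclear halo, and heterogeneity
corrections are out of scope: the simulation answers *when* dose
arrives laterally, not how it varies with depth.

Two evaluation paths exist and are cross-checked in the tests:
`dose_at_point()` evaluates the analytic sum exactly (no truncation,
no interpolation), and `compute_dose_map()` evaluates it on a regular
grid using the separability of the Gaussian. The default grid uses
spacing $\min(\sigma_x,\sigma_y)/5$ and pads the spot bounding box by
$3.5\max(\sigma_x,\sigma_y)$; refinement tests show field-size
estimates from this default are stable to well under 5%, and the
Gaussian beyond the padded extent carries $<10^{-2}$% of a spot's
amplitude.

Grid-generated spot maps (`generate_spot_map()`) place $n_x \times
n_y$ spots centered on the origin and support the common practice of
boosting boundary weights to flatten the field: the four spots extreme
in *both* index directions take `w_corner`, other boundary spots
`w_rim`, interior spots `w_center`. Degenerate grids follow the same
rule (a 1×1 map is a single corner; every spot of a 2×2 map is a
corner). Only rectangular grids are classified; free-form maps carry
explicit weights.

`isodose_mask()` contours the map at a percentage of a reference
dose. The reference is the map maximum by default; a prescribed dose
can be supplied instead, since the literature is ambiguous about which
is meant by "percent of the total dose". Membership is inclusive
(`>=`) so that exact ties — common in toy integer-valued grids — are
deterministic.

## Delivery timeline

`build_timeline()` realizes the delivery as an ordered list of
beam-on events. Within a painting, spots are visited row by row from
the minimum-$y$ row; the default order is serpentine (boustrophedon),
with plain raster available — both exist on real machines and the
choice is configurable because published machine descriptions rarely
state it. The beam-on time of a spot delivering weight $w$ in one
painting is

$$t_{on} = t_{fixed} + t_{per Gy} \cdot w,$$

a fixed term plus a dose-proportional term (ms and ms/Gy). Consecutive
spots in a row are separated by $\tau_x$, row changes cost a single
$\tau_y$ (fly-back is not modelled separately), paintings are
separated by $\tau_{repaint}$, fields by $\tau_{field}$. Repainting
splits every spot's weight equally across $n$ paintings, each
re-traversing the full map in the same order — the simplest model
consistent with specifying only the number of repaintings and the gap
between them; interleaved-row rescanning is not modelled.

Within an event, dose accrues linearly (constant instantaneous rate).
This is the assumption that makes threshold crossing times well
defined; the micro/macro pulse structure of pulsed machines is
deliberately *not* simulated — pulse parameters are schema metadata
only. `cumulative_dose()` therefore returns a piecewise-linear,
non-decreasing curve that ends exactly at the static analytic dose
(conservation is tested to $10^{-9}$ relative at thousands of sampled
points, with and without repainting and with two fields).

## Dose-rate metrics

**Field average dose rate** (`field_average_dose_rate()`): the mean
dose over the `level_percent` isodose region divided by the total
delivery time. The level defaults to 95% of the maximum, the
convention adopted for cross-study comparability. The numerator is
the *mean dose inside the mask* rather than a prescribed dose, so the
metric is well defined for plans without a prescription; a
prescribed-dose mode is available.

**PBS dose rate** (`pbs_dose_rate_at_point()`): with $c(t)$ the
cumulative dose at a point, $D$ its total dose and $\hat d$ a small
threshold,

$$\dot D_{PBS} = \frac{D - 2\hat d}{t_1 - t_0},$$

where $t_0$ is the time the cumulative dose rises above $\hat d$ and
$t_1$ the earliest time it reaches $D - \hat d$. This two-sided
trimmed window is the form commonly used for scanned beams; it
removes the long tails during which a point receives only distant
spots' Gaussian fringes. Conventions, chosen once and tested:

* **Threshold resolution.** "$\hat d$ in percent" means percent of
  the *local* total dose at the evaluated point (default 1%), so the
  trimmed fraction is the same everywhere; percent-of-prescribed or
  absolute-Gy thresholds are available via `dose_threshold()`, since
  the metric is also commonly stated with an absolute threshold.
* **Tie convention.** $t_0 = \sup\{t : c(t) \le \hat d\}$ (latest
  tie) and $t_1 = \inf\{t : c(t) \ge D - \hat d\}$ (earliest tie).
  With $\hat d = 0$ the window then spans exactly the first to last
  non-zero deposition at the point: dead time before, between-fields,
  or after never dilutes the rate, and a point dosed in a single
  event reproduces that event's instantaneous rate bit-for-bit.
* **Negligibility floor.** Because the Gaussian is never truncated,
  every event contributes mathematically non-zero dose everywhere.
  Contributions below $10^{-12}$ of the point's total dose are
  treated as zero when locating the window (they are far below the
  resolution of double-precision accumulation); the total $D$ is not
  floored.
* **Exclusion, not zero.** Points with $D \le 2\hat d$ raise a
  below-threshold error and are excluded from per-spot summaries
  (`pbs_dose_rate_per_spot()` flags them); reporting 0 Gy/s would be
  indistinguishable from a slow delivery. Plans whose total duration
  is zero make every dose-rate quantity undefined and raise an error
  rather than returning infinity.
* **Mean PBS dose rate** is the arithmetic mean over spot centers
  passing the threshold precondition — the natural reading of "dose
  rate of all spots"; grid-cell means can be formed from
  `pbs_dose_rate_at_point()` over a mask if needed.

The event-based crossing search is validated against a brute-force
oracle that samples the cumulative curve every 0.01 ms; on twenty
random 5×5 plans (weights U[0.5, 2] Gy, σ = 3 mm, 5 mm pitch, 1 ms +
10 ms/Gy beam-on, τ~x~ = 2 ms, τ~y~ = 10 ms — the package's reference
conditions) every spot-center value agrees to better than $10^{-4}$
relative. The 5 mm pitch (≈1.7σ) is a typical clinical PBS spacing
and gives fields flat to a few percent with uniform weights.

`dose_rate_volume_histogram()` bins per-cell or per-spot values into
left-closed bins (last bin closed); out-of-range values go to flagged
underflow/overflow bins and fractions are normalized over everything
supplied, so they always sum to 1.

## Effect metrics and harmonization

Endpoint percentages are compared between the ultra-high-dose-rate
(UHDR) and conventional (CONV) arms on a signed scale in $[-1, 1]$
where $+1$ means UHDR is better:

$$\mathrm{Effect}_{crypt} = \frac{P_{UHDR} - P_{CONV}}{100},
  \qquad
  \mathrm{Effect}_{M.d.} = \frac{P_{CONV} - P_{UHDR}}{100}.$$

The sign flips for moist desquamation because reaching it is adverse;
for crypt regeneration and survival a higher percentage is better.
Absolute crypt counts convert to percentages against an assumed
baseline of 140 regenerating crypts per investigated area
(`crypt_percent_from_count()`; the denominator is a parameter because
assays differ, and counts above it are allowed but flagged). Survival
uses the database's 0 = alive, 1 = dead coding — the reverse of the
usual epidemiological event coding — and any other values are
refused. Days 11 and 20 are the canonical survival assessment days;
other days are excluded (and logged) when building sheets.
`discretize_effect()` maps the continuous value to $\{-1, 0, 1\}$
with a no-effect tolerance ε defaulting to 0, exposed because no
canonical tolerance exists.

Skin-toxicity scales differ between groups; `harmonize_grades()` maps
each study's grade labels onto three severity bands — light,
moist desquamation, severe — via an editable per-study scale map
(CSV-loadable with `read_scale_maps()`). The shipped
`example_scale_maps.csv` is a synthetic illustration, not a
transcription of any published scale.
`percent_reaching_moist_desquamation()` counts an animal as having
reached moist desquamation if its band is moist desquamation *or
severe*: the three bands are ordered by severity, so progressing to
severe toxicity implies having reached the intermediate band. This is
configurable (`include_severe = FALSE`) for sensitivity analyses.
Per-animal grades are worst-grade-over-observation values;
time-resolved scoring is out of scope.

## Study records and sheets

`study_schema()` defines one row per collected parameter, grouped
into general, biological-model, endpoint, machine and dosimetric
attributes, typed as text / number / select / multi-select.
Validation (`validate_record()`) returns violations as data — a
record is valid iff the report is empty — covering mandatory fields,
types, the 1966–2024 publication-year inclusion window,
non-negativity of physical quantities, and controlled vocabularies.
The particle vocabulary ({proton, electron, x-ray, heavy ion}) is
closed by the inclusion criteria; the other vocabularies are openly
extensible because no exhaustive enumeration exists, and unknown
values are *reported*, never silently accepted. Machine and
dosimetric numbers that differ between arms use paired `_conv` /
`_uhdr` columns. Average and PBS/instantaneous dose rates are stored
in separate fields; either may be empty, and missing values are
always empty cells, never 0 or −1.

The canonical on-disk format is UTF-8 CSV with a header row —
scriptability first. `build_effect_sheets()` converts an arm-level
observation table into the named analysis sheets (`gut_crypt`,
`gut_crypt_effect`, `gut_survival_percent`, `gut_survival_01`,
`gut_effect_percent`, `gut_effect01`,
`Max_Moist_desquamation_percent` and its effect sheets), pairing arms
per study/endpoint/day; incomplete pairs go to an exclusion log
rather than failing. The per-animal `gut_survival_01` sheet is
populated only when per-animal statuses are supplied — arm-level
percentages cannot be disaggregated. The exact column layout of the
sheets is this package's own; the sheet names and semantics follow
the published analysis workbooks.

## Synthetic data

The fixture generators are first-class, tested code; they stand in
for the real database, which cannot be redistributed here.
`generate_fixture_studies()` draws per-study CONV percentages
uniformly — U[20, 55] for crypt and survival, U[45, 80] for moist
desquamation, ranges chosen to keep both arms away from the 0/100
truncation bounds at moderate effect sizes — then shifts the UHDR arm
by the true effect in the endpoint's beneficial direction plus
Gaussian noise (default sd 5 percentage points, a plausible
between-replicate spread for cohorts of 8–15 animals), truncating to
[0, 100]. The generator returns its realized ground truth, so
recovery tests are exact: with a 0.3 true effect and 200 studies the
pipeline's mean recovered effect is within 0.05 of truth, and with
zero effect and zero noise it is exactly 0.
`generate_fixture_spotmaps()` produces the reference random plans
described above; `generate_fixture_records()` produces fully
populated, schema-valid study records. All three are deterministic
functions of their seed and restore the global RNG state.

What the generators do *not* emulate: correlations between endpoints
within a study, dose–response structure (arm percentages are not
linked to a delivered dose), unbalanced or missing arms, digitization
error from figure extraction, and inter-lab scoring drift beyond what
the scale maps express. Passing recovery tests therefore shows the
*pipeline arithmetic* is faithful, not that real inter-study
heterogeneity is captured.

## Numerical choices and problem sizes

* Event times are kept in ms as doubles; totals are sums in visit
  order. The hand-checkable constructions (the 2×2 serpentine plan,
  repaint totals) are asserted exactly, on inputs chosen to be
  exactly representable.
* Crossing times interpolate linearly inside events, consistent with
  the uniform-rate assumption. The rise-side event search tolerates a
  $10^{-9}$ relative slack to absorb mass removed by the
  negligibility floor; interpolation then uses the exact target,
  clamped into the selected event.
* Default test and validation sizes: 20 random 5×5 plans for the
  oracle comparison, $10^4$ conservation sample points, 200–1000
  generated cases for property loops, 200 studies for effect
  recovery. These run in well under a minute each on a single core
  and are comfortably beyond the sizes at which the checked
  tolerances stabilize.

## A worked example

```{r example}
map <- generate_spot_map(5, 5, 5, 5, w_center = 1, w_rim = 1.2,
                         w_corner = 1.5)
beam <- beam_model(3)
timing <- timing_model(t_spot_fixed = 1, t_spot_per_gy = 10,
                       tau_x = 2, tau_y = 10)
tl <- build_timeline(map, timing)
grid <- compute_dose_map(map, beam)

total_time_s(tl)
field_average_dose_rate(grid, tl, level_percent = 95)
pbs <- pbs_dose_rate_per_spot(tl, map, beam, dose_threshold(1))
pbs$mean
field_size_cm2(isodose_mask(grid, 95), grid$spacing)
```

The PBS mean exceeds the field average on the same plan — the PBS
window at a spot center excludes the transit dead time and the far
rows that contribute negligibly there, which is precisely why the two
conventions must not be compared across studies without
recalculation.

## Known limitations

* 2D, monoenergetic, lateral-Gaussian only; no depth dose, no energy
  layers, no continuous-motion scanning, no pulse microstructure.
* The PBS dose-rate formula is implemented in its trimmed-window form
  as documented above; published variants differ in threshold
  semantics, and entries computed under a different variant should be
  recalculated before comparison.
* The harmonization bands are only as good as the per-study scale
  maps; the package ships the format and validation, not curated
  mappings of published scales.
* Statistical meta-analysis of effect values (pooling,
  heterogeneity, regression) is deliberately out of scope.
```
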