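---
title: "Manikin data reduction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manikin data reduction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maniclo)
```

## What the package computes

A segmented thermal manikin measures, per zone $i$, a surface temperature
$T_{s,i}$ (held near a 34 °C set-point) and a heat loss $H_i$. `maniclo`
reduces these to the standard clothing parameters in two modes.

**Dry mode** yields thermal insulation. The zone value is
$I_{T,i} = (T_{s,i} - T_o)\,A_i / H_{c,i}$, and three aggregation
conventions produce the whole-body total $I_T$:

* *global* — area-weight the temperatures, sum the heat losses:
  $I_T = (\sum T_{s,i} A_i / A - T_o)\, A / \sum H_{c,i}$;
* *serial* — area-weighted arithmetic mean of the $I_{T,i}$;
* *parallel* — area-weighted harmonic mean (conductance summation).

Serial $\ge$ parallel for any heterogeneous zone set (the AM–HM
inequality), with equality only when all zone insulations coincide; with
a uniform surface temperature, global equals parallel exactly. The global
method is the package default because it stays finite when individual
zones under many overlapping layers lose almost no heat — the situation
in which the per-zone quotient degenerates. Basic (intrinsic) insulation
removes the boundary air layer measured on the nude manikin:
$I_{cl} = I_T - I_a / f_{cl}$, with $f_{cl}$ the clothed-to-nude surface
area ratio. 1 clo = 0.155 m²K/W.

**Wet mode** yields evaporative resistance under isothermal conditions
(air, surface and skin nominally at 34 °C), where evaporation is the only
heat-exchange pathway and the measured heat loss is taken as evaporative.
Vapour pressures come from $p = e^{18.956 - 4030/(T+235)} \cdot RH$ with
$RH$ in percent, which lands directly in pascals: the exponential term
alone is in hPa (about 53.2 at 34 °C), and multiplying by a percentage
carries the factor 100. The wetted skin runs cooler than the controlled
set-point because evaporation extracts heat; the correction
$T_{sk,i} = T_{s,i} - 0.0132\,Q_i$ (flux $Q_i$ in W/m²) lowers the
driving vapour pressure, so the corrected resistance
$R_{et} = (p_{sk}-p_a)A/\sum H_{e,i}$ never exceeds the raw one computed
at the set-point. The clothing-only value mirrors the dry decomposition,
$R_{ecl} = R_{et} - R_{ea}/f_{cl}$, and the moisture permeability index
$i_m = I_T/(R_{et} L)$ (Lewis relation $L = 16.5\times10^{-3}$ K/Pa)
compares the two transfer channels on one dimensionless scale.

## Steady-state selection and quality control

Resistance formulas assume steady state. `detect_steady_state()` scans
windows of a fixed length backwards from the end of the trial and accepts
the latest window in which the whole-body heat loss and the area-weighted
mean surface temperature both have (a) an absolute linear-trend slope of
at most `slope_tolerance` per minute, relative to the window mean, and
(b) a coefficient of variation of at most `cv_tolerance`. The defaults —
`min_duration = 600` s (the conventional "last 10 minutes"),
`slope_tolerance = 0.005`/min, `cv_tolerance = 0.02` — are engineering
choices: no published criterion defines "stable" numerically, so the
package fixes one and exposes every knob. The criterion is applied to the
whole-body series, not per zone: individual zones under heavy layering
are intrinsically noisy at near-zero flux, and the whole-body aggregate
is what the downstream formulas consume.

Replicate runs are screened with `repeatability_check()`: relative
difference above 4% flags the pair for re-measurement. The denominator of
that relative difference is the mean of the two values — a symmetric
choice the convention itself leaves open — and a pair sitting exactly at
the threshold passes.

Per-zone mean heat loss is floored at `heat_loss_floor = 0.01` W before
any division. Instantaneous negative readings (possible near zero flux)
are retained in the averaging; only the final mean is floored, which
preserves the unbiasedness of the global method while preventing division
blow-ups in the zone-level outputs.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `ia` | 0.099 | m²K/W | nude (air-layer) insulation of the reference manikin |
| `rea` | 8.0 | m²Pa/W | air-layer evaporative resistance, bare textile skin |
| `lewis` | 16.5e-3 | K/Pa | Lewis relation |
| `clo_si` | 0.155 | m²K/W | definition of the clo |
| `skin_rh` | 96 | % | observed RH at the wetted textile skin across conditions |
| `heat_loss_floor` | 0.01 | W | division guard at near-zero zone flux |
| `min_duration` | 600 | s | "last 10 min" steady-window convention |
| `slope_tolerance` | 0.005 | /min | steady-state trend criterion (package choice) |
| `cv_tolerance` | 0.02 | — | steady-state scatter criterion (package choice) |
| isothermal tolerance | 0.5 / 3 | °C | warn / fail on $|\bar T_s - T_a|$ in wet mode |

## The wardrobe database

`load_wardrobe()` returns 37 clothing items and 25 ensembles of a Dutch
fire-service clothing system (operational-uniform station wear and
incident turnout gear), 12 ensembles carrying wet measurements, plus two
reference rows: the nude manikin (`AL`, source of $I_a$) and the bare
textile skin (`SK`, source of $R_{ea}$). Compositions are explicit
item-id lists; dressing variants noted only in prose in the source tables
are normalised to the closest item variant, with the note preserved
(e.g. the fully-zipped softshell ensemble maps to item `14A` rather than
`14`; the mapping is a judgement call and editable in the CSV).

`audit_consistency()` recomputes every derived column from its printed
inputs. Published tables round columns that were computed from unrounded
measurements, so recomputation from printed values can land one unit off
in the last digit. Default tolerances are half a printed unit tighter
where possible (±0.0015 m²K/W, ±0.005 clo, ±0.15 m²Pa/W, ±0.015 index);
on the shipped tables exactly two clo entries (ensembles `C4`, `C6A`)
exceed the clo tolerance by this rounding mechanism, by at most one
printed unit. They are reported as audit exceptions rather than silently
tolerated, so any future edit that introduces a genuine error still
surfaces.

Group membership for refits (`operational_uniform` = C1–C3B, `incident` =
C4–C9B) follows the two-population structure of the clothing system; the
original fitted subsets are not enumerated anywhere, so refits report
their own $R^2$ and provenance instead of asserting equality with
published coefficients. The shipped "standard" summation coefficients
(slope 0.835, intercept 0.161 clo) are the conventional summation-method
values, not fitted on this wardrobe, and are labelled as such in
`summation_models.json`; every model is data, not code.

## The synthetic generator

`generate_trial()` is the package's ground-truth instrument. It emulates
what the reductions assume about the real measurement: set-point surface
control at 34 °C, per-zone steady heat loss implied by the true
insulation (dry) or true evaporative resistance (wet), an exponential
start-up transient of the flux (time constant 300 s by default, starting
50% above steady), 10-s sampling, and i.i.d. Gaussian sensor noise
(default 0.05 °C on temperatures, 2% of steady flux on heat loss —
magnitudes consistent with chamber variability below 0.1 °C and humidity
variation below 2%). Default chamber conditions are 20 °C / 50% RH /
0.18 m/s for dry trials and isothermal 34 °C / 40% RH / 0.40 m/s for wet
trials; the default 17-zone geometry sums to 1.77 m² and is a documented
synthetic table, not a measured manikin's.

Wet steady state requires solving a scalar fixed point per zone: the
flux cools the skin, which lowers the driving vapour pressure, which
feeds back into the flux. The generator iterates
$Q \leftarrow \tfrac12 Q + \tfrac12 (p_{sk}(Q) - p_a)/R$ (damping 0.5)
to an absolute tolerance of 1e-6 W/m², failing loudly with the iteration
trace after 50 steps. Noise-free generation followed by reduction is the
exact inverse of the generator in both modes (to that tolerance in wet
mode), which is the property the test suite leans on.

What the generator does **not** model: convection/radiation physics
behind the zone coefficients, garment ventilation, wind and body motion,
drift or autocorrelation in sensors, humidity-sensor lag, and moisture
accumulation in clothing over a wet run. Passing recovery tests therefore
demonstrate that the reduction chain is self-consistent and unbiased
under the stated noise model — not that any particular hardware meets
that model.

## Numerical and validation choices

* Rounding for table reproduction is half-up at the printed precision
  (3 decimals m²K/W, 2 decimals clo and indices, 1 decimal m²Pa/W), with
  a tolerance of one unit in the last printed digit, because published
  derived columns were computed from unrounded inputs.
* $R^2$ is always $1 - SS_{res}/SS_{tot}$ on the fitting data; the
  fixed-slope refit reports it against the constrained fit, so it can
  only fall relative to ordinary least squares (nesting).
* Negative basic insulation or clothing evaporative resistance (possible
  for thin items with $f_{cl}\approx 1$ after last-digit rounding) is
  reported with a warning, never clamped.
* Validation problem sizes: recovery experiments in the tests use 20–100
  seeds of 60-minute trials at 10-s sampling (361 × 17 samples each);
  the Monte-Carlo checks of the steady-state detector use 100 replicate
  white-noise series. These sizes make the Monte-Carlo standard errors
  comfortably smaller than the tolerances being asserted.

## Known limitations

* Zone-level air-layer insulations are not available, so local intrinsic
  insulation per zone cannot be derived — only whole-body $I_{cl}$; the
  wardrobe schema reserves room for local/regional companion tables but
  ships them empty.
* The wet pipeline treats the measured heat loss as entirely evaporative;
  the isothermal deviation check (warn at 0.5 °C, fail at 3 °C) guards
  the assumption but cannot decompose a mixed flux.
* Wind and body-motion corrections, mass-loss evaporative measurement and
  additional skin-material corrections are out of scope.
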