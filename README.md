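# porospr

Carbon-ion and proton treatment planning converts CT numbers to stopping
power ratios (SPR) before computing where a beam stops.  Porous,
bone-like materials — trabecular bone, dried skeletal phantom bone,
hydroxyapatite bone substitutes — mix mineral and air at scales far below
CT resolution.  A single-energy CT (SECT) conversion, which maps each
Hounsfield unit to one SPR through a stoichiometric calibration curve,
has no valid answer for such mixtures: a mineral/air voxel and a
soft-tissue voxel can share a CT number while their stopping powers
differ badly.  A dual-energy CT (DECT) conversion recovers the electron
density and effective atomic number per voxel and is largely immune.

`porospr` implements both conversion routes end to end on fully
synthetic CT data with exact ground truth, so the size and direction of
the porous-bone error — and its effect on beam range — can be studied
and tested on a desktop, without scanner data.  It is written for
medical-physics researchers and students working on CT-based range
prediction.

## The models

**Stopping power ratio (Bethe):**

    SPR = rho_e * [ 1 - ln(I/Iw) / ( ln( 2 me c^2 beta^2 / (Iw (1 - beta^2)) ) - beta^2 ) ]

with relative electron density `rho_e`, mean excitation energy `I`
(Bragg additivity, `ln I = sum(lambda_i ln I_i)/sum(lambda_i)` over
electron fractions `lambda_i = w_i Z_i / A_i`), water value
`Iw = 75.3 eV`, and beam speed `beta = 0.481` at 131.0 MeV/u.

**Dual-energy (energy-subtraction) conversion**, per voxel from a
low/high-kV CT-number pair:

    rho_e = a * ((1 + alpha) HU_H - alpha HU_L) / 1000 + b
    (Zeff / Zeff_w)^m - 1 = gamma_L * (mu_L / rho_e - 1),   mu_L = HU_L/1000 + 1
    ln(I / Iw) = c1 * [ (Zeff/Zeff_w)^m - 1 ] - c0          (soft / bone branch, split at Zeff = 8.8)

with the Mayneord exponent `m = 3.3`.  All constants can be fitted from
calibration-insert scans (`fit_dect_params()`) or taken from the
published 80/135 kV set (`default_dect_params()`).

**Single-energy conversion:** a stoichiometric two-term cross-section
model is fitted to insert scans at 120 kV, used to predict CT numbers of
reference human tissues, and turned into a monotone piecewise-linear
HU-to-SPR lookup table with air/water anchors (`build_hu_spr_lut()`).
The inverse of that table also converts SPR maps into "hypothetical"
120 kV CT volumes for planning systems with a fixed table.

**Range analysis:** water-equivalent path length (WEPL) integrals of SPR
maps along rays, virtual range-pullback measurements
(`SPR = (R_water - R_insert)/L_insert`), and WEPL-based range shifts
between two SPR maps.

## Worked example

```r
library(porospr)

res <- run_experiment(experiment_config(seed = 1))
res$samples[, c("sample", "truth_spr", "dect_error_pct", "sect_error_pct")]
#>            sample truth_spr dect_error_pct sect_error_pct
#> 1 porous_bone_p25 1.9521313    -0.08959871    13.95583864
#> 2 porous_bone_p50 1.3017737    -0.10194327    26.92274858
#> 3 porous_bone_p75 0.6514161    -0.32888175    67.22981146
#> 4       lean_meat 1.0417256    -0.02252708     0.10734130
#> 5      fatty_meat 0.9689557    -0.07127031    -0.09203304

res$range_shifts
#>            ray entry_y target_wepl_mm shift_mm
#> 1 through_bone       0             96 5.681479
#> 2    soft_only      30             96 0.000000
```

One call generates a calibration phantom, fits both conversions,
simulates porous hydroxyapatite samples (25/50/75 % air by volume) and
two soft-tissue samples, and compares region-of-interest SPR means
against a virtual range-pullback measurement.  Reading the table: both
routes are accurate on soft tissue, but the single-energy route
overestimates the porous samples' SPR by +14 % to +67 %, growing with
porosity, while the dual-energy route stays within a fraction of a
percent.  On a head-like phantom with a porous bone cylinder, the
dual-energy map places the end of a beam crossing the bone 5.7 mm deeper
than the single-energy map (`shift_mm > 0`), and rays missing the bone
are unaffected.  The full output bundle (calibration JSON, lookup-table
CSV, SPR volumes as NIfTI, histogram/scatter/range CSVs, run log) is
written under `experiment_config()$out_dir`.

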