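Package: porospr
Title: Stopping-Power-Ratio Estimation for Porous Bone from Single- and
    Dual-Energy CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how single-energy (stoichiometric lookup-table)
    and dual-energy (energy-subtraction) CT-number-to-stopping-power-ratio
    conversions behave on porous, bone-like materials, and what the
    difference means for charged-particle beam range.  Provides closed-form
    radiological physics (relative electron density, Mayneord effective
    atomic number, Bragg-additivity mean excitation energy, Bethe stopping
    power ratio), a synthetic CT scanner and digital phantom generator with
    ground truth, both calibration routes, voxelwise SPR conversion with
    region statistics, water-equivalent path length and range-shift
    analysis, and a one-call experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
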