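---
title: "Single- vs dual-energy CT stopping-power estimation for porous bone: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single- vs dual-energy CT stopping-power estimation for porous bone: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porospr)
```

## The problem

Charged-particle treatment planning needs the stopping power ratio (SPR)
of every voxel to predict where a beam stops.  Clinical planning systems
derive SPR from a single-energy CT (SECT) image through a calibrated
CT-number-to-SPR curve.  That curve is single-valued: each Hounsfield
unit maps to exactly one SPR.  Porous bone-like media — trabecular bone,
the dried bone of anthropomorphic phantoms, hydroxyapatite bone
substitutes with ~75 % air by volume and pores of order 100 µm — are
sub-voxel mixtures of a high-`Zeff`, high-density mineral with air.
Their CT numbers fall in the soft-tissue/spongiosa range while their
electron densities are far lower than any solid tissue with the same CT
number, so the SECT curve systematically overestimates their SPR.  A
dual-energy CT (DECT) conversion estimates electron density and
effective atomic number per voxel and does not rely on the tissue-like
HU–SPR pairing, so it degrades much less.

`porospr` reproduces this comparison on synthetic data where the ground
truth is exact, and quantifies the consequence as a water-equivalent
range shift.

## Physics core

For a material of density $\rho$ with elemental mass fractions $w_i$:

* relative electron density
  $\rho_e = \rho \sum_i w_i Z_i/A_i \,/\, (\rho_w \sum w Z/A)_w$;
* effective atomic number by the Mayneord power mean
  $Z_\mathrm{eff} = (\sum_i \lambda_i Z_i^m / \sum_i \lambda_i)^{1/m}$
  with electron-fraction weights $\lambda_i = w_i Z_i / A_i$ and
  $m = 3.3$;
* mean excitation energy by Bragg additivity,
  $\ln I = \sum \lambda_i \ln I_i / \sum \lambda_i$, over a packaged
  condensed-phase elemental $I$ table (H 19.2 eV, O 106 eV, ...), which
  reproduces the adopted water value $I_w = 75.3$ eV;
* the Bethe stopping power ratio
  $\mathrm{SPR} = \rho_e \left[ 1 - \ln(I/I_w) \middle/ \left(
  \ln\frac{2 m_e c^2 \beta^2}{I_w(1-\beta^2)} - \beta^2 \right)\right]$
  at $\beta = 0.481$ (131.0 MeV/u; computed relativistically from the
  kinetic energy with a 931.494 MeV nucleon rest energy and
  $m_ec^2 = 510\,998.95$ eV).

Shell corrections, the density effect, energy-dependent $I$, and nuclear
interactions are outside the model.

**Self-consistency choice.** `physics_constants()` defaults both $I_w$
and $Z_{\mathrm{eff},w}$ to values *computed from the packaged water
composition* (75.3205 eV and 7.478) rather than rounded literature
numbers.  This makes the water anchors exact: ground-truth SPR of water
is 1 to machine precision, the lookup-table water node is exactly
(0 HU, SPR 1), and calibration round trips close exactly.  The published
dual-energy parameter set (`default_dect_params()`) carries its own
$I_w = 75.3$ eV, and the conversion uses the parameter set's $I_w$ in
the Bethe denominator so that published pipeline is reproduced exactly
as printed.

## The synthetic scanner and phantoms

Each tube setting is modeled as one effective energy — 52 keV (80 kV),
63 keV (120 kV), 68 keV (135 kV), typical effective energies for this
scanner class — with additive Gaussian HU noise (defaults 7, 5, 7 HU;
the dual-energy acquisitions are noisier, mirroring a strongly
noise-reduced clinical protocol, and the values are configurable).
Elemental mass attenuation is a *synthetic* parametric per-electron
cross section: the exact Klein–Nishina incoherent term plus a
photoelectric-like $Z^{3.62}/E^{3.2}$ and a coherent-like
$Z^{1.86}/E^{1.9}$ power law, with the two amplitudes anchored once to
plausible water photoelectric (0.0063 cm²/g) and coherent (0.0112 cm²/g)
values at 60 keV.  It is not a measured cross-section table (a copy is
packaged, clearly labelled, in
`inst/extdata/mass_attenuation_synthetic.csv`); it preserves exactly the
electron-density/atomic-number structure that dual-energy imaging
exploits, which is the mechanism under study.  Water evaluates to 0 HU
at every tube by construction, and HU is exactly linear in per-voxel
volume fractions.

What the generator deliberately omits: polychromatic spectra and beam
hardening, scatter, iterative-reconstruction texture, field-of-view
dependent HU shifts, and anatomy.  Consequences: the stoichiometric
model class used for SECT calibration matches the forward model exactly,
so SECT errors measured here are *partial-volume* errors, not spectral
artifacts — which is precisely the porous-bone mechanism of interest —
and passing tests say nothing about spectral or scatter robustness on a
real scanner.

Three phantom families (all voxel mixtures with named masks and exact
ground truth):

* a calibration phantom: nine tissue-substitute inserts (lung to dense
  bone; bone inserts are hydroxyapatite loadings in a muscle-like
  binder) plus water, as 12-mm cylinders on a ring in a water bore
  (128×128×16 voxels at 1×1×2 mm by default);
* porous slabs: 20 mm of hydroxyapatite/air mixture in water
  (64×64×16 at 1 mm).  Default pore model is `"uniform"`
  (partial-volume mixing) because 150-µm pores are far below voxel
  size; a seeded `"binary"` model exists for resolved pores;
* a head-like phantom: soft tissue with a bone cylinder of 2-mm
  cortical shell around a trabecular interior of 30 % mineral, 20 %
  marrow, 50 % air by volume (128×128×32 at 1 mm) — a dried-skeleton
  condition in which trabecular spaces hold air rather than marrow.

## Calibration fits

**Dual-energy.** `fit_rho_e_params()` is ordinary least squares of
reference $\rho_e$ on (HU$_H$, HU$_L$, 1).  The energy-subtraction form
$\rho_e = a[(1+\alpha)HU_H - \alpha HU_L]/1000 + b$ is over-parameterized
(only $a(1+\alpha)$ and $a\alpha$ are identified), so the raw
coefficients $(c_H, c_L)$ are mapped by $a = 1000(c_H + c_L)$,
$\alpha = -1000 c_L / a$; predictions are identical either way.
`fit_gamma_L()` is least squares through the origin of
$(Z_\mathrm{eff}/Z_{\mathrm{eff},w})^m - 1$ on $\mu_L/\rho_e - 1$.
`fit_i_calibration()` fits $\ln(I/I_w) = c_1 x - c_0$ separately for the
soft ($Z_\mathrm{eff} < 8.8$) and bone ($Z_\mathrm{eff} \ge 8.8$)
branches; the boundary is assigned to bone, and the tie rule is recorded
in the output.  All fits are unweighted; degenerate designs (collinear
HU pairs, no atomic-number contrast, a branch with fewer than two
inserts) raise informative errors or set flags rather than returning
arbitrary numbers.

A statistical note verified by the test suite: with HU noise the
electron-density OLS is unbiased, but the origin-constrained
$\gamma_L$ slope carries noise in its *regressor* and therefore a
classical errors-in-variables attenuation of
$\sum\sigma_x^2 / (\sum x^2 + \sum\sigma_x^2)$ — about 0.1 % of
$\gamma_L$ at 5 HU noise.  The tests assert unbiasedness after this
closed-form correction.

**Single-energy.** The stoichiometric model
$\mu/\mu_w = \rho_e (1 + k_1\tilde Z_1 + k_2\tilde Z_2)/(1 + k_1\tilde
Z_{1,w} + k_2\tilde Z_{2,w})$ with exponents 3.62/1.86 becomes linear in
$(k_1, k_2)$ after cross-multiplication, so the fit is exact least
squares with the water residual identically zero.  CT numbers are then
predicted for a packaged 16-entry reference human-tissue list (air to
cortical bone) and paired with their Bethe SPR.

**Lookup-table construction.** Nodes are the predicted tissue points
plus hard anchors (−1000 HU, SPR 0) and (0 HU, SPR 1); nodes closer
than 0.5 HU are collapsed.  Real tissue sets are not quite monotone —
fat-like tissues carry more SPR per HU than water — so monotonicity is
enforced by weighted pool-adjacent-violators in which the anchors carry
effectively infinite weight; tissue nodes pooled into an anchor's block
are then dropped so the anchors remain exact, unique nodes.  The
adjustment is recorded on the object, and it moves fat-like node
lookups by up to a few percent — an inherent cost of a single-valued
monotone curve, present in clinical calibrations too.  Below −1000 HU
the table clamps to SPR 0; above the last node it extends the final
segment's slope.  Inversion uses the generalized inverse (rising
segments only), sends exact plateau values to the plateau's left edge,
and extrapolates above the last node with the same slope as the forward
curve, so forward–inverse round trips close to machine precision.

## Voxel conversion

`deedz_spr_map()` chains the three dual-energy relations per voxel and
evaluates the Bethe formula.  Choices for cases the equations leave
open:

* voxels with $\rho_e < 0.01$ are classed `"air"` and set to SPR 0 (the
  atomic-number relation divides by $\rho_e$);
* the atomic-number term $x$ is floored at $-1 + 10^{-9}$ so
  $(Z_\mathrm{eff}/Z_{\mathrm{eff},w})^m$ stays non-negative;
* the per-voxel soft/bone branch uses $x \ge x^\*$ with
  $x^\* = (8.8/Z_{\mathrm{eff},w})^{3.3} - 1 \approx 0.712$, the voxel
  analog of the insert-level split;
* negative SPR (possible only through extreme noise) is clamped to 0.

Region statistics use a cylindrical region of interest (default 4 mm
diameter, 9 mm length) with voxel-center membership — the simplest
unambiguous rule.  Histograms default to 0–2.5 SPR in 0.05 bins.
`override_spr_region()` implements the soft-tissue-to-1.0 override used
when only the bone contribution is of interest, and
`spr_to_hypothetical_ct()` pushes an SPR map through the inverse lookup
table so a planning system holding the fixed 120 kV table reproduces the
intended SPR exactly.

## Range analysis

Water-equivalent path length is integrated with nearest-voxel sampling
on a fixed cell grid (default step: a quarter of the smallest voxel
spacing) anchored at the ray entry, which makes the integral exactly
additive over concatenated segments.  The virtual range-pullback
measurement returns $R_\mathrm{water} - \mathrm{WEPL}$ of the sample
segment, so the pullback SPR equals the path-mean SPR identically —
the virtual measurement is unbiased by construction, unlike a physical
dose-based R90 reading with its ~0.5 % uncertainty, which is not
modeled.  Range comparison between two SPR maps is WEPL-based: the
depth at which each map accumulates a target WEPL, interpolated linearly
within a step.  This is the standard dose-free surrogate for a
planning-system range comparison; pencil-beam dose deposition, lateral
scatter, biological weighting and dose-volume statistics are out of
scope, so dose-level numbers from planning studies are not comparable
quantities here.

## The packaged experiment

`run_experiment()` performs the whole design at chosen noise levels and
seed: calibrate both routes, convert porous and soft samples, compare
region means against ground truth and the virtual measurement, run the
head-phantom bone statistics and range shifts (target WEPL: 3/4 of the
head extent), and write a deterministic file bundle.  Default problem
sizes (half a million voxels per head volume, 1 mm grids) keep a full
run around two seconds on one core while leaving every insert and mask
dozens of voxels across.  Percent errors follow the signed convention
$100(\hat s - s_\mathrm{ref})/s_\mathrm{ref}$.

The test suite asserts the qualitative findings this package is built
around: on noiseless porous slabs at 25/50/75 % porosity the
single-energy error is positive and grows with porosity, the dual-energy
error is smaller in magnitude at every porosity, and the dual-energy map
ranges deeper along rays crossing porous bone while water-only rays are
unaffected.  Magnitudes depend on the synthetic scanner and phantom
geometry and are reported by `scripts/acceptance.R`, not asserted as
constants.

## Known limitations

* One effective energy per tube: no spectral effects, so cross-scanner
  transfer of fitted constants is not addressed (the published constants
  are provided for that pipeline instead).
* Insert compositions are synthetic tissue-substitute stand-ins at
  nominal densities; vendor compositions of real calibration phantoms
  are proprietary and differ in detail.
* The zero-porosity mineral slab (solid hydroxyapatite) lies beyond the
  densest reference tissue, so its single-energy SPR comes from
  extrapolation of the lookup table's last segment; this is reported as
  such rather than treated as a calibrated region.
* Range shifts are water-equivalent-depth statements, not dose
  statements.
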