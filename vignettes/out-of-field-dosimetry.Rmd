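---
title: "Out-of-field dose comparison for pediatric photon radiotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Out-of-field dose comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oofdose)
```

## The problem

Radiotherapy delivers a prescribed dose to a planning target volume (PTV),
but healthy organs outside the treatment fields also receive dose — from
collimator scatter, treatment-head leakage, and photons scattered inside the
patient. These *out-of-field* (peripheral) doses are small fractions of the
prescription, yet in pediatric patients they matter: children are roughly an
order of magnitude more radiosensitive than adults, and organs such as the
thyroid develop second tumors after average doses as low as tens of mGy.
Intensity-modulated radiotherapy (IMRT) trades conformity in the target for
a "bath" of low dose over large volumes, typically with more monitor units
(MU) than a conformal (3DCRT) plan of the same prescription, so the
comparison of out-of-field organ doses between the two techniques is a
recurring clinical question.

`oofdose` implements, at desk scale, the full comparison chain for a 54 Gy
(30 × 1.8 Gy) pediatric brain course delivered both ways: six non-coplanar
static fields (269 MU per fraction) versus seven coplanar dynamically
modulated fields (334 MU per fraction). The package covers

* a parametric voxel phantom with the study's organs at their clinical
  center-to-center distances from the target,
* the delivery data model — plan tables, dynamic multileaf-collimator (MLC)
  log files, control-point subsampling into a simulation job list,
* a simplified Monte Carlo photon transport engine with per-organ kerma
  tallies and a reference-condition absolute-dose calibration,
* the thermoluminescent-dosimeter (TLD) reduction chain and its quadrature
  uncertainty budget, and
* the comparison statistics (relative differences, technique ratios, dose
  versus distance).

A synthetic-data module generates every input — TLD readings, MLC logs —
so the whole pipeline runs and is tested without any external data.

## Phantom model

No CT data is distributable, and the quantity the analysis actually uses is
the center-to-center distance between the target and each organ. The phantom
is therefore built from geometric primitives (ellipsoids, boxes, cylinders)
voxelized onto a regular grid, with each organ center placed along an
anatomical direction at *exactly* its clinical distance from the PTV center:
right eye 6.2 cm, left eye 8.4 cm, C-spine 11.1 cm, thyroid 13.1 cm, right
lung 21.7 cm, heart 22.2 cm, left lung 23.3 cm. Voxelization recovers these
distances to within half a voxel diagonal.

```{r distances}
ph <- pediatric_phantom()
sapply(tld_reference_doses()$organ, function(o)
  round(organ_distance(ph, "ptv", o), 2))
```

Design choices worth knowing:

* **Coordinates.** Right-handed patient system — x to the patient's left,
  y anterior, z superior — with the isocenter at the PTV center; lengths in
  cm; voxel centers at `origin + (index + 0.5) * voxel_size`.
* **Target volume.** The elliptical PTV is interpreted as 9.8 cm³ *volume*
  (the plausible reading of an "elliptically shaped" target "with 9.8 cm(3)");
  semi-axes in ratio 1.4 : 1 : 1. The volume is configurable.
* **Eye placement.** The orbits sit anterior with only a small inferior
  offset (≈1.7 cm), i.e. near the axial plane through the target. This is
  the anatomy of a frontal-lobe target: it is what makes coplanar axial
  fields traverse the orbit region and is the geometric reason the modulated
  plan irradiates the eyes heavily, consistent with the measured data this
  package models (right-eye dose of order 20% of prescription under IMRT,
  and eye dose objectives in the inverse planning).
* **Overlaps** resolve in painter's order (later organ wins) —
  deterministic and simple.
* **Grids.** Default 2 × 2 × 3 mm (≈0.9 M voxels over the body), chosen so
  the full test suite and the acceptance analysis run in seconds to minutes
  on one core; the CT-resolution 0.9766 × 0.9766 × 3 mm grid of the source
  voxel phantom (≈47 M voxels) is available via `clinical_grid()` /
  `pediatric_phantom(voxel_size = ...)`.
* **Lung** uses low-density (0.26 g/cm³) lung material for transport, while
  the TLD conversion step uses the bundled per-organ 6 MeV coefficients
  (soft-tissue-like for lung) — the two stages deliberately follow their own
  conventions.

## Material data

Photon coefficients live on a 0.01–10 MeV log grid. Water, air and cortical
bone mass attenuation (μ/ρ) and mass energy-absorption (μen/ρ) tables are
transcribed from the standard NIST compilations. Soft tissue, brain, lung
and thyroid are water-equivalent tissues scaled by electrons per gram —
accurate at megavoltage energies for these near-water materials — with the
thyroid table anchored so its 6 MeV μen/ρ equals the bundled organ
conversion value 0.0194 cm²/g (the value used in the measurement campaign;
generic soft tissue would be ≈0.0179). The tungsten alloy entry is an
edge-free Klein–Nishina + photoelectric power-law + pair parametrization; it
backs the collimator-attenuation surrogate only. Lookups interpolate
log-log between tabulated energies and refuse to extrapolate.

## Transport engine

The engine replaces a general-purpose Monte Carlo code with the minimum
physics that reproduces out-of-field dose structure at megavoltage energies:

* **Source.** A point-like target 100 cm from the isocenter with a Gaussian
  focal spot (1.2 mm FWHM) and a parametric 6 MV spectrum,
  p(E) ∝ E·exp(−E/0.9 MeV) on 0.25–6 MeV (mean ≈1.8 MeV); monoenergetic
  mode for physics tests. One *source particle* is one photon emitted into
  the maximum 40 × 40 cm collimated cone; photons are importance-sampled
  onto the jaw rectangle plus a 3 cm margin and carry the area fraction as
  statistical weight. This normalization is what makes per-particle tallies
  — and hence the reference conversion factor — transferable across field
  sizes.
* **Collimation surrogate.** Photons geometrically blocked by leaves carry
  1.7% weight, blocked by jaws 0.2%, and 0.1% of histories are emitted
  isotropically from the target as head leakage — typical published values
  for this linac class, all configurable (`collimation_model()`). The full
  treatment-head geometry is deliberately out of scope.
* **Tracking.** Woodcock delta-tracking against an energy-dependent
  majorant (maximum linear attenuation over the materials present, ×1.05
  safety), so voxel boundaries never need ray-tracing.
* **Interactions.** Klein–Nishina Compton scattering (sampled by the
  standard composition–rejection method), photoelectric absorption, and
  pair production above 1.022 MeV emitting two back-to-back 511 keV photons.
  Channel probabilities decompose the tabulated total μ into an analytic
  Klein–Nishina part, an E⁻³ photoelectric term anchored at 30 keV, and
  pair as the remainder; the small coherent-scattering residue of the
  with-coherent tables is folded into local absorption (Rayleigh transport
  is omitted — a ≲ few % effect at these energies, for a large speed gain).
* **Scoring.** A track-length kerma estimator: at every Woodcock collision
  point (real or virtual) the tally adds w·E·(μen/ρ)/μ_majorant to the
  organ containing the voxel. Dose is collision kerma; electrons are never
  transported, which mirrors the electronic-equilibrium assumption the TLD
  conversion itself makes, and subsumes the 0.1 MeV electron cutoff of the
  reference calculation. The photon cutoff is 0.01 MeV.
* **Variance reduction.** Russian roulette below a weight threshold
  (survivors' weights divided by the survival probability) plus optional
  integer splitting at birth; both are validated unbiased against a
  closed-form slab benchmark.
* **Statistics.** Tallies run in ≥10 batches (default 20) with independent
  RNG streams (xoshiro256++, seeded deterministically from the user seed);
  per-organ relative standard errors come from the batch means. A fixed
  seed gives bit-stable results on one platform.

### Geometry of a beam

`beam_frame()` maps plan angles to a source position and collimator axes:
gantry rotates the source about the patient z axis, the couch kick about the
vertical y axis, the collimator about the beam axis. Of the two possible
couch sign conventions the package uses the one under which the non-coplanar
brain fields enter superiorly, away from the orbits — the anatomically
sensible reading of the plan (the other sign would drive a 63 MU field
nearly through an eye, contradicting the sub-Gy measured 3DCRT eye doses).
The plan table's SSD column is parsed and validated but the simulation is
isocentric (SAD 100 cm, phantom fixed), so SSD is emergent from the phantom
surface rather than imposed.

### Absolute dose

`calibrate_cf()` simulates the reference condition — water phantom with its
surface at the isocenter (SSD 100 cm), 10 × 10 cm field, MLC retracted — and
returns the conversion factor CF mapping tally units to mGy such that the
scoring volume at 10 cm depth receives 10 mGy per MU (both depth and dose
level are explicit configuration, since only the geometry is standard).
`simulate_plan()` then accumulates organ dose = Σ_jobs tally × CF × MU ×
fractions, with one job per static field and one job per subsampled MLC
control point (indices 5, 10, …, 100 of each 100-point log, i.e. 20 per
field, 140 jobs for the seven-field dynamic plan), each selected control
point carrying an equal share of the field MU. Equal weighting is the
simplest consistent reading of uniform index subsampling; the reference
analysis does not state its apportionment.

## TLD chain and uncertainty budget

The reduction chain is

K_air = RD × Ecc × f(Q) × f(fad) × f(E) × f(α) / RCF,
D_tissue = K_air × (μen/ρ)_tissue / (μen/ρ)_air,

with the coefficients at 6 MeV (the convention of the measurement campaign,
kept even though the mean energy of a 6 MV spectrum is nearer 2 MeV), fading
and angular corrections fixed at 1, and per-organ averaging when an organ
holds several dosimeters (1, 1, 2, 4, 2, 12, 16 across the seven organs plus
the C-spine group — 38 dosimeters per technique). The uncertainty budget
combines element correction (3.0%), reader stability (3.8%), reader
calibration (15.0%) and energy dependence (1.4%, rectangular, stored already
standardized) in quadrature:

```{r budget}
combine_uncertainty(uncertainty_budget())
```

Reported organ SDs follow the campaign's convention: SD = mean × the
combined uncertainty quoted at 0.1-percentage-point precision (15.8%). That
convention — not the unrounded 15.824% — reproduces every published SD cell
(e.g. 593.0 mGy → 93.7 mGy).

## Synthetic data generator

The generator is the exact inverse of the reduction chain. For organ truth D:

RD = D × (μen/ρ)_air/(μen/ρ)_tissue × RCF / (Ecc · f_Q · f_E) × noise,

where per-dosimeter Ecc values are drawn around 1 *and recorded in the
output* (so they cancel exactly — the noiseless round trip is exact to
numerical precision), and `noise` is unit-mean multiplicative log-normal
with relative SD equal to the combined budget (15.8%). Log-normal keeps
readings positive and matches the budget's relative formulation; the
unit-mean parameterization makes recovered organ means unbiased. A
`decomposed` mode perturbs Ecc, f(Q), RCF and f(E) individually with their
component spreads (recorded factors stay nominal), which is how the tests
validate that the quadrature budget matches the realized spread.

MLC logs are generated as sliding-window trajectories: the leaf pairs whose
0.5 cm strips fall inside the jaw Y opening (pairs 27–34 of the 60-pair,
Millennium-120-like bank) sweep smoothly varying gaps across the jaw X
range; all other pairs stay parked closed outside the jaws; the cumulative
MU fraction increases strictly to 1. A fixed seed yields a byte-identical
file. What the generator does *not* emulate: optimizer-shaped fluence (the
windows sweep uniformly rather than concentrating fluence near organ-sparing
objectives), vendor binary log formats, within-organ dosimeter placement
(all dosimeters of an organ sample the same true mean), and detector-level
glow-curve physics. Passing tests therefore demonstrate the correctness of
the chain — inversion, counting, weighting, statistics — not clinical
realism of any individual fluence map.

## What the simulations can and cannot reproduce

The package's simulated doses are used for *structural* claims that are
robust to the simplifications: in-field dose exceeds every out-of-field
organ dose; out-of-field organ dose falls with distance from the target
(rank correlation ≤ −0.8 across the seven organs for the modulated plan);
and the modulated technique delivers more dose to the eyes than the static
technique under the packaged plans. The published *measured* organ doses
(e.g. 13 040.6 vs 593.0 mGy for the right eye) are inputs — generator truths
and comparison-stage data — never claimed as simulator outputs: reproducing
them would require the validated treatment-head model, the CT anatomy and
the clinical fluence maps, all out of scope.

## Numerical choices and problem sizes

* Default transport: 20 batches, roulette threshold 0.05 with survival 0.2,
  photon cutoff 0.01 MeV, no splitting.
* The statistical-quality analysis runs the first static field at 10⁷
  histories (the engine does ~2.5 M histories/s on one core), which takes
  the nearest-organ (right eye) tally comfortably below the 5% relative SE
  reporting threshold; at the 2 × 10⁶ floor the estimate sits at the
  threshold itself.
* Whole-plan simulations in the tests use 2 × 10⁴ histories per job for the
  140-job dynamic plan and 2 × 10⁵ per static field — enough for the rank
  and direction-of-effect checks at a few-minute total test budget.
* Round-trip recovery checks use 200 seeded replicates; budget-convergence
  checks 500.
* Closed-form benchmarks (slab attenuation, Klein–Nishina moments,
  inverse-square, variance-reduction unbiasedness) are asserted at 3σ of
  their batch or sampling errors.

## Known limitations

* No electron/positron transport: dose is collision kerma, so buildup
  regions and interfaces are approximate (irrelevant for organ-mean
  out-of-field estimates under near-equilibrium, which is also the TLD
  conversion's own assumption).
* The treatment head is three numbers (two transmissions and a leakage
  fraction), not a geometry; collimator-scatter angular structure is absent.
* Tissue tables are water-scaled; bone and lung heterogeneity enter only
  through density and electrons per gram.
* The 6 MV spectrum is parametric and fixed, not tuned to depth-dose data.
* Dynamic delivery is approximated by 20 equally weighted static snapshots
  per field, the same subsampling the reference analysis used.
* VMAT arcs and planning-system dose recomputation are out of scope; TPS
  doses enter only as imported tables in the comparison stage.
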