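# oofdose

Out-of-field (peripheral) organ-dose comparison for pediatric photon
radiotherapy: 3D conformal (3DCRT) versus intensity-modulated (IMRT)
delivery of a 54 Gy brain course, at desk scale.

## Who this is for

Medical physicists and radiation-protection researchers who want a small,
fully self-contained model of the out-of-field dosimetry chain: how
treatment-plan geometry and dynamic MLC motion translate into doses to
healthy organs centimeters-to-decimeters from the target, how TLD
measurements of those doses are reduced and their uncertainty propagated,
and how the two delivery techniques compare. Out-of-field doses matter most
in children, whose radiosensitivity is roughly ten times an adult's and in
whom tens of mGy to the thyroid measurably raise second-tumor risk.

## What's inside

* **Phantom** — a parametric pediatric voxel phantom whose organs sit at the
  clinical center-to-center distances from the target (right eye 6.2 cm …
  left lung 23.3 cm), with packaged photon coefficient tables (NIST-style
  μ/ρ and μen/ρ, 0.01–10 MeV).
* **Plan** — delivery tables for both techniques (six non-coplanar static
  fields, 269 MU; seven coplanar dynamic fields, 334 MU), a documented
  dynamic-MLC log dialect, and control-point subsampling: indices
  5, 10, …, 100 of each 100-point log → 20 snapshots per field → 140
  simulation jobs for the dynamic plan.
* **Transport** — a simplified Monte Carlo photon engine (Rcpp): Woodcock
  delta-tracking, Klein–Nishina Compton scattering, photoelectric
  absorption, pair production, parametric 6 MV source with a
  transmission/leakage collimation surrogate, track-length kerma tallies
  with batch statistics, Russian roulette + splitting, and a
  reference-condition calibration (10 × 10 cm, SSD 100 cm, water) that maps
  tallies to absolute mGy:

  dose(organ) = Σ_jobs tally × CF × MU_job × fractions.

* **TLD** — the reduction chain
  K_air = RD·Ecc·f(Q)·f(fad)·f(E)·f(α)/RCF, then
  D_tissue = K_air·(μen/ρ)_tissue/(μen/ρ)_air at 6 MeV, organ averaging,
  and the quadrature budget √(3.0² + 3.8² + 15.0² + 1.4²) % = 15.8 % (k = 1).
* **Compare** — relative differences |calc − meas|/meas × 100, per-organ
  technique ratios with transparent aggregation, dose-versus-distance
  tables and plots.
* **Synthetic data** — exact-inverse TLD reading generator with the stated
  noise budget (38 dosimeters per technique), sliding-window MLC log
  generator (moving pairs 27–34), and the packaged plan fixtures.

## Worked example

Generate a synthetic TLD campaign for the modulated technique, reduce it,
and compare the published measurements between techniques:

```r
library(oofdose)

rec <- generate_tld_readings(generator_config(seed = 42), "IMRT")
reduce_tld(rec)
#>        organ technique mean_mGy   sd_mGy  n
#> 1  right_eye      IMRT 11787.81 1862.474  1
#> 2   left_eye      IMRT  7118.77 1124.765  1
#> 3    c_spine      IMRT   202.86   32.051  2
#> 4    thyroid      IMRT    75.40   11.913  4
#> 5      heart      IMRT    30.51    4.820  2
#> 6 right_lung      IMRT    35.56    5.618 12
#> 7  left_lung      IMRT    28.03    4.428 16
```

Each row is the mean of the organ's dosimeters after the full reduction
chain; `sd_mGy` is mean × the combined 15.8 % measurement uncertainty — the
reporting convention of the underlying campaign. The generator truth here is
the bundled reference table, so e.g. the thyroid (true 79.4 mGy, 4
dosimeters) is recovered as 75.4 mGy within its ~8 % sampling error.

```r
ref <- tld_reference_doses()
technique_ratio_table(
  data.frame(organ = ref$organ, dose_mGy = ref$dose_imrt_mGy),
  data.frame(organ = ref$organ, dose_mGy = ref$dose_3dcrt_mGy))
#> <oof_comparison> IMRT vs 3DCRT
#>        organ dose_a_mGy dose_b_mGy rel_diff_pct  ratio
#> 1  right_eye    13040.6      593.0    2099.0894 21.991
#> 2   left_eye     6525.3      475.2    1273.1692 13.732
#> 3    c_spine      182.3      180.9       0.7739  1.008
#> 4    thyroid       79.4       69.7      13.9168  1.139
#> 5 right_lung       37.4       28.0      33.5714  1.336
#> 6      heart       30.6       25.2      21.4286  1.214
#> 7  left_lung       27.1       19.8      36.8687  1.369
#> mean relative difference: 497.0%   mean ratio: 5.97
```

The eyes — nearest the target and traversed by the coplanar modulated
fields — dominate the technique difference (ratios 22× and 14×), while
distant organs see 1.1–1.4×; the arithmetic-mean ratio (5.97) is printed
alongside the per-organ values so the averaging convention is auditable.

End-to-end Monte Carlo, from phantom to absolute organ dose:

```r
ph  <- pediatric_phantom()
pl  <- load_fixture_plans(seed = 1)
src <- source_model(); col <- collimation_model()
cal <- calibrate_cf(src, col, transport_config(n_histories = 4e5, seed = 7))
imrt <- simulate_plan(ph, pl$plan_imrt, src, col,
                      transport_config(n_histories = 2e4, seed = 21), cal)
dose_vs_distance(imrt[imrt$organ %in% tld_reference_doses()$organ, ], ph)
```

which returns the seven organs sorted by distance with simulated course
doses in mGy, falling monotonically (rank correlation ≤ −0.8) with distance.

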