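# credkit

Offline computational core of a semi-automated **continuous-rotation
electron diffraction** (cRED / MicroED) workflow with a **SerialED**
crystal-screening front end.

Submicrometre crystals — zeolites, MOFs, pharmaceuticals — diffract
electrons well enough for full structure determination, but collecting a
rotation data set on one crystal involves a pile of bookkeeping that has
to be exactly right before XDS or DIALS will integrate the frames:
detector geometry, beam centre, lens distortion, per-frame oscillation
angles, and the angular gaps left by crystal-tracking snapshots. credkit
implements that bookkeeping, the screening classifier used to pick which
crystal to shoot, the quality control used to judge whether the crystal
stayed in the beam, and a rotating-crystal simulator so all of it is
testable without a microscope. It is aimed at electron crystallographers
and at developers of acquisition software who need a reference
implementation of the conventions.

## What is implemented

| Area | Functions | Model / convention |
|---|---|---|
| Electron optics | `electron_wavelength`, `resolution_at_radius` | relativistic de Broglie wavelength, λ = h/√(2m₀eV(1+eV/2m₀c²)); d = λ/(2 sin(½ arctan(r/L))) |
| Timepix geometry | `expand_timepix`, `cross_untrusted_rectangles`, `apply_flatfield` | 512→516 module-gap expansion (counts split ÷3, conserved); XDS `UNTRUSTED_RECTANGLE` masks |
| Beam centre | `center_gaussian_max`, `center_top_percentile`, `median_center` | smoothed arg-max (σ = 10–30 px) for processing; top-5% centroid for screening; component-wise median over frames |
| Distortion | `fit_elliptical_distortion`, `geo_corr_tables` | direct least-squares ellipse fit; e = √(1−(b/a)²); affine correction as XDS `GEO_CORR` tables (integer hundredths of a pixel) |
| Schedule | `build_schedule`, `oscillation_angle`, `excluded_ranges`, `dials_exclusions` | n data slots : 1 defocus-tracking slot (n = 10 typical); oscillation = tilt range / total time × frame time; `EXCLUDE_DATA_RANGE` / `scan_range` bookkeeping |
| Screening | `preprocess_pattern`, `cred_cnn`, `isolation_filter`, `write_candidates` | crop 400² about the beam → cap at μ+4σ → scale to [0,1] → 150²; CNN (batch 75, 20 epochs, dropout 0.15, BCE, RMSprop); 1.5 µm neighbour / 0.5 µm edge rules |
| I/O | `write_smv`/`read_smv`, `write_mrc`, `write_tiff16`, `write_xds_inp`, `write_dials_params`, `write_redp`, `write_experiment_log` | SMV (ADSC dialect), MRC mode 2, baseline TIFF16; XDS.INP, DIALS parameters, REDp tilt table, YAML log |
| QC | `scale_series`, `tracking_flags` | per-frame summed counts outside the beam disc, median-normalized; dip/run-length verdict |
| Simulation | `synthetic_experiment`, `simulate_rotation_series`, `simulate_pattern_classes`, `simulate_crystal_field` | kinematic rotating-crystal model on the Ewald sphere, r = Lλ/d projection, Poisson noise, aperture-overlap attenuation |
| Pipeline | `cred_run`, `inst/scripts/credkit` | `simulate` / `process` / `screen` / `export` with YAML config and seeds |

## Worked example

Derive the integration geometry of a typical run — 430 data frames,
every tenth pattern replaced by a tracking snapshot — and write the XDS
input:

```r
library(credkit)

sched <- build_schedule(n_data = 430, n_interval = 10,
                        frame_time = 0.512, start_angle = -43.90,
                        rotation_speed = 102.55 / 224.7)
sched
#> Acquisition schedule: 430 data + 43 defocus-tracking slots (n_interval = 10)
#>   0.2337 deg/frame at 0.456 deg/s, angles -43.90 to 66.63 deg, slot 0.512 s (delay 0.2 s)

electron_wavelength(200)
#> [1] 0.02507934

oscillation_angle(102.55, 224.7, 0.512)
#> [1] 0.2336698

excluded_ranges(sched)[1:3, ]
#>      first last
#> [1,]    11   11
#> [2,]    22   22
#> [3,]    33   33

write_xds_inp(sched, beam_center = c(257.8, 255.2),
              beam = beam_parameters(200, 250, 55), "XDS.INP")
```

The schedule interleaves 43 tracking slots among 473 slots total; each
gap sweeps exactly one 0.2337° frame oscillation, so XDS can treat the
excluded frames as ordinary missing images. The wavelength at 200 kV
rounds to the familiar 0.02508 Å. `XDS.INP` contains one
`EXCLUDE_DATA_RANGE` line per gap, the two `UNTRUSTED_RECTANGLE` strips
masking the Timepix module cross, and the beam centre you measured with
`median_center()` over `center_gaussian_max()` estimates.

The full simulate → process → export loop, including screening, runs
from a shell:

```sh
Rscript inst/scripts/credkit simulate --out run1 --seed 7
Rscript inst/scripts/credkit process  --out run1
Rscript inst/scripts/credkit export   --out run1
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the externally checkable quantities of the workflow: the
relativistic wavelength at 200 kV, the number of tracking images a
430-frame/interval-10 schedule interleaves, and the eccentricity the
distortion fit recovers from noiseless ring points with axis ratio
0.9755. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and problem size `n`)
per quantity.
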