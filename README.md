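# memquant

Quantitative fluorescence-microscopy analysis of membrane protein
organization and dynamics at the B-cell surface — the image-analysis
toolbox behind questions like *is CD20 clustered?*, *does it overlap
CD70?*, *how mobile is it?*, and *is CD70 recruited into the
immunological synapse between a B cell and a T cell?*

## What it computes

| Pipeline | Core quantity |
|---|---|
| `detect_clusters()` | cluster count, size (µm²), intensity from maxima-seeded watershed ∧ offset-Otsu threshold |
| `pearson_coefficient()`, `manders_coefficients()` | Pearson r; Manders M1/M2 with Costes bisection auto-threshold |
| `normalize_series()`, `fit_recovery()`, `batch_frap()` | FRAP double normalization; mobile fraction and T½ = τ·ln 2 from `I(t) = I₀ + A(1 − e^{−t/τ})` |
| `detect_particles()`, `link_detections()`, `msd_curve()`, `classify_motion()`, `mean_speed()` | spot detection in TIRF movies, trajectories, time-averaged MSD, confined/free/active labels from the MSD exponent α, speeds (µm/s) |
| `count_pla_spots()` | PLA dots per cell (threshold + watershed + size filter) |
| `fit_calibration_curve()`, `calibrate_molecules()`, `molecules_per_cluster()` | bead-calibrated molecules per cell and per cluster |
| `detect_synapses()`, `score_recruitment()`, `synapses_per_cell()`, `compare_groups()` | top-1%-CD3 contacts, in/out enrichment with the inclusive ≥150% recruitment rule, synapses per B cell, per-image rank tests |
| `stamp_enrichment()` | reporter enrichment on 5-µm micropatterned ligand stamps |
| `simulate_*()` | every input class as a synthetic scene with exact ground truth |

All containers are plain: scenes are `ImageScene` objects (named channel
matrices + pixel size), masks are `LabelMask` integer rasters, results
are data.frames. A minimal TIFF codec (64-bit-float scenes with JSON
metadata, 16-bit label masks) and a flat-TOML-configurable CLI
(`run_cli()`, subcommands `simulate | clusters | coloc | frap | spt |
pla | synapse | stamp | calibrate`) round out the I/O.

## Worked example

Simulate a B–T conjugate scene with a known 2× CD70 enrichment in the
contact, detect the synapses, and score recruitment:

```r
library(memquant)
sy  <- simulate_synapse_scene(3, enrichment_ratio = 2, seed = 5)
det <- detect_synapses(sy$scene)            # top 1% of CD3 over foreground
score_synapses(sy$scene, det, seed = 1)
#>   synapse_id in_mean out_mean enrichment_pct recruited scored
#> 1          1     200      100            200      TRUE   TRUE
#> 2          2     200      100            200      TRUE   TRUE
#> 3          3     200      100            200      TRUE   TRUE
synapses_per_cell(sy$scene, det)
#>   n_synapses n_b_cells n_t_cells synapses_per_b_cell synapses_per_t_cell
#> 1          3         3         3                   1                   1
```

`in_mean` is the CD70 mean inside the CD3-defined contact; `out_mean`
averages five congruent control regions rotated onto the non-synapse
membrane; `enrichment_pct = 100·in/out`, and `recruited` applies the
inclusive ≥150% rule — here every synapse reports exactly the simulated
200%.

A FRAP trace with true mobile fraction 0.6 and τ = 20 s (1% noise),
fitted after double normalization:

```r
sim <- simulate_frap_series(0.6, tau_s = 20, noise_sd = 0.01, seed = 1)
fit_recovery(normalize_series(sim$series))
#> FRAPFit: mobile fraction 0.601 | t1/2 13.98 s | tau 20.17 s | converged
```

The half-time lands on the closed form τ·ln 2 ≈ 13.86 s within the noise.

The same pipelines drive the CLI:

```sh
Rscript -e 'memquant::run_cli()' simulate --kind cluster --n-clusters 8 --seed 4 --out-dir out
Rscript -e 'memquant::run_cli()' clusters --in out/cluster_scene.tif --channel CD20 --threshold otsu20 --out-dir out
```

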