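# rgckit

Quantitative characterization of labeled retinal ganglion cell (RGC)
populations, for retinal neuroscientists working from whole-mount cell
maps, traced single-cell morphologies, cross-section image stacks, and
patch-clamp spike trains.

A genetically labeled RGC population raises four quantitative
questions, each answered by one module:

1. **Is the mosaic regular?** (`compute_nnd`, `regularity_index`,
   `density_recovery_profile`, `fit_drp_curve`) — A single RGC type
   tiles the retina as a regular mosaic with an exclusion zone; mixed
   populations look spatially random. The density recovery profile
   counts neighbors in annuli around each cell,
   ρ(r) = N(r+∂r)/A(r+∂r) in cells/mm²: flat at the global density for
   a random mosaic, depressed near r = 0 for a regular one. The
   regularity index is mean NND divided by its dispersion (SEM by
   convention here, with the classical SD variant exposed;
   RI_sem = RI_sd·√n).
2. **Where in the IPL do cells stratify?** (`detect_boundaries`,
   `coons_straighten`, `depth_profile`) — Curved cross-sections are
   flattened into a rectangular inner-plexiform-layer frame (0% depth
   at the GCL border, 100% at the INL border) with a bilinearly
   blended Coons patch over the two nuclear-stain boundaries, then
   reduced to normalized depth profiles.
3. **What morphological subtype is each filled cell?** (`read_swc`,
   `total_neurite_length`, `branch_points`,
   `stratification_distribution`, `classify_subtype`) — SWC
   morphometry plus a four-way stratification call: bistratified in
   S2+S4, monostratified in S4, S5, or S1.
4. **What does the cell do?** (`adaptation_index`, `fi_curve`,
   `classify_flash_response`, `spot_size_tuning`, `direction_tuning`)
   — Firing adaptation 1 − T_last/T_initial, ON/OFF/ON-OFF flash
   classification, spot-size tuning, and the vector-sum
   direction-selectivity index DSI = |Σ n_d e^{iθ_d}| / Σ n_d.

A synthetic-data module (`gen_*`) generates every input class with
known ground truth — random/hard-core/lattice mosaics, regular and
adapting spike trains, flash- and direction-tuned responses,
mono/bistratified arbors, curved sections with planted bands — so
every stage is testable by parameter recovery without any microscope.
See `vignettes/rgckit-methods.Rmd` for the models, conventions, and
their assumptions.

## Worked example

```r
library(rgckit)

# a regular mosaic: 100 cells/mm2 with a 50 um exclusion zone
mosaic <- gen_hardcore_pattern(density = 100, dmin = 50,
                               window = c(0, 0, 2000, 2000), seed = 1)
mosaic
#> point_pattern: 400 points [hardcore]
#>   window: [0, 2000] x [0, 2000] um (4.000 mm^2)

regularity_index(compute_nnd(mosaic), "sd")
#> regularity index (sd mode): 4.273  [mean NND 69.40 um, n = 400]

drp <- density_recovery_profile(mosaic, dr = 10, r_max = 200)
round(drp$density[1:8], 1)
#> [1]   0.0   0.0   0.0   0.0   0.0 127.7 124.3  92.0
```

The RI of ~4.3 is well above the ~1.9 expected of a random pattern,
and the DRP's first five annuli (radii wholly inside 50 µm) are
exactly empty — the exclusion-zone signature of a single-type mosaic.

```r
# direction tuning of a synthetic upward-preferring cell
trials <- gen_direction_trials(pref_dir = 90, kappa = 8, base_count = 50,
                               n_trials = 10, seed = 2)
direction_tuning(trials)
#> direction_tuning (vector_sum): DSI = 0.958, preferred 90 deg

# morphology: a cell stratifying at 30% and 70% IPL depth
cell <- gen_morphology(strat_depths = c(30, 70), seed = 3)
total_neurite_length(cell)     # 6080 um
branch_points(cell)            # 122
classify_subtype(stratification_distribution(cell))
#> subtype: bistratified_S2S4  (peaks at 31, 71% depth)

# firing adaptation: last ISI twice the first
train <- gen_spike_train(n_spikes = 10, first_isi = 0.05, isi_ratio = 2,
                         seed = 4)
adaptation_index(train, "literal")   # -1  (= 1 - 2, by construction)
```

The subtype call recovers the planted 30/70% bistratification (peaks
map to the ON stratum S4 and OFF stratum S2), and the adaptation index
equals 1 − ρ for a train built with ISI ratio ρ, here exactly −1.

## End-to-end demo and CLI

```r
run_pipeline(default_config(seed = 1, output_dir = "rgckit-out"))
# writes per-stage CSVs, summary.json, run.log
```

A command-line wrapper is installed at `exec/rgckit` inside the
package library (subcommands `simulate`, `drp`, `regularity`,
`straighten`, `stratify`, `morph`, `ephys`, `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/rgckit", package="rgckit"))')" \
  simulate --density 150 --size 1500 --seed 4 --out pts.csv
```

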