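# kinetotrack

Simulation and quantification of kinetochore motility on dynamic
microtubules.

In reconstituted budding-yeast lysate assays, kinetochore particles bind
the side of a microtubule, walk processively toward its plus end, convert
irreversibly to an end-on attachment at the tip, and then track the
depolymerizing plus end. The behavior is read out on kymographs
(distance × time images) and quantified by a run/pause slope rule.
`kinetotrack` packages the whole chain:

* a **continuous-time stochastic simulator** of the two-state
  (run/pause) lateral transport model with irreversible lateral→end-on
  conversion, tip-coupled depolymerization and microtubule dynamic
  instability, with per-genotype presets (`WT`, `kip3_null`,
  `kip3_dT_LZ`);
* a **kymograph renderer** (Gaussian PSF, Poisson noise, fluorophore
  blinking, 72.2 nm pixels, 5 s frames) and synthetic spindle line-scan
  profiles;
* the **quantification rules**: ridge-following track extraction,
  run/pause segmentation with the resolution threshold
  72.2 nm / 50 s = 86.64 nm/min (quoted as 86.7), state-resolved
  velocities, run lengths, time fractions, motile and reach-the-end
  fractions, mean ± SEM cohort summaries, 0.2-unit histograms;
* **categorical classifiers**: always/partially/never track
  colocalization against a blinking reference, and the bilobed versus
  declustered spindle line-scan phenotype;
* an **end-to-end pipeline** with Kruskal–Wallis group comparisons,
  deterministic seeding and machine-readable reports.

## The model in brief

A laterally bound kinetochore is motile with probability `p_motile`;
motile kinetochores alternate exponential runs (velocity `v_run`, µm/min
toward the plus end) and pauses. When the plus end comes within one
pixel (72.2 nm) of the kinetochore, attachment converts irreversibly to
end-on; the pair then alternates tip-tracking (`v_tip_track`, minus-end
directed) and tip pauses, and the microtubule never regrows. Free plus
ends follow standard dynamic instability (`v_growth`, catastrophe
frequency `f_cat`, rescue frequency `f_res`, shrinkage `v_depol_free`).
Measured preset values (velocities, motile fractions, the 0.537 add-back
rescue probability) are fixed; dwell means and microtubule dynamics are
calibrated model values documented in `inst/config/presets.yaml` and the
vignette.

## Worked example

```r
library(kinetotrack)

preset <- make_preset("WT")
ts  <- simulate_cohort(preset, n = 16, duration = 1800, frame_interval = 5,
                       seed = 42)
res <- analyze_trajectory_set(ts, imaging_config(), mode = "render",
                              seed = 7)
res$cohort
```

```
<cohort_summary> n = 16 tracks
  run velocity  0.484 +/- 0.020 um/min  (runs-only, per track)
  tip velocity  0.381 +/- 0.003 um/min
  run length    0.717 +/- 0.067 um  (70 runs pooled)
  lateral time moving  34.3%   tip time moving  38.8%
  moved at all  87.5%   reached plus end  43.8%
```

Sixteen synthetic wild-type kinetochores were imaged onto noisy, blinking
kymographs, re-extracted, and segmented with the 10-frame / 86.64 nm/min
rule. Laterally bound kinetochores ran at ~0.48 µm/min in ~0.72 µm runs
and spent ~34% of their side-bound time moving; ~88% moved at all and
~44% reached the plus end, where tip tracking proceeded at ~0.38 µm/min
for ~39% of the tip-bound time. At this small n the fraction-type
statistics carry ±10 percentage points of sampling noise; the packaged
presets are calibrated so that full 128-track cohorts center on the
published values (0.56 µm/min, 0.73 µm, 30%, 77%, 28.1%, 0.4 µm/min,
40%).

A command-line wrapper over the same functions lives at
`inst/cli/kinetotrack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/kinetotrack.R", package="kinetotrack"))')" \
    simulate --preset WT --n 16 --seed 1 --out traj.csv
```

## Package layout

```
R/                  simulator, renderer, extraction/segmentation,
                    summaries, classifiers, statistics, pipeline
inst/config/        packaged genotype presets (YAML)
inst/cli/           command-line wrapper
scripts/            acceptance script
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette (model, calibration, design choices)
```
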