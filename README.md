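# beadflow

Quantify cilia-driven ependymal flow from fluorescence time-lapse videos of
microbeads, and ciliary beat frequency (CBF) from confocal linescan traces.

Motile cilia on the ependymal cells lining the brain ventricles propel
cerebrospinal fluid along the ventricular wall. A standard ex vivo assay
releases 1-µm fluorescent latex beads over a dissected lateral-ventricle
whole-mount, films them at ~20 frames/s, and reads the average bead speed as
an indicator of the ependymal flow rate; speed distributions are compared
between groups (e.g. genotypes) with the Mann–Whitney rank-sum test. CBF is
measured separately from linescans acquired at ~529 lines/s.

`beadflow` is the computational side of that assay:

* **Detection** — multi-scale Laplacian-of-Gaussian filtering with kernels

  `h(i,j) = (i² + j² − 2σ²) g(i,j) / (σ⁴ Σₘ Σₙ g(m,n))`,
  `g(i,j) = exp(−(i²+j²)/2σ²)`, `σ = r/√2`,

  on support `i,j ∈ [−⌈2σ⌉, ⌈2σ⌉]` for radii r = 3–5 px; local response
  minima above a sensitivity threshold, non-minima suppression of
  overlapping candidates, Gaussian-heatmap merging of near-duplicates, and
  removal of beads stationary for too many frames via complete-linkage
  clustering under the Chebyshev metric.
* **Tracking** — a constant-velocity Kalman filter over (x, y, vx, vy) with
  inflated motion error (predictions are less trusted than LoG detections),
  gated global minimum-cost association, and pruning of tracks visible for
  too few frames.
* **Flow statistics** — per-track speeds in µm/s, cohort mean and direction,
  and a Mann–Whitney rank-sum comparison (exact by enumeration for small
  groups, tie-corrected normal approximation otherwise).
* **CBF** — kymograph extraction and a Welch-periodogram beat-frequency
  estimator with parabolic peak refinement and a peak-counting cross-check.
* **Simulation** — synthetic bead videos and linescans with known ground
  truth, so every stage is testable without microscope data.

## Worked example

```r
library(beadflow)

## a synthetic recording: 10 beads carried at 3 px/frame (= 30 um/s at
## 0.5 um/px and 20 frames/s), Brownian jitter, 3 stationary decoys
cfg <- scene_config(n_beads = 10, seed = 11)
sim <- generate_bead_video(cfg)

det <- detect_sequence(sim$sequence)
trk <- track_sequence(det, n_frames = 100)
trk
#> bead_tracks: 10 reported tracks

fs <- summarize_flow(trk, pixel_size = 0.5, frame_interval = 0.05)
fs
#> flow_summary: 10 tracks, mean speed 30.577 um/s
#>   direction (0.999, -0.002), |direction| = 0.999
```

The ten flowing beads are recovered as ten tracks (the stationary decoys are
removed by the refinement stage), the mean speed lands within 2% of the
programmed 30 µm/s, and the direction vector has near-unit norm, i.e. the
flow is coherent along +x.

Comparing two speed cohorts, e.g. wild type versus a slowed mutant:

```r
rank_sum_test(fs$per_track_speed, 0.8 * fs$per_track_speed)
#> Mann-Whitney rank-sum: U = 0 (n1 = 10, n2 = 10), p = 1.083e-05 [exact enumeration]
```

Beat frequency from a noisy synthetic linescan at the reference acquisition
geometry (529 Hz, 5000 samples):

```r
estimate_cbf(generate_linescan(24, sampling_rate = 529, n = 5000,
                               snr = 2, seed = 1))
#> CBF estimate: 23.997 Hz (peak power fraction 0.646)
```

Real recordings enter through `read_sequence()` (multi-page TIFF or a frame
directory) and `run_pipeline()`, which writes detections/tracks CSVs and a
flow-summary JSON stamped with the configuration hash. A command-line
wrapper with verbs `simulate`, `detect`, `track`, `stats`, `cbf`, `run`
lives at `inst/cli/beadflow.R`:

```sh
Rscript inst/cli/beadflow.R run --in scene.tif --out-dir results \
        --pixel-size 0.5 --frame-interval 0.05
```

## The methods vignette

`vignettes/bead-flow-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, the numerical
choices (threshold anchoring, tie-breaking, border handling, degenerate
inputs), what the simulator does and does not emulate, and known
limitations.
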