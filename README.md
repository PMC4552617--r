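# memloc

Membrane localization analysis for single-molecule fluorescence imaging of
rod-shaped bacteria.

## The problem

Low-copy bacterial proteins — DNA-repair polymerases in particular — can be
sequestered at the inner membrane and released into the cytosol on demand.
Deciding *where* a tagged protein sits from widefield single-molecule movies
is hard: cells are ~0.6–0.8 µm wide (barely above the diffraction limit),
copy numbers are in the single digits to tens, and the label photobleaches
within seconds. `memloc` implements, as tested reusable R functions, the
image-analysis toolchain for exactly this regime, together with a
synthetic-movie generator that provides ground truth for every estimator:

* **Simulation** — spherocylindrical cells with membrane-diffusing,
  cytosol-diffusing and DNA-bound static emitters; single-exponential
  photobleaching (τ = 5 s) with reversible dark states; depth-dependent
  PSF (optical sectioning), motion blur, EMCCD noise (Poisson–Gamma–read),
  uneven illumination; fast "time-sampling" movies (296 × 34 ms frames),
  5-min time-lapse series driven by a three-phase expression program, and
  two-channel static-focus scenes.
* **Short-axis correlation statistic** — the image is duplicated, shifted
  sideways by a distance lag and correlated against itself (or against a
  second channel). Rows are averaged in 20 µm bins, lags run to 1 µm.
  Membrane-associated signal in vertically aligned cells produces symmetric
  secondary peaks at a lag equal to the cell width; cytosolic signal gives
  a single broad origin peak. Time courses are normalized so the maximal
  zero-lag value is 1 and the central-peak amplitude tracks relative
  protein concentration.
* **Foci** — discoidal peak filtering, local-maxima detection, sub-pixel
  elliptical 2D Gaussian fitting (Levenberg–Marquardt), super-resolution
  rendering as unit-volume Gaussians of width σx, σy (the localization
  uncertainties), greedy nearest-neighbor tracking, static-focus selection
  (persistence > 300 ms), and normalized-cell location maps.
* **Counting** — per-cell bleaching trajectories, autofluorescence and
  background reference correction, single-exponential amplitude fits
  A·exp(−t/τ) + c, single-molecule calibration from late-movie dark-state
  returns or from change-point photobleaching step sizes, spherocylinder
  volumes from masks, and nM concentrations via
  c [nM] = N / (0.6022 · V [fL]).
* **Colocalization** — mutual-nearest-neighbor pairing under a 100 nm cap
  with a Monte-Carlo chance baseline over random focus placements.
* **Post-synchronization** — burst classification, alignment of
  single-burst cells to their intensity peak, three-phase segmentation and
  per-phase correlation analysis.

## Worked example

Simulate a field of membrane-labeled cells, run the correlation statistic,
and read off the membrane signature:

```r
library(memloc)
set.seed(7)

mem <- autocorrScene("membrane", nCells = 54, cellWidth = 0.6)
cyt <- autocorrScene("cytosolic", nCells = 54)

mem$peaks
#> [1] 0.5273746
round(c(membrane = mem$score, cytosolic = cyt$score), 2)
#>  membrane cytosolic
#>      0.43      0.19
```

The membrane population shows a symmetric secondary correlation peak at
0.53 µm — within one camera pixel of the simulated 0.6 µm cell width (the
small inward shift is an intrinsic property of image correlation on 3D
cells; see the methods vignette) — while the cytosolic population shows
no secondary peak and a much lower membrane score.

Counting molecules from bleaching movies:

```r
set.seed(31)
cs <- memloc:::countingScene(nCells = 10, emittersPerCell = 16)
cs$calibration
#> SMCalibration (returns): 5543 counts/molecule from 530 observations
round(mean(cs$perCell$n_molecules), 1)   # true value: 16
#> [1] 14.2
```

Each cell carried 16 molecules; the pipeline recovers the count from the
bleach-fit amplitude divided by the single-molecule unit intensity measured
in the final 50 frames of the same movie.

End-to-end scenarios (simulate → analyze → CSV/JSON reports) run via

```r
runScenario("membrane-vs-cytosolic", outdir = "out", seed = 1)
```

with scenarios `membrane-vs-cytosolic`, `two-channel-membrane`,
`induction-timelapse`, `static-coloc`, `counting-calibration`,
`illumination-recovery`.

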