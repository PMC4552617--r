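---
title: "Models and methods: simulating and quantifying membrane localization in single-molecule movies of rod-shaped bacteria"
author: "memloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memloc)
```

# The scientific problem

Low-copy DNA-repair proteins in bacteria can be held at the inner membrane
and released into the cytosol when needed. Deciding whether a fluorescently
tagged protein is membrane-associated or cytosolic from widefield
single-molecule movies is hard: cells are sub-micrometer wide, copy numbers
are in the single digits to tens, and photobleaching destroys the signal
within seconds. `memloc` implements a complete, testable pipeline for this
regime:

* a synthetic-movie generator for spherocylindrical cells with
  membrane-diffusing, cytosol-diffusing and DNA-bound static emitters;
* image conditioning (flat-fielding, discoidal peak filtering);
* an image-wide **short-axis autocorrelation / cross-correlation
  statistic** whose off-origin peaks at a lag equal to the cell width
  report membrane association;
* focus detection, sub-pixel Gaussian fitting, super-resolution rendering,
  persistence tracking and normalized-cell location maps;
* **bleach-decay molecule counting** with two single-molecule
  calibrations (late-movie dark-state returns; change-point photobleaching
  step sizes) and conversion to nM concentrations;
* distance-based two-channel **colocalization** with a Monte-Carlo chance
  baseline;
* single-cell burst **post-synchronization** and three-phase segmentation
  of induction time courses.

Because no deposited experimental data exist for this regime, the
simulator is a first-class component: every analysis claim in the test
suite is validated against simulations with known ground truth.

# The cell and emitter model

A cell is a spherocylinder (`CellGeometry`): a cylinder of diameter $w$
capped by two hemispheres, pole-to-pole length $L$, at an orientation
close to the image vertical (flow-aligned cells). Emitters
(`seedEmitters`) come in three modes:

* **membrane** — uniform on the spherocylinder surface, diffusing along it
  (default $D = 0.02\,\mu m^2/s$: sharp within one 34 ms frame, mobile
  over seconds). Diffusion is implemented as a free 3D Gaussian step
  followed by radial re-projection onto the surface, adequate at these
  step sizes.
* **cytosolic** — uniform in the volume, fast ($D = 5\,\mu m^2/s$), with
  specular reflection at the wall; a cytosolic molecule traverses the cell
  within one frame and appears as a blur.
* **static** — uniform in the volume and immobile (DNA-bound).

Photophysics (`Photophysics`) is a three-state model: bright molecules
photobleach with mean bright lifetime `bleachTau` (default 5 s, the
measured constant of the red fluorescent protein this pipeline is built
around) or shelve into a reversible dark state; dark molecules return at
`returnRate`. Bleaching is absorbing and occurs from the bright state
only, so with blinking disabled the expected bright survival is exactly
$e^{-t/\tau}$ — a property the test suite checks against the closed form.
Late-movie dark-state returns are the basis of one of the two
single-molecule intensity calibrations.

# The imaging model

`renderFrame` draws each bright emitter as a 2D Gaussian integrated
exactly over the pixel grid (so rendered mass equals the expected photon
count), with expected photons `photonRate * frameInterval` scaled by the
local illumination. Three optical terms matter:

* **Diffraction.** The in-focus PSF width defaults to
  $\sigma = 0.10\,\mu m$, the diffraction-limited width of red emission
  through a high-NA (~1.5) single-molecule objective
  ($\sigma \approx 0.21 \lambda / NA$). In the two-channel scenes the
  yellow channel is rendered proportionally sharper.
* **Defocus.** The focal plane lies at the cell midplane. An emitter at
  out-of-plane distance $z$ renders with
  $\sigma(z) = \sigma_0 \sqrt{1 + (z/z_R)^2}$ (Gaussian-beam model,
  `depthOfField` $z_R = 0.10\,\mu m$) at conserved total mass, so
  molecules on the near/far cell surface are dim and blurred while
  molecules at the in-plane periphery stay sharp. This optical sectioning
  is essential, not cosmetic: the projected transverse density of a
  uniformly labeled membrane is an arcsine distribution whose
  pair-correlation is *monotone* — without defocus the membrane
  cross-peak at the cell width does not exist in the image statistic at
  red-light diffraction scales.
* **Motion blur.** Mobile emitters render with an extra width
  $D \cdot \Delta t / 3$ per axis, which fully blurs cytosolic molecules
  within one frame.

The camera model is the standard EMCCD approximation: Poisson photons,
Gamma(shape = photons, scale = `emGain`) electron multiplication, Gaussian
read noise, constant offset, clamping at zero and digitization. Uniform
coverslip background and cellular autofluorescence (inside cell
footprints) are added before the noise stages, both scaled by the
illumination field. The default illumination is a Gaussian vignette whose
corners receive 70% of the center intensity.

# The localization statistic

`rowAutocorrelation` averages the peak-filtered image rows within vertical
bins (default 20 µm), correlates each bin's horizontal profile against
itself at integer-pixel lags up to 1 µm, and averages the per-bin
functions. Vertically aligned membrane-labeled cells contribute two sharp
edge lines separated by the cell width, which appear as symmetric
secondary correlation peaks at that separation; cytosolic cells produce a
single broad origin peak. `crossCorrelation` applies the same machinery
across two channels, and `normalizeTimecourse` scales a series of
functions by the per-time mean cellular intensity so that the maximal
zero-lag value over the course is 1, making the central-peak amplitude a
readout of relative protein concentration over time.

Numerical choices that required a decision:

* **DC removal.** The discoidal filter clips negative values, which leaves
  a small positive DC level in the profiles; raw lag products would turn
  that level into a flat pedestal over all lags that buries the membrane
  peak. Each bin profile's *median* is therefore subtracted before the
  products — robust against the compact cell structure in narrow
  single-cell crops, while removing the noise pedestal in image-wide
  fields.
* **Overlap scaling.** Lag products are divided by the overlap length
  (unbiased scaling), so the finite image width does not taper the
  function toward large lags.
* **Peak readout.** `secondaryPeaks` finds off-origin local maxima
  (exclusion zone 0.25 µm, minimum height 2% of the zero-lag value) and
  refines positions by a 3-point parabola. The parabola inherits a ~1 px
  inward bias from the origin-peak flank under the side lobe, so an
  optional whole-function decomposition (generalized-Gaussian origin peak
  + symmetric Gaussian side pair + constant) is provided and used by the
  validation scenarios.
* **Expected peak position.** Even with optical sectioning, the weighted
  membrane-line separation of a 3D cell is slightly below the nominal
  width (the in-focus selection samples the ring at $|z| > 0$, and the
  one-sided arcsine tail shifts the blurred line modes inward).
  At default parameters the measured side peak sits about 0.05–0.08 µm
  inside the cell width (e.g. ~0.52 µm for 0.6 µm cells, ~0.72 µm for
  0.8 µm cells) — within one camera pixel of the nominal value, and an
  intrinsic property of image-based correlation on 3D cells rather than
  an implementation artifact.
* **Scene density.** The image-wide statistic needs sparse signal per
  vertical bin: cross-cell correlation terms grow with the square of the
  number of cells per bin while the within-cell membrane structure grows
  linearly. The validation scenes therefore use ~9 cells per
  16 µm field with randomized horizontal positions; regular grids are the
  worst case (aligned columns pile cross-cell mass near the within-cell
  lags).

`membraneScore` condenses a function into the ratio of correlation mass at
the expected width (± 0.1 µm) to the zero-lag value, clipped to [0, 1];
on simulated populations of 25 cells per class the per-cell scores of
membrane and cytosolic cells separate with zero overlap at defaults.

# Foci: detection, fitting, rendering, persistence

Detection runs on discoidal-filtered images (`discoidalFilter`, default
radii 1 and 3 px — tight enough that defocused out-of-plane blobs are
rejected; each pixel becomes the disk mean minus the annulus mean,
negatives clipped). The default threshold is mean + 6 SD of the filtered
image. Candidates are local maxima with a 3 px minimum separation.

`fitGaussianFocus` fits an elliptical 2D Gaussian plus constant background
to a 9×9 window of the *raw* image by Levenberg–Marquardt. Fits are
discarded when the center leaves the window, widths leave
$[0.5, 3] \cdot \sigma_{PSF}$, or the amplitude is not significant
(A < 2 SE(A)) — the latter removes candidates on flat background. Under
EMCCD noise the pixel variance grows with the signal (excess-noise
factor 2), so the covariance of an *unweighted* fit understates the center
uncertainty about two-fold; passing the camera gain and read noise
switches the fit to inverse-variance weights, after which the reported
uncertainties match the realized localization error to ~30% on repeated
simulations. The center standard errors $\sigma_x, \sigma_y$ from the fit
covariance are used by `renderSuperres`, which draws each focus as the unit-volume
Gaussian $f(x,y) = \frac{1}{2\pi\sigma_x\sigma_y}
e^{-(x^2/2\sigma_x^2 + y^2/2\sigma_y^2)}$: constant volume per molecule,
sharper where localization is better. The discrete rendered sum equals
the number of foci at any pixel size (erf-based pixel integration).

`linkTracks` links foci greedily by nearest neighbor within 2 px per
frame, bridging up to one missed frame; `staticFoci` flags tracks
persisting strictly longer than 300 ms (at 34 ms frames: at least 9
frames) as static, i.e. DNA-bound. The tracking parameters are
package decisions — at the default membrane diffusivity a membrane
molecule rarely jumps beyond 2 px per frame, so duration alone cannot
separate static from membrane-diffusing molecules; the mixed-simulation
test therefore contrasts static against cytosolic emitters, which is also
the contrast that matters in average projections.

`cellCoordinates` maps focus positions to normalized cell coordinates
($l$ along the long axis, $s$ across the short axis, both in
$[-\frac12, \frac12]$), and `locationMap` renders all foci from all cells
on one standard cell as unit-volume spots divided by the number of cells.

# Molecule counting and calibration

`cellTrajectory` measures the mean fluorescence per pixel within a cell
mask per frame; `fitDecay` fits $A e^{-t/\tau} + c$ by unweighted
least squares (offset free, absorbing residual background). The amplitude
$A$ — not any single frame — measures the initial label fluorescence,
pooling all 296 frames. Contributions from coverslip background
(cell-free regions, per field) and cellular autofluorescence (a separate
field of unlabeled cells) are fitted the same way and subtracted first
(`correctTrajectory`). A flagged fit (flat trace, unidentifiable decay)
degenerates to $A = 0$, $c = \bar{v}$ so it still works as a reference.

The count is $A \cdot \mathrm{area} / \mathrm{unit}$, where the
single-molecule unit intensity comes from either calibration:

* **returns** (`smIntensityFromReturns`): foci in the final 50 frames,
  where most fluorescence has bleached and isolated molecules reappear
  from dark states; the unit is the mean fitted integrated Gaussian
  volume. Only foci at least 8 px from any other candidate are used, so
  overlapping molecules do not bias the mean.
* **steps** (`smIntensityFromSteps`): photobleaching traces of static
  foci, segmented by $\ell_2$-cost binary segmentation with a BIC-style
  penalty ($6 \hat\sigma^2 \log n$, noise from the MAD of first
  differences — the factor was calibrated once on noiseless and noisy
  staircase fixtures so a monotone ramp is not over-segmented); the unit
  is the mode of the downward step-size distribution.

Counting conventions: photometry uses the cell mask dilated by 3 px so the
PSF spill of peripheral molecules is captured (without it counts are
biased ~15% low); geometry (length, width, volume) uses the plain mask.
`cellVolume` takes the length from the principal-axis extent and solves
the width from the footprint-area identity
$\mathrm{area} = w(L - w) + \pi w^2/4$, which is more robust to
pixelation than the transverse extent; the volume is the spherocylinder
formula, and `concentrationNM` applies the Avogadro identity
$c\,[\mathrm{nM}] = N / (0.6022 \cdot V\,[\mathrm{fL}])$.

The calibration scenes use bright cells (~100 copies) for the
bleach-constant fit — per-cell decay fits on 16-copy cells are dominated
by binomial survival noise — and 16-copy cells for count recovery, where
the acceptance check is on the 50-cell mean.

# Colocalization

`matchFoci` pairs foci across channels by iterated mutual nearest
neighbors under a 100 nm cap (no focus counted twice); the colocalized
fraction is paired B over total B. `chanceBaseline` scatters the B foci
uniformly inside each cell footprint and re-matches against the fixed A
foci (default 1000 draws); for well-separated A foci it converges to the
capture-area ratio $n_A \pi r^2 / \mathrm{footprint}$, but the
Monte-Carlo estimate also handles overlapping capture disks and boundary
effects. With two foci per average cell and the 100 nm criterion the
baseline is ~2%, comfortably below the 10% bound used when judging
observed fractions. Per-cell statistics (`perCellStats`) report SEM over
cells, never over foci.

# Post-synchronization

`classifyBursts` calls a single-cell trajectory "none" when its maximum
stays below a noise floor (median + 3 robust SDs of the earliest fifth of
the trace), "single" when exactly one contiguous epoch exceeds half the
maximum, else "multiple" — the operational definition of a "well-defined
burst", configurable because no sharper rule exists. Only single-burst
cells are aligned (`alignToPeak`) by shifting each peak to time zero;
alignment is idempotent, and on jittered synthetic bursts it narrows the
mean peak by at least the onset jitter. `phaseSegments` splits the mean
trajectory at the 20%-of-maximum rise crossing and the peak into the
basal, production and decline phases; `phaseCorrelation` then averages
per-frame autocorrelation *shapes* (each normalized to unit zero-lag —
raw functions scale with intensity squared and would be dominated by the
brightest frames) within each phase, which on the simulated
membrane-then-release program shows membrane side peaks during production
and a broadened origin peak after release.

# The expression program

`simulateTimelapse` drives molecule counts deterministically: zero before
`tOnset`, linear accumulation at `productionRate` to `tPeak`, exponential
decline at `decayRate` after; molecules are produced in `initialMode` and
all switch to `releasedMode` at `tRelease` (membrane release). Because
time-lapse frames are minutes apart, mobile emitter positions decorrelate
completely between frames and are re-drawn each frame rather than
integrated. The canonical induction scene uses onset 60 min, 1.2
molecules/min to a peak of 60 copies at 110 min, release at the peak and
4%/min decline — a strong induction of a damage-response gene in a
filamenting cell (4.5 µm; stressed rod cells elongate, which also reduces
the polar-cap fraction of membrane signal).

# What the simulations do and do not show

The generator reproduces the geometry, photophysics, optics and noise
that the analysis must cope with, under known ground truth; passing tests
show the estimators are correct and approximately unbiased *under this
model*. Real data add complications the model omits deliberately: no
optical aberrations or PSF rings, no z-stacks, no photoswitching
chemistry, no cell growth or division during movies, no segmentation
errors (masks are exact), and autofluorescence that does not itself
bleach. Absolute experimental numbers (nM concentrations, copies per
cell in vivo) therefore cannot be reproduced here — the pipeline
validates methods, not biology.

# Problem sizes

The shipped validation scenes are sized for a desktop run: 54 cells per
correlation scene (6 fields of 9), 20 bright cells plus 8 unlabeled
reference cells for the bleach constant, 20 movies for the illumination
profile, 50 cells for count recovery, 30–40 cells for colocalization.
Each completes in seconds to about a minute on one core.
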