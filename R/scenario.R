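# End-to-end scenario orchestration: simulate -> analyze -> report.

memlocScenarios <- c("membrane-vs-cytosolic", "two-channel-membrane",
                     "induction-timelapse", "static-coloc",
                     "counting-calibration", "illumination-recovery")

# Acquisition built from a run config.
configAcquisition <- function(cfg, dim = c(160L, 160L),
                              nFrames = cfg$n_frames,
                              illumination = matrix(numeric(0), 0, 0)) {
  Acquisition(dim = dim, pixelSize = cfg$pixel_size_um,
              psfSigma = cfg$psf_sigma_um,
              depthOfField = cfg$depth_of_field_um,
              frameInterval = cfg$frame_interval_s,
              nFrames = as.integer(nFrames), emGain = cfg$em_gain,
              readNoise = cfg$read_noise, offset = cfg$camera_offset,
              backgroundRate = cfg$background_rate,
              autofluorRate = cfg$autofluor_rate,
              illumination = illumination)
}

#' Simulate membrane/cytosolic fields and their autocorrelation
#'
#' Simulates a field of vertically oriented cells per labeling mode,
#' peak-filters the frames and returns the averaged short-axis
#' autocorrelation function plus its secondary-peak positions.
#'
#' @param mode "membrane" or "cytosolic".
#' @param nCells number of cells (default 54).
#' @param cellWidth cell width (um, default from config).
#' @param emittersPerCell emitters seeded per cell (default 40).
#' @param nFrames frames rendered and averaged per field (default 6).
#' @param cfg run config list (\code{\link{defaultRunConfig}}).
#' @return list with \code{cf} (\code{\link{CorrelationFunction}}),
#'   \code{peaks} (secondary |lag| positions, um), \code{score}
#'   (\code{\link{membraneScore}} at the simulated width), \code{nCells}.
#' @export
autocorrScene <- function(mode = c("membrane", "cytosolic"), nCells = 54,
                          cellWidth = NULL, emittersPerCell = 40,
                          nFrames = 6, cfg = defaultRunConfig()) {
  mode <- match.arg(mode)
  if (is.null(cellWidth)) cellWidth <- cfg$cell_width_um
  # few cells per field: the image-wide statistic needs sparse signal per
  # vertical bin, or cross-cell correlation terms swamp the within-cell
  # membrane structure
  perField <- 9L
  nFields <- ceiling(nCells / perField)
  acq <- configAcquisition(cfg, dim = c(160L, 160L), nFrames = nFrames)
  photo <- Photophysics(bleachTau = Inf, photonRate = cfg$photon_rate)
  acc <- NULL
  done <- 0L
  for (f in seq_len(nFields)) {
    nf <- min(perField, nCells - done); done <- done + nf
    cells <- layoutCells(nf, acq, length = cfg$cell_length_um,
                         width = cellWidth)
    emitters <- lapply(cells, seedEmitters, mode = mode,
                       n = emittersPerCell)
    sim <- simulateTimesampling(cells, emitters, photo, acq)
    filt <- discoidalFilter(sim$stack, cfg$discoidal_r_inner,
                            cfg$discoidal_r_outer)
    cf <- suppressWarnings(rowAutocorrelation(
      filt, maxLag = cfg$max_lag_um, binHeight = cfg$bin_height_um))
    acc <- if (is.null(acc)) values(cf) else acc + values(cf)
    lagAxis <- lags(cf)
  }
  cf <- CorrelationFunction(lagAxis, acc / nFields, type = "auto")
  list(cf = cf,
       peaks = secondaryPeaks(cf, exclusion = cfg$peak_exclusion_um,
                              refine = "decompose"),
       score = membraneScore(cf, cellWidth), nCells = nCells)
}

#' Two-channel membrane simulation and cross-correlation
#'
#' Both channels carry membrane-mode emitters on the same cells; returns
#' the averaged unnormalized cross-correlation and its off-origin peaks.
#'
#' @param nCells number of cells (default 54).
#' @param cellWidth cell width (um, default 0.8 for a wider strain).
#' @param emittersPerCell per channel per cell (default 40).
#' @param nFrames frames per field (default 6).
#' @param cfg run config list.
#' @return list with \code{cf}, \code{peaks}, \code{nCells}.
#' @export
crossCorrScene <- function(nCells = 54, cellWidth = 0.8,
                           emittersPerCell = 40, nFrames = 6,
                           cfg = defaultRunConfig()) {
  perField <- 9L
  nFields <- ceiling(nCells / perField)
  # two-channel imaging: the green/yellow channel has a slightly narrower
  # diffraction width than the red channel (PSF scales with wavelength)
  acqA <- configAcquisition(cfg, dim = c(160L, 160L), nFrames = nFrames)
  acqA@psfSigma <- cfg$psf_sigma_um * 527 / 633
  acqB <- configAcquisition(cfg, dim = c(160L, 160L), nFrames = nFrames)
  acq <- acqA
  photo <- Photophysics(bleachTau = Inf, photonRate = cfg$photon_rate)
  acc <- NULL; done <- 0L
  for (f in seq_len(nFields)) {
    nf <- min(perField, nCells - done); done <- done + nf
    cells <- layoutCells(nf, acq, length = cfg$cell_length_um,
                         width = cellWidth)
    emA <- lapply(cells, seedEmitters, mode = "membrane",
                  n = emittersPerCell)
    emB <- lapply(cells, seedEmitters, mode = "membrane",
                  n = emittersPerCell)
    simA <- simulateTimesampling(cells, emA, photo, acqA)
    simB <- simulateTimesampling(cells, emB, photo, acqB)
    fA <- discoidalFilter(simA$stack, cfg$discoidal_r_inner,
                          cfg$discoidal_r_outer)
    fB <- discoidalFilter(simB$stack, cfg$discoidal_r_inner,
                          cfg$discoidal_r_outer)
    cf <- suppressWarnings(crossCorrelation(
      fA, fB, maxLag = cfg$max_lag_um, binHeight = cfg$bin_height_um))
    acc <- if (is.null(acc)) values(cf) else acc + values(cf)
    lagAxis <- lags(cf)
  }
  cf <- CorrelationFunction(lagAxis, acc / nFields, type = "cross")
  list(cf = cf,
       peaks = secondaryPeaks(cf, exclusion = cfg$peak_exclusion_um,
                              refine = "decompose"),
       nCells = nCells)
}

#' Bleach-constant recovery scene
#'
#' Simulates labeled cells plus unlabeled reference cells in one field for
#' \code{cfg$n_frames} frames, extracts per-cell trajectories, corrects
#' them by the fitted background (cell-free region) and autofluorescence
#' (unlabeled cells) references, fits single-exponential decays, and
#' returns the per-cell fits.
#'
#' @param nCells labeled cells (default 20).
#' @param nReference unlabeled autofluorescence-reference cells
#'   (default 6).
#' @param emittersPerCell label copies per cell (default 100; a brightly
#'   labeled calibration regime so the per-cell decay fit is not dominated
#'   by small-number survival fluctuations).
#' @param mode emitter mode (default "membrane").
#' @param cfg run config list.
#' @return list with \code{fits} (list of \code{\link{ExpDecayFit}} per
#'   labeled cell), \code{taus}, \code{amplitudes}, \code{cells},
#'   \code{masks}, \code{sim}.
#' @export
bleachScene <- function(nCells = 20, nReference = 8, emittersPerCell = 100,
                        mode = "membrane", cfg = defaultRunConfig()) {
  acq <- configAcquisition(cfg, dim = c(200L, 200L))
  photo <- Photophysics(bleachTau = cfg$bleach_tau_s,
                        photonRate = cfg$photon_rate)
  # labeled field; wide spacing keeps PSF spill out of neighboring masks
  cells <- layoutCells(nCells, acq, length = cfg$cell_length_um,
                       width = cfg$cell_width_um, minSep = 2.5)
  emitters <- lapply(cells, seedEmitters, mode = mode, n = emittersPerCell)
  sim <- simulateTimesampling(cells, emitters, photo, acq)
  masks <- lapply(cells, makeMask, acq = acq)
  # background: pixels well away from any cell (dilated union mask)
  far <- !dilateMask(makeMask(cells, acq), 10L)
  bgFit <- fitDecay(cellTrajectory(sim$stack, far))
  # autofluorescence: a separate field of unlabeled cells, as measured on
  # an unlabeled strain; corrected by its own cell-free background
  afFit <- NULL
  if (nReference > 0) {
    refCells <- layoutCells(nReference, acq,
                            length = cfg$cell_length_um,
                            width = cfg$cell_width_um, minSep = 2.5)
    refSim <- simulateTimesampling(
      refCells, lapply(refCells, seedEmitters, mode = mode, n = 0L),
      photo, acq)
    refMasks <- lapply(refCells, makeMask, acq = acq)
    refFar <- !dilateMask(makeMask(refCells, acq), 10L)
    refBg <- fitDecay(cellTrajectory(refSim$stack, refFar))
    afVals <- rowMeans(vapply(refMasks, function(m)
      cellTrajectory(refSim$stack, m)$value, numeric(acq@nFrames)))
    tms <- (seq_len(acq@nFrames) - 1) * acq@frameInterval
    afFit <- fitDecay(data.frame(
      time = tms, value = afVals - evalDecay(refBg, tms)))
  }
  fits <- lapply(seq_len(nCells), function(k) {
    traj <- cellTrajectory(sim$stack, masks[[k]])
    fitDecay(correctTrajectory(traj, afFit, bgFit))
  })
  ok <- !vapply(fits, isFlagged, logical(1))
  list(fits = fits,
       taus = vapply(fits, decayTau, numeric(1))[ok],
       amplitudes = vapply(fits, amplitude, numeric(1))[ok],
       cells = cells, masks = masks, sim = sim,
       backgroundFit = bgFit, autofluorFit = afFit)
}

#' Illumination-recovery scene
#'
#' Renders movies of sparse cells under the Gaussian vignette and runs the
#' beam-estimation procedure, returning the recovered profile and its
#' corner-to-center ratio.
#'
#' @param nMovies number of movies (default 20).
#' @param framesPerMovie frames per movie (default 8).
#' @param cellsPerMovie cells per field (default 6).
#' @param cornerRatio generating corner/center ratio (default from config).
#' @param cfg run config list.
#' @return list with \code{profile}, \code{cornerRatio} (recovered, mean of
#'   the four corner pixels), \code{nMovies}.
#' @export
illuminationScene <- function(nMovies = 20, framesPerMovie = 8,
                              cellsPerMovie = 6, cornerRatio = NULL,
                              cfg = defaultRunConfig()) {
  if (is.null(cornerRatio)) cornerRatio <- cfg$illumination_corner_ratio
  dim <- c(128L, 128L)
  ill <- gaussianVignette(dim, cornerRatio)
  acq <- configAcquisition(cfg, dim = dim, nFrames = framesPerMovie,
                           illumination = ill)
  photo <- Photophysics(bleachTau = cfg$bleach_tau_s,
                        photonRate = cfg$photon_rate)
  fw <- dim[2] * cfg$pixel_size_um; fh <- dim[1] * cfg$pixel_size_um
  movies <- lapply(seq_len(nMovies), function(i) {
    # fields of unlabeled cells at random positions: the beam estimate is
    # dominated by coverslip background and cellular autofluorescence, as
    # in practice where most label has bleached
    cells <- lapply(seq_len(cellsPerMovie), function(j)
      CellGeometry(center = c(stats::runif(1, 1, fw - 1),
                              stats::runif(1, 2, fh - 2)),
                   orientation = stats::rnorm(1, 0, 5 * pi / 180),
                   length = cfg$cell_length_um, width = cfg$cell_width_um))
    emitters <- lapply(cells, seedEmitters, mode = "cytosolic", n = 0L)
    simulateTimesampling(cells, emitters, photo, acq)$stack
  })
  prof <- estimateIllumination(movies, blurRadius = cfg$blur_radius_px,
                               offset = cfg$camera_offset)
  corners <- c(prof[1, 1], prof[1, dim[2]], prof[dim[1], 1],
               prof[dim[1], dim[2]])
  list(profile = prof, cornerRatio = mean(corners), nMovies = nMovies)
}

#' Run a named end-to-end scenario
#'
#' Simulates, analyzes and reports one of the package's canonical
#' scenarios with a fixed root seed; per-scenario child seeds are derived
#' deterministically. When \code{outdir} is given, result tables are
#' written as CSV with a provenance JSON sidecar, so identical seeds give
#' byte-identical outputs.
#'
#' Scenarios: \code{membrane-vs-cytosolic} (autocorrelation secondary-peak
#' validation), \code{two-channel-membrane} (cross-correlation),
#' \code{induction-timelapse} (three-phase expression program and
#' normalized autocorrelation time course), \code{static-coloc}
#' (two-channel colocalization with chance baseline),
#' \code{counting-calibration} (bleach-decay counting and single-molecule
#' calibration), \code{illumination-recovery} (beam estimation).
#'
#' @param name scenario name; unknown names raise an error that lists the
#'   available scenarios.
#' @param config optional named list overriding
#'   \code{\link{defaultRunConfig}} keys.
#' @param outdir optional output directory.
#' @param seed root seed (default from config).
#' @return a list of scenario results, with the provenance block attached
#'   as attribute \code{provenance}.
#' @export
runScenario <- function(name, config = list(), outdir = NULL, seed = NULL) {
  if (!name %in% memlocScenarios)
    stop("unknown scenario '", name, "'; available: ",
         paste(memlocScenarios, collapse = ", "))
  cfg <- utils::modifyList(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- seed
  childSeed <- (cfg$seed * 1009L + match(name, memlocScenarios) * 101L) %%
    2147483647L
  set.seed(childSeed)
  res <- switch(name,
    "membrane-vs-cytosolic" = {
      mem <- autocorrScene("membrane", cfg = cfg)
      cyt <- autocorrScene("cytosolic", cfg = cfg)
      list(membrane = mem, cytosolic = cyt,
           table = data.frame(
             mode = c("membrane", "cytosolic"),
             peak_um = c(if (length(mem$peaks)) mem$peaks[1] else NA_real_,
                         if (length(cyt$peaks)) cyt$peaks[1] else NA_real_),
             score = c(mem$score, cyt$score)))
    },
    "two-channel-membrane" = {
      xc <- crossCorrScene(cfg = cfg)
      list(cross = xc,
           table = data.frame(
             peak_um = if (length(xc$peaks)) xc$peaks[1] else NA_real_))
    },
    "induction-timelapse" = {
      inductionTimelapse(cfg = cfg)
    },
    "static-coloc" = {
      staticColocScene(cfg = cfg)
    },
    "counting-calibration" = {
      countingScene(cfg = cfg)
    },
    "illumination-recovery" = {
      sc <- illuminationScene(cfg = cfg)
      sc$table <- data.frame(corner_ratio = sc$cornerRatio)
      sc
    })
  prov <- list(scenario = name, seed = cfg$seed, childSeed = childSeed,
               package = as.character(utils::packageVersion("memloc")))
  attr(res, "provenance") <- prov
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$table))
      utils::write.csv(res$table,
                       file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(prov, file.path(outdir, paste0(name, "_run.json")),
                         auto_unbox = TRUE)
  }
  res
}

# Time-lapse induction scenario: one large cell under the three-phase
# program, analyzed by the normalized autocorrelation time course.
inductionTimelapse <- function(nTimepoints = 37, cfg = defaultRunConfig()) {
  acq <- configAcquisition(cfg, dim = c(64L, 24L), nFrames = nTimepoints)
  cell <- CellGeometry(center = c(1.2, 3.2), orientation = 0,
                       length = 4.5, width = cfg$cell_width_um)
  program <- ExpressionProgram(tOnset = 60, productionRate = 1.2,
                               tPeak = 110, tRelease = 110,
                               decayRate = 0.04)
  photo <- Photophysics(bleachTau = Inf, photonRate = cfg$photon_rate)
  sim <- simulateTimelapse(cell, program, photo, acq,
                           intervalMin = cfg$timelapse_interval_min)
  mask <- makeMask(cell, acq)
  filt <- discoidalFilter(sim$stack, cfg$discoidal_r_inner,
                          cfg$discoidal_r_outer)
  cfs <- lapply(seq_len(nTimepoints), function(t)
    suppressWarnings(rowAutocorrelation(
      frames(filt)[, , t], maxLag = min(cfg$max_lag_um, 1.0),
      binHeight = cfg$bin_height_um, pixelSize = cfg$pixel_size_um)))
  # per-frame background from the cell-free region of the same field
  bg <- meanCellIntensity(sim$stack, !dilateMask(mask, 8L))
  I <- meanCellIntensity(sim$stack, mask) - bg
  tc <- normalizeTimecourse(cfs, pmax(I, 0), times = sim$times)
  list(sim = sim, timecourse = tc, program = program, mask = mask,
       intensities = I,
       table = data.frame(time = sim$times, intensity = I))
}

# Two-channel static-focus colocalization scenario.
staticColocScene <- function(nCells = 40, nA = 2, nB = 2,
                             colocFraction = 0.27, offsetSdNm = 30,
                             cfg = defaultRunConfig()) {
  acq <- configAcquisition(cfg, dim = c(160L, 160L), nFrames = 10L)
  photo <- Photophysics(bleachTau = Inf, photonRate = cfg$photon_rate)
  cells <- layoutCells(nCells, acq, length = cfg$cell_length_um,
                       width = 0.8)
  sim <- simulateTwoChannel(cells, nA = nA, nB = nB,
                            colocFraction = colocFraction,
                            offsetSdNm = offsetSdNm, photo = photo,
                            acq = acq)
  projA <- averageProjection(sim$stackA)
  projB <- averageProjection(sim$stackB)
  perCell <- do.call(rbind, lapply(seq_along(cells), function(k) {
    # analyze each cell's foci from the projections
    fociA <- fitProjectionFoci(projA, cells[[k]], acq)
    fociB <- fitProjectionFoci(projB, cells[[k]], acq)
    m <- matchFoci(fociA, fociB, cfg$coloc_radius_nm)
    data.frame(cell = k, nA = nrow(fociA), nB = nrow(fociB),
               fraction = m$fraction)
  }))
  truthA <- sim$fociA
  chance <- chanceBaseline(cells, truthA, nBPerCell = nB,
                           radiusNm = cfg$coloc_radius_nm, nDraws = 200)
  stats <- perCellStats(perCell, chance = chance$baseline)
  list(sim = sim, perCell = perCell, stats = stats, chance = chance,
       cells = cells, table = stats)
}

# Detect+fit foci of one cell in an average projection.
fitProjectionFoci <- function(proj, cell, acq) {
  filt <- discoidalFilter(proj)
  cand <- detectFoci(filt)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fitGaussianFocus(proj, cand$row[i], cand$col[i],
                     pixelSize = acq@pixelSize, psfSigma = acq@psfSigma)))
  if (is.null(fits)) return(data.frame(x = numeric(0), y = numeric(0)))
  keep <- insideFootprint(cell, fits$x, fits$y, tol = 0.15)
  fits[keep, c("x", "y"), drop = FALSE]
}

# Bleach counting + calibration scenario: known emitter numbers, count
# recovery through the returns calibration. Fields of at most 12 labeled
# cells are simulated until nCells have been measured.
countingScene <- function(nCells = 20, emittersPerCell = 16,
                          cfg = defaultRunConfig()) {
  perField <- 10L
  if (nCells > perField) {
    done <- 0L; out <- NULL; sims <- list(); calib <- NULL
    while (done < nCells) {
      nf <- min(perField, nCells - done)
      sc <- countingScene(nf, emittersPerCell, cfg)
      sc$perCell$cell <- sc$perCell$cell + done
      out <- rbind(out, sc$perCell)
      done <- done + nf
      calib <- sc$calibration; sims <- c(sims, list(sc$sim))
    }
    return(list(sim = sims, calibration = calib, perCell = out,
                trueCount = emittersPerCell, table = out))
  }
  # mild blinking: enough dark-state returns late in the movie for the
  # single-molecule calibration without distorting the ensemble decay
  cfgPhoto <- Photophysics(bleachTau = cfg$bleach_tau_s,
                           photonRate = cfg$photon_rate,
                           darkRate = 0.05, returnRate = 0.01)
  acq <- configAcquisition(cfg, dim = c(180L, 180L))
  nRef <- 6L
  cells <- layoutCells(nCells + nRef, acq, length = cfg$cell_length_um,
                       width = 0.8, minSep = 2.5)
  emitters <- lapply(seq_along(cells), function(k)
    seedEmitters(cells[[k]], "static",
                 if (k <= nCells) emittersPerCell else 0L))
  sim <- simulateTimesampling(cells, emitters, cfgPhoto, acq)
  masks <- lapply(cells, makeMask, acq = acq)
  # photometry masks: cell outline dilated by 3 px to capture the PSF
  # spill of peripheral molecules; geometry (volume) from the plain mask
  pmasks <- lapply(masks, dilateMask, radius = 3L)
  allMask <- makeMask(cells, acq)
  bgFit <- fitDecay(cellTrajectory(sim$stack, !dilateMask(allMask, 10L)))
  afVals <- rowMeans(vapply(nCells + seq_len(nRef), function(k)
    cellTrajectory(sim$stack, pmasks[[k]])$value, numeric(acq@nFrames)))
  afFit <- fitDecay(data.frame(
    time = (seq_len(acq@nFrames) - 1) * acq@frameInterval, value = afVals))
  afFit <- ExpDecayFit(afFit@amplitude, afFit@tau,
                       afFit@offset - (bgFit@amplitude + bgFit@offset),
                       afFit@residualNorm, afFit@flagged)
  calib <- smIntensityFromReturns(sim$stack, tailFrames = cfg$tail_frames,
                                  psfSigma = cfg$psf_sigma_um)
  perCell <- do.call(rbind, lapply(seq_len(nCells), function(k) {
    fit <- fitDecay(correctTrajectory(cellTrajectory(sim$stack, pmasks[[k]]),
                                      afFit, bgFit))
    vol <- cellVolume(masks[[k]], cfg$pixel_size_um)
    nMol <- if (!isFlagged(fit) && !isFlagged(calib))
      countMolecules(fit, sum(pmasks[[k]]), calib) else NA_real_
    data.frame(cell = k, amplitude = amplitude(fit), tau = decayTau(fit),
               flagged = isFlagged(fit), area_px = vol$areaPx,
               volume_fL = vol$volume, n_molecules = nMol,
               concentration_nM = if (is.na(nMol)) NA_real_ else
                 concentrationNM(nMol, vol$volume))
  }))
  list(sim = sim, calibration = calib, perCell = perCell,
       trueCount = emittersPerCell, table = perCell)
}
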