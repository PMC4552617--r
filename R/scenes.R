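# Scene-level simulators: time-sampling movies, time-lapse series,
# two-channel static-focus scenes.

#' Lay out vertically oriented cells in a field of view
#'
#' Arranges \code{n} cells in horizontal rows spanning the field; within
#' each row the horizontal cell positions are drawn uniformly at random
#' (with a minimum separation so cells do not overlap), as in a flow-cell
#' field where cells attach at random positions but align with the flow.
#' Each cell is vertical up to a small orientation jitter.
#'
#' @param n number of cells.
#' @param acq an \code{\link{Acquisition}} (field size).
#' @param length,width cell dimensions (um); both may be vectors recycled
#'   over cells.
#' @param jitterDeg half-range of the orientation jitter in degrees
#'   (uniform in [-jitterDeg, +jitterDeg], default 5).
#' @param positionJitter SD of vertical center jitter (um).
#' @param minSep minimum center-to-center separation within a row (um);
#'   default cell width + 0.35.
#' @return a list of \code{\link{CellGeometry}}.
#' @export
layoutCells <- function(n, acq, length = 3, width = 0.6, jitterDeg = 5,
                        positionJitter = 0.15, minSep = NULL) {
  fw <- acq@dim[2] * acq@pixelSize
  fh <- acq@dim[1] * acq@pixelSize
  len <- rep_len(length, n); wid <- rep_len(width, n)
  margin <- max(len) / 2 + 0.3
  rowPitch <- max(len) + 0.6
  nRows <- max(1L, floor((fh - 2 * margin) / rowPitch) + 1L)
  ys <- seq(margin, fh - margin, length.out = max(nRows, 2L))[seq_len(nRows)]
  perRow <- ceiling(n / nRows)
  if (is.null(minSep)) minSep <- max(wid) + 0.35
  x0 <- 0.5 + max(wid); x1 <- fw - 0.5 - max(wid)
  cells <- vector("list", n)
  i <- 0L
  for (ry in ys) {
    if (i >= n) break
    m <- min(perRow, n - i)
    # random horizontal positions with minimum separation (dart throwing,
    # falling back to an evenly spaced row when the field is crowded)
    xs <- numeric(0)
    for (tries in seq_len(200L * m)) {
      if (length(xs) >= m) break
      cand <- stats::runif(1, x0, x1)
      if (all(abs(cand - xs) >= minSep)) xs <- c(xs, cand)
    }
    if (length(xs) < m)
      xs <- c(xs, seq(x0, x1, length.out = m))[seq_len(m)]
    for (cx in xs[seq_len(m)]) {
      i <- i + 1L
      cy <- ry + stats::rnorm(1, 0, positionJitter)
      th <- stats::runif(1, -jitterDeg, jitterDeg) * pi / 180
      cells[[i]] <- CellGeometry(center = c(cx, cy), orientation = th,
                                 length = len[i], width = wid[i])
    }
  }
  cells
}

# Record the truth of one frame into preallocated structures.
recordTruth <- function(frame, cells, emitters) {
  do.call(rbind, lapply(seq_along(cells), function(k) {
    em <- emitters[[k]]
    if (nrow(em) == 0L)
      return(NULL)
    pos <- cellToImage(cells[[k]], em$a, em$b)
    data.frame(frame = frame, cell = k, id = seq_len(nrow(em)),
               x = pos$x, y = pos$y, mode = em$mode, state = em$state,
               channel = em$channel, stringsAsFactors = FALSE)
  }))
}

#' Simulate a video-rate time-sampling movie
#'
#' Renders \code{acq@nFrames} consecutive frames of a field of cells,
#' advancing Brownian dynamics and photophysics by one frame interval
#' between frames. Defaults emulate fast continuous acquisition (296 frames
#' of 34 ms) during which the label photobleaches.
#'
#' @param cells list of \code{\link{CellGeometry}}.
#' @param emitters list of emitter data.frames parallel to \code{cells}
#'   (see \code{\link{seedEmitters}}).
#' @param photo a \code{\link{Photophysics}}.
#' @param acq an \code{\link{Acquisition}}.
#' @param DMembrane,DCyto diffusion coefficients (um^2/s).
#' @param recordPositions keep per-frame emitter positions in the ground
#'   truth (memory-heavy for long movies).
#' @return list with elements \code{stack} (\code{\link{ImageStack}}) and
#'   \code{truth} (\code{\link{GroundTruth}}).
#' @export
simulateTimesampling <- function(cells, emitters, photo = Photophysics(),
                                 acq = Acquisition(), DMembrane = 0.02,
                                 DCyto = 5, recordPositions = FALSE) {
  if (is(cells, "CellGeometry")) cells <- list(cells)
  if (is.data.frame(emitters)) emitters <- list(emitters)
  nT <- acq@nFrames
  mask <- makeMask(cells, acq)
  arr <- array(0, c(acq@dim, nT))
  counts <- matrix(0, length(cells), nT)
  posList <- if (recordPositions) vector("list", nT) else NULL
  for (t in seq_len(nT)) {
    counts[, t] <- vapply(emitters, function(e) sum(e$state != "bleached"),
                          numeric(1))
    if (recordPositions) posList[[t]] <- recordTruth(t, cells, emitters)
    arr[, , t] <- renderFrame(cells, emitters, photo, acq, mask = mask,
                              DMembrane = DMembrane, DCyto = DCyto)
    emitters <- lapply(seq_along(cells), function(k)
      stepDynamics(emitters[[k]], cells[[k]], photo, acq@frameInterval,
                   DMembrane, DCyto))
  }
  truth <- new("GroundTruth", counts = counts,
               positions = if (recordPositions)
                 do.call(rbind, posList) else data.frame(),
               pairs = data.frame())
  list(stack = ImageStack(arr, acq@pixelSize, acq@frameInterval),
       truth = truth, finalEmitters = emitters)
}

# Deterministic molecule count of the expression program at time t (min).
programCount <- function(program, t) {
  n <- numeric(length(t))
  rising <- t >= program@tOnset & t <= program@tPeak
  n[rising] <- program@productionRate * (t[rising] - program@tOnset)
  nPeak <- program@productionRate * (program@tPeak - program@tOnset)
  falling <- t > program@tPeak
  n[falling] <- nPeak * exp(-program@decayRate * (t[falling] - program@tPeak))
  n
}

#' Simulate a time-lapse series driven by an expression program
#'
#' Renders one frame every \code{intervalMin} minutes while the molecule
#' count of each cell follows the deterministic three-phase program: zero
#' before onset, linear accumulation to the peak, exponential decline after.
#' Molecules are produced in \code{program@initialMode}; at
#' \code{program@tRelease} every molecule switches to
#' \code{program@releasedMode} and is re-seeded in the corresponding
#' compartment. Because frames are minutes apart, diffusing molecules are
#' fully mixed between frames: mobile emitter positions are re-drawn
#' uniformly (surface or volume) at every frame.
#'
#' @param cells list of \code{\link{CellGeometry}}.
#' @param program an \code{\link{ExpressionProgram}}.
#' @param photo a \code{\link{Photophysics}} (photon rate only; time-lapse
#'   exposures are too sparse for appreciable bleaching, which the program's
#'   decay term absorbs).
#' @param acq an \code{\link{Acquisition}} (nFrames = number of time points).
#' @param intervalMin minutes between frames (default 5).
#' @param tStart first time point in minutes (default 0).
#' @return list with \code{stack}, \code{truth}, and \code{times} (min).
#' @export
simulateTimelapse <- function(cells, program = ExpressionProgram(),
                              photo = Photophysics(), acq = Acquisition(),
                              intervalMin = 5, tStart = 0) {
  if (is(cells, "CellGeometry")) cells <- list(cells)
  nT <- acq@nFrames
  times <- tStart + (seq_len(nT) - 1) * intervalMin
  mask <- makeMask(cells, acq)
  arr <- array(0, c(acq@dim, nT))
  counts <- matrix(0, length(cells), nT)
  posList <- vector("list", nT)
  noBleach <- Photophysics(bleachTau = Inf, darkRate = 0, returnRate = 0,
                           photonRate = photo@photonRate)
  for (t in seq_len(nT)) {
    tm <- times[t]
    nTarget <- round(programCount(program, tm))
    mode <- if (tm >= program@tRelease) program@releasedMode else
      program@initialMode
    emitters <- lapply(cells, function(cell)
      seedEmitters(cell, mode, nTarget))
    counts[, t] <- nTarget
    posList[[t]] <- recordTruth(t, cells, emitters)
    arr[, , t] <- renderFrame(cells, emitters, noBleach, acq, mask = mask)
  }
  truth <- new("GroundTruth", counts = counts,
               positions = do.call(rbind, posList), pairs = data.frame())
  list(stack = ImageStack(arr, acq@pixelSize, intervalMin * 60),
       truth = truth, times = times)
}

#' Simulate a two-channel scene of static foci
#'
#' Places \code{nA} immobile foci per cell in channel A and \code{nB} in
#' channel B; each B focus is independently colocalized with probability
#' \code{colocFraction}, placed at an A focus (distinct anchors while any
#' remain) plus an isotropic Gaussian offset of standard deviation
#' \code{offsetSdNm} per axis; the rest are uniform inside the cell
#' volume. Both channels are rendered as short movies of static
#' emitters (no bleaching), e.g. for average-projection analysis.
#'
#' @param cells list of \code{\link{CellGeometry}}.
#' @param nA,nB foci per cell in channels A and B.
#' @param colocFraction fraction of B foci tied to an A focus, in [0, 1].
#' @param offsetSdNm SD of the pairing offset (nanometers).
#' @param photo a \code{\link{Photophysics}}.
#' @param acq an \code{\link{Acquisition}}.
#' @return list with \code{stackA}, \code{stackB}, \code{truth}; the truth
#'   \code{pairs} table holds one row per B focus with its generation label
#'   (\code{colocalized}) and true positions of both channels.
#' @export
simulateTwoChannel <- function(cells, nA = 2, nB = 2, colocFraction = 0,
                               offsetSdNm = 0, photo = Photophysics(
                                 bleachTau = Inf),
                               acq = Acquisition(nFrames = 10L)) {
  if (is(cells, "CellGeometry")) cells <- list(cells)
  stopifnot(colocFraction >= 0, colocFraction <= 1)
  emA <- vector("list", length(cells))
  emB <- vector("list", length(cells))
  pairRows <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    A <- seedEmitters(cell, "static", nA, channel = "A")
    B <- seedEmitters(cell, "static", nB, channel = "B")
    # each B focus is independently colocalized with probability
    # colocFraction, anchored to distinct A foci while any remain
    lab <- if (nB > 0) stats::runif(nB) < colocFraction else logical(0)
    if (nA == 0) lab[] <- FALSE
    idx <- which(lab)
    if (length(idx) > 0) {
      anchor <- if (length(idx) <= nA) sample.int(nA, length(idx)) else
        c(sample.int(nA, nA),
          sample.int(nA, length(idx) - nA, replace = TRUE))
      off <- offsetSdNm / 1000
      B$a[idx] <- A$a[anchor] + stats::rnorm(length(idx), 0, off)
      B$b[idx] <- A$b[anchor] + stats::rnorm(length(idx), 0, off)
      B$c[idx] <- A$c[anchor]
    }
    emA[[k]] <- A; emB[[k]] <- B
    pA <- cellToImage(cell, A$a, A$b)
    pB <- cellToImage(cell, B$a, B$b)
    pairRows[[k]] <- data.frame(
      cell = k, focusB = seq_len(max(nB, 0)), colocalized = lab,
      xB = pB$x, yB = pB$y,
      stringsAsFactors = FALSE)
    attr(pairRows[[k]], "fociA") <- data.frame(cell = k, x = pA$x, y = pA$y)
  }
  fociA <- do.call(rbind, lapply(pairRows, attr, "fociA"))
  simA <- simulateTimesampling(cells, emA, photo, acq, DMembrane = 0,
                               DCyto = 0)
  simB <- simulateTimesampling(cells, emB, photo, acq, DMembrane = 0,
                               DCyto = 0)
  pairs <- do.call(rbind, pairRows)
  attr(pairs, "fociA") <- fociA
  truth <- new("GroundTruth", counts = simB$truth@counts,
               positions = data.frame(), pairs = pairs)
  list(stackA = simA$stack, stackB = simB$stack, truth = truth,
       fociA = fociA)
}
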