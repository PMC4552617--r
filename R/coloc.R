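# Two-channel focus colocalization with a Monte-Carlo chance baseline.

#' Match foci between two channels
#'
#' Mutual-nearest-neighbor pairing under a distance cap: an A focus and a B
#' focus are paired when each is the other's nearest unpaired neighbor and
#' their distance does not exceed \code{radiusNm}. Pairing is iterated
#' (closest mutual pairs first) so no focus is counted twice. The
#' colocalized fraction is the number of paired B foci over all B foci.
#'
#' @param fociA,fociB data.frames with columns x, y in micrometers (common
#'   coordinate system).
#' @param radiusNm distance cap in nanometers (default 100).
#' @return list with \code{pairs} (data.frame of indices a, b and distance
#'   in um) and \code{fraction} (paired B / total B; NA when B is empty).
#' @export
matchFoci <- function(fociA, fociB, radiusNm = 100) {
  nA <- nrow(fociA); nB <- nrow(fociB)
  if (nB == 0L)
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   distance = numeric(0)), fraction = NA_real_))
  if (nA == 0L)
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   distance = numeric(0)), fraction = 0))
  cap <- radiusNm / 1000
  d <- sqrt(outer(fociA$x, fociB$x, "-")^2 + outer(fociA$y, fociB$y, "-")^2)
  freeA <- rep(TRUE, nA); freeB <- rep(TRUE, nB)
  pa <- integer(0); pb <- integer(0); pd <- numeric(0)
  repeat {
    dd <- d
    dd[!freeA, ] <- Inf; dd[, !freeB] <- Inf
    # mutual nearest neighbors within the cap
    found <- FALSE
    nnB <- apply(dd, 2, which.min)
    nnA <- apply(dd, 1, which.min)
    for (b in which(freeB)) {
      a <- nnB[b]
      if (!freeA[a] || dd[a, b] > cap) next
      if (nnA[a] == b) {
        pa <- c(pa, a); pb <- c(pb, b); pd <- c(pd, d[a, b])
        freeA[a] <- FALSE; freeB[b] <- FALSE
        found <- TRUE
      }
    }
    if (!found) break
  }
  list(pairs = data.frame(a = pa, b = pb, distance = pd),
       fraction = length(pb) / nB)
}

#' Monte-Carlo chance-colocalization baseline
#'
#' Estimates the colocalized fraction expected by chance: B foci are placed
#' uniformly at random inside each cell footprint and matched against the
#' fixed A foci of that cell; the fraction of B foci paired, averaged over
#' draws, is the baseline. For well-separated A foci this converges to the
#' capture-area ratio nA * pi * r^2 / footprint area, but the Monte-Carlo
#' estimate also handles overlapping capture disks and cell-boundary
#' effects.
#'
#' @param cells list of \code{\link{CellGeometry}}.
#' @param fociA data.frame with columns cell, x, y (um): fixed A foci.
#' @param nBPerCell number of random B foci per cell per draw.
#' @param radiusNm colocalization radius (nm).
#' @param nDraws number of Monte-Carlo draws (>= 10 for a usable estimate;
#'   default 1000).
#' @return list with \code{baseline} (mean fraction), \code{se}
#'   (Monte-Carlo standard error), \code{draws}.
#' @export
chanceBaseline <- function(cells, fociA, nBPerCell = 2, radiusNm = 100,
                           nDraws = 1000) {
  if (is(cells, "CellGeometry")) cells <- list(cells)
  fr <- numeric(nDraws)
  for (d in seq_len(nDraws)) {
    paired <- 0L; total <- 0L
    for (k in seq_along(cells)) {
      A <- fociA[fociA$cell == k, , drop = FALSE]
      em <- seedEmitters(cells[[k]], "static", nBPerCell)
      pos <- cellToImage(cells[[k]], em$a, em$b)
      B <- data.frame(x = pos$x, y = pos$y)
      m <- matchFoci(A, B, radiusNm)
      paired <- paired + nrow(m$pairs); total <- total + nrow(B)
    }
    fr[d] <- if (total > 0) paired / total else NA_real_
  }
  list(baseline = mean(fr, na.rm = TRUE),
       se = stats::sd(fr, na.rm = TRUE) / sqrt(sum(!is.na(fr))),
       draws = fr)
}

#' Per-cell colocalization statistics
#'
#' Summarizes per-cell focus counts and colocalized fractions: means with
#' standard errors computed over cells (not over foci).
#'
#' @param perCell data.frame with one row per cell and columns \code{nA},
#'   \code{nB}, \code{fraction} (NA where a cell had no B foci).
#' @param chance optional chance baseline fraction to attach.
#' @return one-row data.frame: nCells, meanA, meanB, fraction, sem, chance.
#' @export
perCellStats <- function(perCell, chance = NA_real_) {
  stopifnot(nrow(perCell) >= 1L)
  fr <- perCell$fraction[!is.na(perCell$fraction)]
  data.frame(
    nCells = nrow(perCell),
    meanA = mean(perCell$nA), meanB = mean(perCell$nB),
    fraction = if (length(fr)) mean(fr) else NA_real_,
    sem = if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr)) else
      NA_real_,
    chance = chance)
}
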