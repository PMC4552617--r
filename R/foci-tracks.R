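# Temporal linking of foci and static-focus selection.

#' Link foci across frames into tracks
#'
#' Greedy nearest-neighbor linking: at each frame transition, candidate
#' (track end, new focus) pairs are sorted by distance and assigned
#' one-to-one while the distance stays within \code{maxJump} pixels
#' (scaled by the number of skipped frames plus one when gap closing).
#' Unmatched tracks stay open for up to \code{maxGap} missed frames;
#' unmatched foci start new tracks.
#'
#' @param foci data.frame of fitted foci with columns x, y (um) and frame.
#' @param pixelSize um per pixel (converts \code{maxJump} to um).
#' @param maxJump maximum per-frame displacement (px, default 2).
#' @param maxGap maximum number of missed frames bridged (default 1).
#' @return the input data.frame with an added integer \code{track} column.
#' @export
linkTracks <- function(foci, pixelSize = 0.1, maxJump = 2, maxGap = 1) {
  if (nrow(foci) == 0L) {
    foci$track <- integer(0)
    return(foci)
  }
  foci <- foci[order(foci$frame), , drop = FALSE]
  foci$track <- NA_integer_
  maxJumpUm <- maxJump * pixelSize
  nextId <- 1L
  # active tracks: id, last x, y, last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    lastFrame = integer(0))
  for (f in sort(unique(foci$frame))) {
    sel <- which(foci$frame == f)
    act <- act[f - act$lastFrame <= maxGap + 1L, , drop = FALSE]
    if (nrow(act) && length(sel)) {
      cand <- expand.grid(ti = seq_len(nrow(act)), fi = seq_along(sel))
      gap <- f - act$lastFrame[cand$ti]
      d <- sqrt((act$x[cand$ti] - foci$x[sel][cand$fi])^2 +
                (act$y[cand$ti] - foci$y[sel][cand$fi])^2)
      ok <- d <= maxJumpUm * gap
      cand <- cand[ok, , drop = FALSE]; d <- d[ok]
      ord <- order(d)
      usedT <- logical(nrow(act)); usedF <- logical(length(sel))
      for (i in ord) {
        ti <- cand$ti[i]; fi <- cand$fi[i]
        if (usedT[ti] || usedF[fi]) next
        usedT[ti] <- TRUE; usedF[fi] <- TRUE
        id <- act$id[ti]
        foci$track[sel[fi]] <- id
        act$x[ti] <- foci$x[sel[fi]]
        act$y[ti] <- foci$y[sel[fi]]
        act$lastFrame[ti] <- f
      }
      new <- sel[!usedF]
    } else new <- sel
    for (i in new) {
      foci$track[i] <- nextId
      act <- rbind(act, data.frame(id = nextId, x = foci$x[i], y = foci$y[i],
                                   lastFrame = f))
      nextId <- nextId + 1L
    }
  }
  foci
}

#' Summarize tracks
#'
#' One row per track: start/end frames, number of foci, duration in seconds
#' ((end - start + 1) * frameInterval), and mean position.
#'
#' @param foci data.frame with a \code{track} column
#'   (\code{\link{linkTracks}}).
#' @param frameInterval seconds per frame.
#' @return data.frame with columns track, start, end, nFoci, duration, x, y.
#' @export
trackSummary <- function(foci, frameInterval = 0.034) {
  if (nrow(foci) == 0L)
    return(data.frame(track = integer(0), start = integer(0),
                      end = integer(0), nFoci = integer(0),
                      duration = numeric(0), x = numeric(0), y = numeric(0)))
  sp <- split(foci, foci$track)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    track = d$track[1], start = min(d$frame), end = max(d$frame),
    nFoci = nrow(d),
    duration = (max(d$frame) - min(d$frame) + 1L) * frameInterval,
    x = mean(d$x), y = mean(d$y))))
  rownames(out) <- NULL
  out[order(out$track), , drop = FALSE]
}

#' Select static foci by persistence
#'
#' Tracks whose duration strictly exceeds \code{minDuration} are flagged
#' static: molecules immobilized long enough (default > 300 ms, i.e. at
#' least 9 frames of 34 ms) to be interpreted as DNA-bound rather than
#' diffusing.
#'
#' @param tracks track summary data.frame (\code{\link{trackSummary}}).
#' @param minDuration persistence threshold in seconds (default 0.300).
#' @return the summary restricted to static tracks, with a \code{static}
#'   column added (all TRUE).
#' @export
staticFoci <- function(tracks, minDuration = 0.300) {
  out <- tracks[tracks$duration > minDuration, , drop = FALSE]
  if (nrow(out)) out$static <- TRUE else out$static <- logical(0)
  out
}
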