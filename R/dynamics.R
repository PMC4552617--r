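# Brownian dynamics and photophysics of the simulated emitters.

#' Advance emitters by one time step
#'
#' Moves and photo-switches the emitters of one cell over an interval
#' \code{dt}. Membrane emitters take a free 3D Brownian step (variance
#' 2 D dt per axis) and are re-projected radially onto the spherocylinder
#' surface; cytosolic emitters take Brownian steps with reflecting walls;
#' static emitters do not move. Photostates then update: bright emitters
#' bleach with rate 1/bleachTau (absorbing) or shelve into a dark state with
#' rate darkRate; dark emitters return to the bright state with rate
#' returnRate. With no blinking the expected bright survival after time t is
#' exactly exp(-t / bleachTau).
#'
#' @param emitters data.frame as returned by \code{\link{seedEmitters}}.
#' @param cell the \code{\link{CellGeometry}} the emitters belong to.
#' @param photo a \code{\link{Photophysics}}.
#' @param dt time step in seconds (> 0).
#' @param DMembrane,DCyto diffusion coefficients (um^2/s).
#' @return the updated emitter data.frame.
#' @export
stepDynamics <- function(emitters, cell, photo, dt,
                         DMembrane = 0.02, DCyto = 5) {
  stopifnot(dt > 0)
  n <- nrow(emitters)
  if (n == 0L) return(emitters)

  mob <- emitters$state != "bleached"   # bleached molecules are inert
  mem <- emitters$mode == "membrane" & mob
  cyt <- emitters$mode == "cytosolic" & mob

  if (any(mem) && DMembrane > 0) {
    s <- sqrt(2 * DMembrane * dt)
    k <- sum(mem)
    a <- emitters$a[mem] + stats::rnorm(k, 0, s)
    b <- emitters$b[mem] + stats::rnorm(k, 0, s)
    cc <- emitters$c[mem] + stats::rnorm(k, 0, s)
    sp <- nearestSurfacePoint(a, b, cc, cell)
    emitters$a[mem] <- sp$sa
    emitters$b[mem] <- sp$sb
    emitters$c[mem] <- sp$sc
  }
  if (any(cyt) && DCyto > 0) {
    s <- sqrt(2 * DCyto * dt)
    k <- sum(cyt)
    a <- emitters$a[cyt] + stats::rnorm(k, 0, s)
    b <- emitters$b[cyt] + stats::rnorm(k, 0, s)
    cc <- emitters$c[cyt] + stats::rnorm(k, 0, s)
    for (iter in 1:8) {                 # specular reflection at the wall
      out <- !insideSpherocylinder(a, b, cc, cell)
      if (!any(out)) break
      sp <- nearestSurfacePoint(a[out], b[out], cc[out], cell)
      a[out] <- 2 * sp$sa - a[out]
      b[out] <- 2 * sp$sb - b[out]
      cc[out] <- 2 * sp$sc - cc[out]
    }
    out <- !insideSpherocylinder(a, b, cc, cell)
    if (any(out)) {                     # pathological step: place just inside
      sp <- nearestSurfacePoint(a[out], b[out], cc[out], cell)
      eps <- 1e-6
      a[out] <- sp$sa - eps * sp$na
      b[out] <- sp$sb - eps * sp$nb
      cc[out] <- sp$sc - eps * sp$nc
    }
    emitters$a[cyt] <- a
    emitters$b[cyt] <- b
    emitters$c[cyt] <- cc
  }

  # photostate transitions over dt (competing exponential rates)
  kb <- if (is.finite(photo@bleachTau) && photo@bleachTau > 0)
    1 / photo@bleachTau else 0
  kd <- photo@darkRate
  kr <- photo@returnRate
  bright <- which(emitters$state == "bright")
  if (length(bright) && (kb + kd) > 0) {
    p <- 1 - exp(-(kb + kd) * dt)
    hit <- bright[stats::runif(length(bright)) < p]
    if (length(hit)) {
      toBleach <- stats::runif(length(hit)) < kb / (kb + kd)
      emitters$state[hit[toBleach]] <- "bleached"
      emitters$state[hit[!toBleach]] <- "dark"
    }
  }
  dark <- which(emitters$state == "dark")
  if (length(dark) && kr > 0) {
    p <- 1 - exp(-kr * dt)
    back <- dark[stats::runif(length(dark)) < p]
    emitters$state[back] <- "bright"
  }
  emitters
}
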