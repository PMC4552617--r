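# Frame rendering with EMCCD noise model.

#' Gaussian vignette illumination field
#'
#' Smooth radial illumination profile on the pixel grid: a centered 2D
#' Gaussian scaled so the corner pixels receive \code{cornerRatio} of the
#' center intensity, emulating the slightly uneven excitation beam of a
#' widefield microscope.
#'
#' @param dim integer(2), image size (rows, columns).
#' @param cornerRatio corner-to-center intensity ratio in (0, 1].
#' @return a matrix with maximum 1.
#' @export
gaussianVignette <- function(dim, cornerRatio = 0.70) {
  stopifnot(cornerRatio > 0, cornerRatio <= 1)
  d <- as.integer(dim)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- matrix(seq_len(d[1]) - cy, d[1], d[2])
  xx <- matrix(seq_len(d[2]) - cx, d[1], d[2], byrow = TRUE)
  r2 <- xx^2 + yy^2
  if (cornerRatio == 1) return(matrix(1, d[1], d[2]))
  r2max <- (d[1] - cy)^2 + (d[2] - cx)^2
  sig2 <- r2max / (2 * log(1 / cornerRatio))
  exp(-r2 / (2 * sig2))
}

# Illumination value at continuous image positions (um); flat field -> 1.
illuminationAt <- function(acq, x, y) {
  if (length(acq@illumination) == 0) return(rep(1, length(x)))
  ps <- acq@pixelSize
  ci <- pmin(pmax(floor(y / ps) + 1, 1), acq@dim[1])
  cj <- pmin(pmax(floor(x / ps) + 1, 1), acq@dim[2])
  acq@illumination[cbind(ci, cj)]
}

# Add one PSF-blurred emitter to the expected-photon image. The Gaussian is
# integrated exactly over each pixel (difference of normal CDFs), so the
# image sum equals `photons` up to window truncation (window = 5 sigma).
addEmitterPhotons <- function(img, x, y, photons, acq, sig = acq@psfSigma) {
  ps <- acq@pixelSize
  halfw <- ceiling(5 * sig / ps)
  cj <- floor(x / ps) + 1
  ci <- floor(y / ps) + 1
  j0 <- max(1, cj - halfw); j1 <- min(ncol(img), cj + halfw)
  i0 <- max(1, ci - halfw); i1 <- min(nrow(img), ci + halfw)
  if (j0 > j1 || i0 > i1) return(img)
  xe <- (j0 - 1):j1 * ps                      # pixel edges
  ye <- (i0 - 1):i1 * ps
  px <- diff(stats::pnorm(xe, mean = x, sd = sig))
  py <- diff(stats::pnorm(ye, mean = y, sd = sig))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + photons * (py %o% px)
  img
}

#' Render one camera frame
#'
#' Builds the expected photon image of a scene and (optionally) applies the
#' EMCCD noise model. Bright emitters are drawn as 2D Gaussians, each
#' carrying an expected \code{photonRate * frameInterval} photons scaled by
#' the local illumination. The spot width of each emitter is its in-focus
#' \code{psfSigma} widened by defocus (the focal plane lies at the cell
#' midplane, so molecules on the near and far cell surface render blurred
#' and dim while molecules at the in-plane periphery stay sharp) and, for
#' diffusing emitters, by intra-frame motion blur (variance D *
#' frameInterval / 3 per axis, fully blurring fast cytosolic molecules
#' within one frame). Uniform coverslip background is added everywhere and
#' cellular autofluorescence inside the cell footprints, both scaled by the
#' illumination. With \code{noise = TRUE} the photon image is Poisson
#' sampled, amplified through a Gamma(shape = photons, scale = emGain)
#' electron-multiplication stage, Gaussian read noise and the camera offset
#' are added, and the result is rounded and clamped at zero. With
#' \code{noise = FALSE} the expected output \code{photons * emGain + offset}
#' is returned unrounded.
#'
#' @param cells list of \code{\link{CellGeometry}} (or a single one).
#' @param emitters list of emitter data.frames parallel to \code{cells}.
#' @param photo a \code{\link{Photophysics}} (supplies the photon rate).
#' @param acq an \code{\link{Acquisition}}.
#' @param noise logical, apply the stochastic camera model.
#' @param mask optional precomputed logical mask of cell interiors (else
#'   computed from \code{cells}).
#' @param DMembrane,DCyto diffusion coefficients (um^2/s) used for the
#'   motion-blur term of membrane and cytosolic emitters.
#' @return a numeric matrix of camera counts.
#' @export
renderFrame <- function(cells, emitters, photo, acq, noise = TRUE,
                        mask = NULL, DMembrane = 0.02, DCyto = 5) {
  if (is(cells, "CellGeometry")) { cells <- list(cells) }
  if (is.data.frame(emitters)) emitters <- list(emitters)
  stopifnot(length(cells) == length(emitters))
  d <- acq@dim
  img <- matrix(0, d[1], d[2])

  for (k in seq_along(cells)) {
    em <- emitters[[k]]
    if (is.null(em) || nrow(em) == 0L) next
    br <- em$state == "bright"
    if (!any(br)) next
    pos <- cellToImage(cells[[k]], em$a[br], em$b[br])
    ill <- illuminationAt(acq, pos$x, pos$y)
    nph <- photo@photonRate * acq@frameInterval * ill
    defoc <- if (acq@depthOfField > 0 && is.finite(acq@depthOfField))
      1 + (em$c[br] / acq@depthOfField)^2 else rep(1, sum(br))
    Dmode <- ifelse(em$mode[br] == "membrane", DMembrane,
                    ifelse(em$mode[br] == "cytosolic", DCyto, 0))
    sig <- sqrt(acq@psfSigma^2 * defoc + Dmode * acq@frameInterval / 3)
    for (i in seq_along(pos$x))
      img <- addEmitterPhotons(img, pos$x[i], pos$y[i], nph[i], acq, sig[i])
  }

  ill <- if (length(acq@illumination)) acq@illumination else
    matrix(1, d[1], d[2])
  img <- img + acq@backgroundRate * acq@frameInterval * ill
  if (acq@autofluorRate > 0 && length(cells)) {
    if (is.null(mask)) mask <- makeMask(cells, acq)
    img <- img + acq@autofluorRate * acq@frameInterval * ill * mask
  }

  if (!noise) return(img * acq@emGain + acq@offset)

  n <- stats::rpois(length(img), img)
  out <- numeric(length(img))
  pos <- n > 0
  if (acq@emGain > 1) {
    out[pos] <- stats::rgamma(sum(pos), shape = n[pos], scale = acq@emGain)
  } else {
    out[pos] <- n[pos] * acq@emGain
  }
  out <- out + stats::rnorm(length(out), 0, acq@readNoise) + acq@offset
  matrix(pmax(round(out), 0), d[1], d[2])
}
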