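# Spherocylinder geometry: emitter seeding, coordinate transforms, masks.

# Long-axis and short-axis unit vectors of a cell in image coordinates
# (x = column, y = row); orientation is measured from the image vertical.
cellAxes <- function(cell) {
  th <- cell@orientation
  list(u = c(sin(th), cos(th)),   # long axis
       v = c(cos(th), -sin(th)))  # short axis
}

# Cylindrical half-length of the spherocylinder (pole-to-pole length minus
# the two hemispherical caps).
cylHalfLength <- function(cell) (cell@length - cell@width) / 2

# TRUE for cell-frame points (a = axial, b, c = transverse) inside the
# spherocylinder volume.
insideSpherocylinder <- function(a, b, cc, cell, tol = 0) {
  r <- cell@width / 2 + tol
  h <- cylHalfLength(cell)
  ax <- pmax(abs(a) - h, 0)
  ax^2 + b^2 + cc^2 <= r^2
}

# Nearest point on the spherocylinder surface and its outward radial
# direction, for cell-frame points. Points on the axis get a random
# transverse direction.
nearestSurfacePoint <- function(a, b, cc, cell) {
  h <- cylHalfLength(cell)
  r <- cell@width / 2
  axp <- pmin(pmax(a, -h), h)
  dx <- a - axp; dy <- b; dz <- cc
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  deg <- nrm < 1e-12
  if (any(deg)) {
    phi <- stats::runif(sum(deg), 0, 2 * pi)
    dy[deg] <- cos(phi); dz[deg] <- sin(phi); dx[deg] <- 0
    nrm[deg] <- 1
  }
  list(sa = axp + r * dx / nrm, sb = r * dy / nrm, sc = r * dz / nrm,
       na = dx / nrm, nb = dy / nrm, nc = dz / nrm)
}

emitterModes <- c("membrane", "cytosolic", "static")

#' Seed emitters in or on a cell
#'
#' Places \code{n} fluorophores in the frame of one cell: uniformly on the
#' spherocylinder surface for \code{mode = "membrane"} (slowly diffusing
#' membrane-associated molecules that appear as sharp peripheral foci),
#' uniformly inside the volume for \code{"cytosolic"} (fast-diffusing
#' molecules that blur within one frame), or uniformly inside the volume and
#' immobile for \code{"static"} (DNA-bound molecules).
#'
#' Cell-frame coordinates are (a, b, c): a along the long axis (centered at
#' 0), b along the in-plane short axis, c out of plane. All emitters start
#' in the bright state.
#'
#' @param cell a \code{\link{CellGeometry}}.
#' @param mode one of "membrane", "cytosolic", "static".
#' @param n number of emitters (>= 0).
#' @param channel channel label attached to the emitters.
#' @return a data.frame with columns a, b, c (um), mode, state, channel.
#' @export
seedEmitters <- function(cell, mode = c("membrane", "cytosolic", "static"),
                         n, channel = "A") {
  mode <- match.arg(mode)
  stopifnot(n >= 0)
  n <- as.integer(n)
  if (n == 0L)
    return(data.frame(a = numeric(0), b = numeric(0), c = numeric(0),
                      mode = character(0), state = character(0),
                      channel = character(0), stringsAsFactors = FALSE))
  r <- cell@width / 2
  h <- cylHalfLength(cell)
  if (mode == "membrane") {
    aCyl <- 4 * pi * r * h        # cylinder area 2*pi*r*(2h)
    aCap <- 4 * pi * r^2          # two hemispherical caps = full sphere
    onCyl <- stats::runif(n) < aCyl / (aCyl + aCap)
    a <- b <- cc <- numeric(n)
    nc <- sum(onCyl)
    if (nc > 0) {
      phi <- stats::runif(nc, 0, 2 * pi)
      a[onCyl] <- stats::runif(nc, -h, h)
      b[onCyl] <- r * cos(phi)
      cc[onCyl] <- r * sin(phi)
    }
    ns <- n - nc
    if (ns > 0) {
      # uniform on the sphere, split onto the two caps by axial sign
      g <- matrix(stats::rnorm(3 * ns), ncol = 3)
      g <- g / sqrt(rowSums(g^2))
      a[!onCyl] <- sign(g[, 1]) * h + r * g[, 1]
      b[!onCyl] <- r * g[, 2]
      cc[!onCyl] <- r * g[, 3]
    }
  } else {
    # rejection sampling in the bounding box; acceptance ~ pi/4 * V ratio
    a <- b <- cc <- numeric(0)
    while (length(a) < n) {
      m <- max(2L * (n - length(a)), 16L)
      ca <- stats::runif(m, -cell@length / 2, cell@length / 2)
      cb <- stats::runif(m, -r, r)
      ccc <- stats::runif(m, -r, r)
      keep <- insideSpherocylinder(ca, cb, ccc, cell)
      a <- c(a, ca[keep]); b <- c(b, cb[keep]); cc <- c(cc, ccc[keep])
    }
    a <- a[seq_len(n)]; b <- b[seq_len(n)]; cc <- cc[seq_len(n)]
  }
  data.frame(a = a, b = b, c = cc, mode = mode, state = "bright",
             channel = channel, stringsAsFactors = FALSE)
}

# Cell-frame (a, b) to image-frame (x, y) in micrometers.
cellToImage <- function(cell, a, b) {
  ax <- cellAxes(cell)
  list(x = cell@center[1] + a * ax$u[1] + b * ax$v[1],
       y = cell@center[2] + a * ax$u[2] + b * ax$v[2])
}

# Image-frame (x, y) to cell-frame (a, b).
imageToCell <- function(cell, x, y) {
  ax <- cellAxes(cell)
  dx <- x - cell@center[1]; dy <- y - cell@center[2]
  list(a = dx * ax$u[1] + dy * ax$u[2],
       b = dx * ax$v[1] + dy * ax$v[2])
}

# TRUE for image-frame points inside the projected footprint (rectangle
# (L - w) x w capped by two semicircles of radius w/2), with tolerance in um.
insideFootprint <- function(cell, x, y, tol = 0) {
  cf <- imageToCell(cell, x, y)
  h <- cylHalfLength(cell)
  r <- cell@width / 2 + tol
  ax <- pmax(abs(cf$a) - h, 0)
  ax^2 + cf$b^2 <= r^2
}

# Analytic projected footprint area (um^2).
footprintArea <- function(cell) {
  w <- cell@width
  (cell@length - w) * w + pi * (w / 2)^2
}

#' Binary mask of one or more cells
#'
#' Rasterizes the projected spherocylinder footprint(s) onto the acquisition
#' pixel grid: a pixel is inside when its center falls within the footprint.
#' Stands in for bright-field segmentation of real data. The mask of several
#' cells is the union of the single-cell masks.
#'
#' @param cells a \code{\link{CellGeometry}} or list of them.
#' @param acq an \code{\link{Acquisition}} (supplies grid and pixel size).
#' @return a logical matrix of dimension \code{acq@dim}.
#' @export
makeMask <- function(cells, acq) {
  if (is(cells, "CellGeometry")) cells <- list(cells)
  d <- acq@dim; ps <- acq@pixelSize
  xs <- (seq_len(d[2]) - 0.5) * ps
  ys <- (seq_len(d[1]) - 0.5) * ps
  xg <- matrix(xs, nrow = d[1], ncol = d[2], byrow = TRUE)
  yg <- matrix(ys, nrow = d[1], ncol = d[2])
  mask <- matrix(FALSE, d[1], d[2])
  for (cell in cells)
    mask <- mask | matrix(insideFootprint(cell, as.vector(xg), as.vector(yg)),
                          d[1], d[2])
  mask
}

# Binary dilation of a logical mask by a disk of the given radius (px).
dilateMask <- function(mask, radius) {
  r <- as.integer(radius)
  idx <- -r:r
  brush <- outer(idx^2, idx^2, "+") <= r^2
  out <- EBImage::dilate(EBImage::Image(mask * 1), brush * 1)
  EBImage::imageData(out) > 0.5
}

#' Spherocylinder volume from length and width
#'
#' V = pi (w/2)^2 (L - w) + (4/3) pi (w/2)^3, in femtoliters when L and w
#' are in micrometers (1 um^3 = 1 fL).
#'
#' @param length pole-to-pole length L (um).
#' @param width cell diameter w (um).
#' @return volume in fL.
#' @export
spherocylinderVolume <- function(length, width) {
  r <- width / 2
  pi * r^2 * (length - width) + (4 / 3) * pi * r^3
}
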