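# Super-resolution rendering, normalized cell coordinates, location maps.

# Render unit-volume Gaussians at (x, y) um with per-spot sds (um) onto a
# canvas; each spot is integrated exactly over the pixels so the discrete
# sum of one fully contained spot is 1.
renderGaussians <- function(x, y, sdx, sdy, dim, pixelSize) {
  img <- matrix(0, dim[1], dim[2])
  xe <- (0:dim[2]) * pixelSize
  ye <- (0:dim[1]) * pixelSize
  for (i in seq_along(x)) {
    px <- diff(stats::pnorm(xe, mean = x[i], sd = sdx[i]))
    py <- diff(stats::pnorm(ye, mean = y[i], sd = sdy[i]))
    img <- img + py %o% px
  }
  img
}

#' Super-resolution reconstruction from fitted foci
#'
#' Draws every focus as a unit-volume elliptical Gaussian
#' \code{f(x, y) = 1 / (2 pi sigma_x sigma_y) exp(-(x^2 / 2 sigma_x^2 +
#' y^2 / 2 sigma_y^2))} centered at its fitted position, with widths equal
#' to the localization uncertainties sigma_x, sigma_y of the fit: every
#' molecule contributes the same total mass while better-localized
#' molecules appear sharper. The discrete image sum therefore equals the
#' number of foci regardless of the rendering pixel size.
#'
#' @param foci data.frame with x, y, sigma_x, sigma_y (um).
#' @param pixelSize rendering pixel size (um), typically much finer than
#'   the camera pixel.
#' @param dim canvas size (rows, cols) in rendering pixels.
#' @return a numeric matrix.
#' @export
renderSuperres <- function(foci, pixelSize, dim) {
  if (nrow(foci) == 0L) return(matrix(0, dim[1], dim[2]))
  renderGaussians(foci$x, foci$y, foci$sigma_x, foci$sigma_y, dim, pixelSize)
}

#' Normalized cell coordinates of a focus
#'
#' Maps image positions (um) into the frame of their cell: \code{l} along
#' the long axis and \code{s} across the short axis, both normalized to
#' [-1/2, 1/2] in units of cell length and width. Positions outside the
#' cell footprint (beyond a tolerance) map to NA.
#'
#' @param x,y image coordinates (um), vectors of equal length.
#' @param cell the \code{\link{CellGeometry}}.
#' @param tol footprint tolerance in um (default 0.1, about one pixel).
#' @return data.frame with columns l and s (NA for excluded foci).
#' @export
cellCoordinates <- function(x, y, cell, tol = 0.1) {
  cf <- imageToCell(cell, x, y)
  inside <- insideFootprint(cell, x, y, tol = tol)
  l <- ifelse(inside, cf$a / cell@length, NA_real_)
  s <- ifelse(inside, cf$b / cell@width, NA_real_)
  data.frame(l = l, s = s)
}

# Inverse of cellCoordinates for points known to belong to the cell.
cellCoordinatesInverse <- function(l, s, cell) {
  cellToImage(cell, l * cell@length, s * cell@width)
}

#' Location map of foci on a standard cell
#'
#' Re-projects the normalized (l, s) coordinates of all foci from all cells
#' onto one cell of standard length and width, renders each as a
#' unit-volume Gaussian spot and divides the image by the number of cells
#' analyzed, giving the mean per-cell spatial density of foci.
#'
#' @param ls data.frame with columns l and s (\code{\link{cellCoordinates}};
#'   NA rows are dropped).
#' @param standardCell a \code{\link{CellGeometry}} of average size.
#' @param nCells number of cells analyzed (>= 1).
#' @param pixelSize rendering pixel size (um, default 0.02).
#' @param spotSigma rendering spot sigma (um, default 0.05).
#' @param margin canvas margin around the cell (um, default 0.2).
#' @return list with \code{image} and the canvas \code{extent} (um offsets
#'   of the canvas origin relative to the cell center).
#' @export
locationMap <- function(ls, standardCell, nCells, pixelSize = 0.02,
                        spotSigma = 0.05, margin = 0.2) {
  stopifnot(nCells >= 1)
  ls <- ls[stats::complete.cases(ls), , drop = FALSE]
  L <- standardCell@length; w <- standardCell@width
  # canvas in the cell frame: long axis vertical
  wUm <- w + 2 * margin; hUm <- L + 2 * margin
  dim <- c(ceiling(hUm / pixelSize), ceiling(wUm / pixelSize))
  x <- ls$s * w + wUm / 2
  y <- ls$l * L + hUm / 2
  img <- renderGaussians(x, y, rep(spotSigma, length(x)),
                         rep(spotSigma, length(x)), dim, pixelSize) / nCells
  list(image = img, extent = c(-wUm / 2, -hUm / 2))
}
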