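# Image conditioning: flat-field estimation/correction, discoidal peak
# filter, average projections.

# Reflect-pad a matrix by `pad` pixels on every side.
reflectPad <- function(img, pad) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- min(pad, nr - 1L, nc - 1L)
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  img[ri, ci, drop = FALSE]
}

# Convolve with reflect-padding via EBImage::filter2 (FFT-based).
convolveReflect <- function(img, kernel) {
  pad <- max(dim(kernel)) %/% 2 + 1L
  padded <- reflectPad(img, pad)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  pad <- (nrow(padded) - nrow(img)) %/% 2L
  out[pad + seq_len(nrow(img)), pad + seq_len(ncol(img)), drop = FALSE]
}

#' Estimate the illumination profile from movies
#'
#' Averages every frame of every movie, smooths the mean image by Gaussian
#' blurring (default radius 10 px) and normalizes it as a fraction of the
#' brightest pixel, producing the "beam" profile used for flat-fielding.
#' A constant camera offset can be subtracted before normalization so the
#' profile reflects illumination rather than the detector baseline.
#'
#' @param movies a list of \code{\link{ImageStack}} objects (or 3D arrays),
#'   or a single one.
#' @param blurRadius Gaussian blur sigma in pixels (default 10).
#' @param offset camera baseline to subtract (counts, default 0).
#' @return a matrix with values in (0, 1] and maximum 1.
#' @export
estimateIllumination <- function(movies, blurRadius = 10, offset = 0) {
  if (is(movies, "ImageStack") || is.array(movies)) movies <- list(movies)
  if (length(movies) == 0L) stop("need at least one movie")
  acc <- NULL; n <- 0
  for (m in movies) {
    a <- if (is(m, "ImageStack")) frames(m) else m
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    s <- rowSums(a, dims = 2L)
    acc <- if (is.null(acc)) s else acc + s
    n <- n + dim(a)[3L]
  }
  mean_img <- acc / n - offset
  blurred <- EBImage::gblur(reflectPad(mean_img, ceiling(2 * blurRadius)),
                            sigma = blurRadius)
  pad <- (nrow(blurred) - nrow(mean_img)) %/% 2L
  blurred <- blurred[pad + seq_len(nrow(mean_img)),
                     pad + seq_len(ncol(mean_img)), drop = FALSE]
  blurred <- pmax(blurred, max(blurred) * 1e-6)
  blurred / max(blurred)
}

#' Flat-field correction
#'
#' Divides an image (or every frame of a stack) pixel-wise by the
#' illumination profile.
#'
#' @param image a matrix, 3D array or \code{\link{ImageStack}}.
#' @param profile illumination profile with strictly positive values.
#' @return the corrected object, same class as the input.
#' @export
flatten <- function(image, profile) {
  if (any(profile <= 0)) stop("illumination profile must be positive")
  if (is(image, "ImageStack")) {
    a <- frames(image)
    stopifnot(identical(dim(a)[1:2], dim(profile)))
    out <- sweep(a, 1:2, profile, "/")
    return(ImageStack(out, pixelSize(image), frameInterval(image)))
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    stopifnot(identical(dim(image)[1:2], dim(profile)))
    return(sweep(image, 1:2, profile, "/"))
  }
  stopifnot(identical(dim(image), dim(profile)))
  image / profile
}

# Disk-mean minus annulus-mean kernel of the discoidal filter.
discoidalKernel <- function(rInner, rOuter) {
  r <- ceiling(rOuter)
  idx <- -r:r
  d <- sqrt(outer(idx^2, idx^2, "+"))
  disk <- d <= rInner
  ann <- d > rInner & d <= rOuter
  disk / sum(disk) - ann / sum(ann)
}

#' Discoidal averaging (peak-enhancing) filter
#'
#' Replaces each pixel by the mean over a disk of radius \code{rInner}
#' minus the mean over the surrounding annulus \code{(rInner, rOuter]},
#' then clips negative values to zero. Flat backgrounds and slow gradients
#' map to ~0 while diffraction-limited peaks are preserved, which makes the
#' filter the standard preprocessing step before peak detection and
#' correlation analysis. Boundaries are handled by reflection.
#'
#' @param image a matrix, 3D array or \code{\link{ImageStack}}.
#' @param rInner,rOuter disk and annulus radii in pixels (defaults 1 and
#'   3, tight enough that defocused out-of-plane signal is rejected),
#'   0 < rInner < rOuter.
#' @return the filtered object, same class as the input.
#' @export
discoidalFilter <- function(image, rInner = 1, rOuter = 3) {
  stopifnot(rInner > 0, rInner < rOuter)
  kern <- discoidalKernel(rInner, rOuter)
  one <- function(m) pmax(convolveReflect(m, kern), 0)
  if (is(image, "ImageStack")) {
    a <- frames(image)
    for (t in seq_len(dim(a)[3L])) a[, , t] <- one(a[, , t])
    return(ImageStack(a, pixelSize(image), frameInterval(image)))
  }
  if (is.array(image) && length(dim(image)) == 3L) {
    for (t in seq_len(dim(image)[3L])) image[, , t] <- one(image[, , t])
    return(image)
  }
  one(image)
}

#' Temporal average projection of a movie
#'
#' Per-pixel mean over frames. Average projections highlight static foci
#' while blurring mobile molecules into the diffuse cellular background.
#'
#' @param movie an \code{\link{ImageStack}} or 3D array.
#' @return a matrix.
#' @export
averageProjection <- function(movie) {
  a <- if (is(movie, "ImageStack")) frames(movie) else movie
  if (is.matrix(a)) return(a)
  rowMeans(a, dims = 2L)
}
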