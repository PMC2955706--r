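#' Read a grayscale micrograph as a cell image
#'
#' Thin wrapper over `EBImage::readImage()` for PNG/TIFF input; colour
#' images are collapsed to grayscale by channel averaging.
#'
#' @param path Image file path (PNG or TIFF).
#' @param pixel_size Pixel edge length (um per pixel).
#' @return A `cell_image` (see [generate_cell_image()]), without ground
#'   truth.
#' @export
read_cell_image <- function(path, pixel_size) {
  stopifnot(pixel_size > 0)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  structure(list(pixels = px, pixel_size = pixel_size,
                 ground_truth = NULL),
            class = "cell_image")
}

#' Binarise a cell image
#'
#' Thresholds the raster (Otsu's method by default, or a fixed intensity),
#' fills holes and keeps only the largest connected component — the cell.
#' Mirrors the contour-recognition step of threshold-based micrograph
#' digitisation.
#'
#' @param image A `cell_image`.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @return A binary matrix (0/1) of the same dimensions.
#' @export
binarize <- function(image, threshold = "otsu") {
  stopifnot(inherits(image, "cell_image"))
  px <- image$pixels
  if (identical(threshold, "otsu")) {
    rng <- range(px)
    if (diff(rng) <= 0)
      stop("no cell detected: image has no contrast", call. = FALSE)
    norm <- (px - rng[1L]) / diff(rng)
    thr_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- rng[1L] + thr_norm * diff(rng)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
  }
  mask <- px > thr
  if (!any(mask))
    stop("no cell detected: empty foreground after thresholding",
         call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::fillHull(lab)
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(counts)
  out <- (EBImage::imageData(lab) == keep) * 1
  matrix(out, nrow = nrow(px), ncol = ncol(px))
}

#' Extract the cell contour geometry from a binary mask
#'
#' Computes the cross-sectional area, the principal axes via second
#' moments of the foreground pixels, and the half-width profile of the
#' cross section measured perpendicular to the long axis at pixel-spaced
#' positions along it. For a solid ellipse the standard deviation of the
#' pixel coordinates along a principal axis is half the semi-axis, which
#' fixes the moment-to-length conversion.
#'
#' @param mask Binary matrix from [binarize()] (exactly one foreground
#'   component).
#' @param pixel_size Pixel edge length (um per pixel).
#' @return An object of class `contour_result`: a list with `mask`,
#'   `area` (um^2), `long_axis` and `short_axis` (full lengths, um),
#'   `orientation` (radians) and `axis_profile` (data frame:
#'   `position`, `half_width`, both um).
#' @export
extract_contour <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    stop("mask has no foreground", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(EBImage::imageData(lab)) > 1)
    stop("mask must contain exactly one connected component",
         call. = FALSE)
  xy <- (fg - 0.5) * pixel_size  # pixel centres in um
  area <- nrow(fg) * pixel_size^2
  ctr <- colMeans(xy)
  cen <- sweep(xy, 2L, ctr)
  cov_xy <- crossprod(cen) / nrow(cen)
  ev <- eigen(cov_xy, symmetric = TRUE)
  # solid ellipse: variance along a principal axis is (semi-axis)^2 / 4
  long_axis <- 4 * sqrt(ev$values[1L])
  short_axis <- 4 * sqrt(ev$values[2L])
  orientation <- atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L])
  # half-width profile along the long axis
  u <- cen %*% ev$vectors[, 1L]
  breaks <- seq(min(u) - pixel_size / 2, max(u) + pixel_size,
                by = pixel_size)
  bin <- findInterval(u, breaks)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  pos <- breaks[-length(breaks)] + pixel_size / 2
  # width of the cross-section slice = slice area / slice thickness
  half_width <- counts * pixel_size^2 / pixel_size / 2
  structure(list(mask = mask, area = area,
                 long_axis = long_axis, short_axis = short_axis,
                 orientation = orientation,
                 axis_profile = data.frame(position = pos,
                                           half_width = half_width)),
            class = "contour_result")
}

#' @export
print.contour_result <- function(x, ...) {
  cat(sprintf(
    "Cell contour: area %.2f um^2, axes %.2f x %.2f um, angle %.2f rad\n",
    x$area, x$long_axis, x$short_axis, x$orientation))
  invisible(x)
}

#' Volume by rotating the cross section about its long axis
#'
#' Disk integration of the half-width profile:
#' \eqn{V = \pi \int h(x)^2 dx} along the long axis, evaluated with the
#' trapezoidal rule at pixel resolution. This realises the axisymmetric
#' volume estimate used for *Chlamydomonas*, whose cells are rotationally
#' symmetric about the long axis.
#'
#' @param contour A [extract_contour()] result.
#' @return Volume in um^3.
#' @export
volume_of_revolution <- function(contour) {
  stopifnot(inherits(contour, "contour_result"))
  prof <- contour$axis_profile
  if (nrow(prof) == 0L || all(prof$half_width <= 0))
    stop("degenerate axis profile: no positive half-widths",
         call. = FALSE)
  h2 <- prof$half_width^2
  x <- prof$position
  pi * sum(diff(x) * (h2[-1L] + h2[-length(h2)]) / 2)
}

#' Prolate-spheroid volume from full axis lengths
#'
#' Closed-form reference for an ellipsoid of revolution about its long
#' axis: `(4/3) * pi * (La/2) * (Lb/2)^2`, with `La` and `Lb` the full
#' long- and short-axis lengths. This is the analytic counterpart of
#' [volume_of_revolution()] for a perfectly elliptical cross section.
#'
#' @param La Full long-axis length (um), `>= Lb`.
#' @param Lb Full short-axis length (um), positive.
#' @return Volume in um^3.
#' @examples
#' spheroid_volume(6, 4)  # 16 * pi
#' @export
spheroid_volume <- function(La, Lb) {
  stopifnot(is.numeric(La), is.numeric(Lb))
  if (any(Lb <= 0)) stop("Lb must be positive", call. = FALSE)
  if (any(Lb > La))
    stop("Lb must not exceed La (La is the long axis)", call. = FALSE)
  (4 / 3) * pi * (La / 2) * (Lb / 2)^2
}

#' Measure the volume of one imaged cell
#'
#' End-to-end volumetry: binarise, extract the contour, and integrate the
#' solid of revolution. Also reports the spheroid closed form from the
#' measured axes.
#'
#' @param image A `cell_image`.
#' @param threshold Passed to [binarize()].
#' @return A one-row data frame: `area_um2`, `La_um`, `Lb_um`,
#'   `volume_um3` (disk integration), `volume_spheroid_um3`.
#' @export
measure_cell_volume <- function(image, threshold = "otsu") {
  mask <- binarize(image, threshold)
  contour <- extract_contour(mask, image$pixel_size)
  data.frame(area_um2 = contour$area,
             La_um = contour$long_axis,
             Lb_um = contour$short_axis,
             volume_um3 = volume_of_revolution(contour),
             volume_spheroid_um3 = spheroid_volume(contour$long_axis,
                                                   contour$short_axis))
}
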