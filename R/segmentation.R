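#' Build the cortical mask from traced contours
#'
#' Marks every pixel whose centre lies inside the periosteal polygon and
#' outside all endosteal polygons. Boundary pixels follow a half-open
#' convention (counted inside the periosteal polygon, outside endosteal
#' polygons) so abutting regions never double-count. Cortical area Ct.Ar is
#' the masked pixel count times the pixel area.
#'
#' @param contours A [contour_set()].
#' @param shape Image dimensions `c(nrow, ncol)`.
#' @param pixel_spacing_um Pixel edge length in micrometres.
#' @return An object of class `cortical_mask`: list with `mask` (logical
#'   matrix), `area_mm2` (Ct.Ar), `centroid` (x, y pixel coordinates of the
#'   mask centre of mass) and `pixel_spacing_um`.
#' @export
cortical_mask <- function(contours, shape, pixel_spacing_um) {
  stopifnot(inherits(contours, "contour_set"), length(shape) == 2L,
            pixel_spacing_um > 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  peri <- contours$periosteal
  if (min(peri[, 1]) < -0.5 || max(peri[, 1]) > nc - 0.5 ||
      min(peri[, 2]) < -0.5 || max(peri[, 2]) > nr - 0.5) {
    stop("periosteal polygon extends outside the image bounds")
  }
  # restrict evaluation to the polygon's bounding box
  c0 <- max(1L, floor(min(peri[, 1])) + 1L)
  c1 <- min(nc, ceiling(max(peri[, 1])) + 1L)
  r0 <- max(1L, floor(min(peri[, 2])) + 1L)
  r1 <- min(nr, ceiling(max(peri[, 2])) + 1L)
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 1L, each = length(rows))
  py <- rep(rows - 1L, times = length(cols))
  inside <- .point_in_polygon(px, py, peri, boundary = "inside")
  for (e in contours$endosteal) {
    inside <- inside & !.point_in_polygon(px, py, e, boundary = "outside")
  }
  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  npx <- sum(mask)
  if (npx == 0L) stop("cortical mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  structure(
    list(
      mask = mask,
      area_mm2 = npx * (pixel_spacing_um / 1e3)^2,
      centroid = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
      pixel_spacing_um = pixel_spacing_um
    ),
    class = "cortical_mask"
  )
}

#' @export
print.cortical_mask <- function(x, ...) {
  cat(sprintf("<cortical_mask> %d px, Ct.Ar = %.3f mm2, centroid (%.1f, %.1f)\n",
              sum(x$mask), x$area_mm2, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Intensity histogram of an image, optionally restricted to a mask
#'
#' @param img A [microradiograph()] or an integer matrix in `[0, 255]`.
#' @param mask Optional logical matrix (or [cortical_mask()]) selecting the
#'   pixels to count.
#' @return Integer vector of 256 counts for bins 0..255.
#' @export
intensity_histogram <- function(img, mask = NULL) {
  px <- if (inherits(img, "microradiograph")) img$pixels else img
  if (inherits(mask, "cortical_mask")) mask <- mask$mask
  v <- if (is.null(mask)) as.vector(px) else px[mask]
  tabulate(v + 1L, nbins = 256L)
}

#' Triangle-method automatic threshold
#'
#' Implements the Zack geometric construction on a 256-bin histogram: both
#' axes are normalised to `[0, 1]`, a line is drawn from the histogram peak to
#' the farthest nonzero bin on the longer-tail side, and the threshold is the
#' bin whose histogram point lies at maximum perpendicular distance below that
#' line. Ties are broken toward the peak. A histogram with a single nonzero
#' bin returns that bin.
#'
#' @param histogram Integer vector of 256 counts (bins 0..255).
#' @return Integer threshold level in `[0, 255]`.
#' @export
triangle_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0)) {
    stop("`histogram` must be 256 non-negative counts")
  }
  nz <- which(histogram > 0)
  if (length(nz) == 0L) stop("histogram is empty")
  if (length(nz) == 1L) return(nz - 1L)
  peak <- which.max(histogram)
  lo <- nz[1]; hi <- nz[length(nz)]
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (end == peak) return(peak - 1L)
  cand <- if (end > peak) peak:end else end:peak
  x <- (cand - 1) / 255
  y <- histogram[cand] / max(histogram)
  x1 <- (peak - 1) / 255; y1 <- 1
  x2 <- (end - 1) / 255; y2 <- histogram[end] / max(histogram)
  d <- abs((x2 - x1) * (y1 - y) - (x1 - x) * (y2 - y1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  best <- cand[d >= max(d) - 1e-12]
  as.integer(best[which.min(abs(best - peak))] - 1L)
}

#' Threshold a section and report the histogram used
#'
#' Computes the triangle threshold either from the cortical-region histogram
#' (default, so empty background does not dominate) or from the full frame
#' (for replicating analyses that thresholded whole images).
#'
#' @param img A [microradiograph()].
#' @param mask A [cortical_mask()].
#' @param mode `"roi"` (histogram over masked pixels) or `"full"` (whole
#'   frame).
#' @param side Which side of the level holds pores: `"pores_below"`
#'   (radiolucent pores rendered dark; default) or `"pores_above"`.
#' @return List with `level`, `histogram` and `side` (class
#'   `threshold_result`).
#' @export
threshold_section <- function(img, mask, mode = c("roi", "full"),
                              side = c("pores_below", "pores_above")) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  h <- intensity_histogram(img, if (mode == "roi") mask else NULL)
  structure(list(level = triangle_threshold(h), histogram = h, side = side,
                 mode = mode),
            class = "threshold_result")
}

#' Binarise pore versus bone phases within the cortical mask
#'
#' A pixel is assigned to the pore phase iff it lies in the cortical mask and
#' its intensity is strictly beyond the threshold level on the stated pore
#' side. Pixels outside the mask are always bone-phase `FALSE`, so within the
#' mask the pore and bone phases partition the masked pixels.
#'
#' @param img A [microradiograph()].
#' @param mask A [cortical_mask()] (or logical matrix).
#' @param level Integer threshold level in `[0, 255]`, or a
#'   `threshold_result` from [threshold_section()].
#' @param side `"pores_below"` or `"pores_above"`; ignored when `level` is a
#'   `threshold_result`, which carries its own side.
#' @return Logical matrix, `TRUE` for pore-phase pixels.
#' @export
binarize_pores <- function(img, mask, level,
                           side = c("pores_below", "pores_above")) {
  if (inherits(level, "threshold_result")) {
    side <- level$side
    level <- level$level
  } else {
    side <- match.arg(side)
  }
  stopifnot(level >= 0, level <= 255)
  px <- if (inherits(img, "microradiograph")) img$pixels else img
  m <- if (inherits(mask, "cortical_mask")) mask$mask else mask
  pore <- if (side == "pores_below") px < level else px > level
  pore & m
}
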