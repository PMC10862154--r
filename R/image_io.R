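#' Construct a microradiograph object
#'
#' A microradiograph is an 8-bit greyscale raster with a physical pixel
#' spacing and optional specimen metadata. Mineralised matrix is radiopaque
#' (bright); pores are radiolucent (dark) under the default rendering.
#'
#' @param pixels Integer matrix of intensities in `[0, 255]`; rows run down
#'   the image (y), columns run rightward (x).
#' @param pixel_spacing_um Length of one pixel edge in micrometres (> 0).
#' @param site Sampling site, one of `"rib"`, `"tibia"`, `"mc_diaphysis"`,
#'   `"mc_metaphysis"`, or `NA`.
#' @param subject_id Specimen identifier.
#' @param group Exercise group, `"exercised"`, `"rested"`, or `NA`.
#' @return An object of class `microradiograph`.
#' @export
microradiograph <- function(pixels, pixel_spacing_um, site = NA_character_,
                            subject_id = NA_character_, group = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty matrix")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop("intensities must lie in [0, 255]")
  }
  if (!is.numeric(pixel_spacing_um) || length(pixel_spacing_um) != 1L ||
      is.na(pixel_spacing_um) || pixel_spacing_um <= 0) {
    stop("`pixel_spacing_um` must be a single positive number")
  }
  if (!is.na(site)) {
    site <- match.arg(site, c("rib", "tibia", "mc_diaphysis", "mc_metaphysis"))
  }
  if (!is.na(group)) group <- match.arg(group, c("exercised", "rested"))
  structure(
    list(pixels = pixels, pixel_spacing_um = as.numeric(pixel_spacing_um),
         site = site, subject_id = subject_id, group = group),
    class = "microradiograph"
  )
}

#' @export
print.microradiograph <- function(x, ...) {
  cat(sprintf(
    "<microradiograph> %d x %d px, %.1f um/px (%.2f x %.2f mm)\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_spacing_um,
    nrow(x$pixels) * x$pixel_spacing_um / 1e3,
    ncol(x$pixels) * x$pixel_spacing_um / 1e3
  ))
  cat(sprintf("  subject: %s  group: %s  site: %s\n",
              x$subject_id, x$group, x$site))
  invisible(x)
}

#' Read a microradiograph from an 8-bit greyscale TIFF
#'
#' Reads a single-plane 8-bit TIFF without any intensity rescaling and
#' attaches the stated physical pixel spacing. 16-bit input is rejected
#' unless `convert_16bit = TRUE`, in which case it is first reduced with
#' [convert_16bit_to_8bit()].
#'
#' @param path Path to the TIFF file.
#' @param pixel_spacing_um Pixel edge length in micrometres.
#' @param convert_16bit Convert 16-bit input by global min-max rescaling
#'   instead of raising an error.
#' @inheritParams microradiograph
#' @return A [microradiograph()] object.
#' @export
load_microradiograph <- function(path, pixel_spacing_um,
                                 site = NA_character_,
                                 subject_id = NA_character_,
                                 group = NA_character_,
                                 convert_16bit = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(raw)) != 2L) {
    stop("expected a single-channel greyscale TIFF: ", path)
  }
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (bits == 8L) {
    px <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  } else if (bits == 16L) {
    if (!convert_16bit) {
      stop("16-bit TIFF: pass convert_16bit = TRUE to rescale to 8-bit")
    }
    px <- convert_16bit_to_8bit(matrix(as.integer(round(raw * 65535)),
                                       nrow(raw), ncol(raw)))
  } else {
    stop("unsupported bit depth: ", bits)
  }
  microradiograph(px, pixel_spacing_um, site = site,
                  subject_id = subject_id, group = group)
}

#' Write a microradiograph as an 8-bit greyscale TIFF
#'
#' The written file round-trips pixel-identically through
#' [load_microradiograph()].
#'
#' @param img A [microradiograph()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_microradiograph <- function(img, path) {
  stopifnot(inherits(img, "microradiograph"))
  tiff::writeTIFF(img$pixels / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  invisible(path)
}

#' Reduce a 16-bit image to 8 bits by global min-max rescaling
#'
#' Applies a linear min-max rescale to `[0, 255]` with round-half-up, the
#' deterministic, order-preserving reduction used before analysis. A constant
#' image (zero dynamic range) maps to all zeros.
#'
#' @param pixels16 Non-empty numeric matrix of 16-bit intensities.
#' @return Integer matrix with values in `[0, 255]`.
#' @export
convert_16bit_to_8bit <- function(pixels16) {
  if (!is.matrix(pixels16) || length(pixels16) == 0L) {
    stop("`pixels16` must be a non-empty matrix")
  }
  lo <- min(pixels16); hi <- max(pixels16)
  if (hi == lo) {
    out <- matrix(0L, nrow(pixels16), ncol(pixels16))
    return(out)
  }
  scaled <- (pixels16 - lo) / (hi - lo) * 255
  out <- matrix(as.integer(floor(scaled + 0.5)), nrow(pixels16), ncol(pixels16))
  out
}

#' Construct a validated contour set
#'
#' A contour set holds the manually traced periosteal boundary and zero or
#' more endosteal (medullary) boundaries of one section, as closed simple
#' polygons in pixel coordinates (origin top-left, x rightward, y downward).
#' Every endosteal polygon must lie strictly inside the periosteal polygon.
#'
#' @param periosteal Two-column matrix of vertices (x, y).
#' @param endosteal List of two-column vertex matrices (possibly empty).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(periosteal, endosteal = list()) {
  periosteal <- .as_vertex_matrix(periosteal, "periosteal")
  if (is.matrix(endosteal)) endosteal <- list(endosteal)
  endosteal <- lapply(seq_along(endosteal), function(i) {
    .as_vertex_matrix(endosteal[[i]], paste0("endosteal[", i, "]"))
  })
  if (!.is_simple_polygon(periosteal)) {
    stop("periosteal polygon is self-intersecting or degenerate")
  }
  for (i in seq_along(endosteal)) {
    e <- endosteal[[i]]
    if (!.is_simple_polygon(e)) {
      stop("endosteal polygon ", i, " is self-intersecting or degenerate")
    }
    inside <- .strictly_inside(e[, 1], e[, 2], periosteal)
    if (!all(inside) || .polygons_cross(e, periosteal)) {
      stop("endosteal polygon ", i,
           " is not strictly inside the periosteal polygon")
    }
  }
  structure(list(periosteal = periosteal, endosteal = endosteal),
            class = "contour_set")
}

.as_vertex_matrix <- function(v, what) {
  if (is.list(v) && !is.data.frame(v) && !is.matrix(v)) {
    v <- do.call(rbind, lapply(v, as.numeric))
  }
  v <- as.matrix(v)
  if (ncol(v) != 2L || nrow(v) < 3L || anyNA(v)) {
    stop(what, " must be a matrix of >= 3 (x, y) vertices")
  }
  # drop an explicit closing vertex; polygons are implicitly closed
  n <- nrow(v)
  if (all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> periosteal: %d vertices; %d endosteal polygon(s)\n",
              nrow(x$periosteal), length(x$endosteal)))
  invisible(x)
}

#' Read a contour set from a JSON file
#'
#' The file dialect is a JSON object
#' `{"periosteal": [[x, y], ...], "endosteal": [[[x, y], ...], ...]}` with
#' vertices in pixel coordinates. The manual tracing the contours represent
#' was interactive and left no standard on-disk format, so this plain-text
#' dialect is the package's own.
#'
#' @param path Path to the JSON contour file.
#' @return A validated [contour_set()].
#' @export
load_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$periosteal)) stop("contour file lacks a 'periosteal' polygon")
  endo <- obj$endosteal
  if (is.null(endo)) endo <- list()
  # equal-length polygons may come back as one 3-D array
  if (is.array(endo) && length(dim(endo)) == 3L) {
    endo <- lapply(seq_len(dim(endo)[1]), function(i) endo[i, , ])
  }
  if (is.matrix(endo)) endo <- list(endo)
  contour_set(obj$periosteal, endo)
}

#' Write a contour set to a JSON file
#'
#' @param contours A [contour_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  obj <- list(
    periosteal = unname(contours$periosteal),
    endosteal = lapply(contours$endosteal, unname)
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a study metadata table
#'
#' One row per section with columns `subject_id`, `group`, `site`,
#' `image_path`, `roi_path`, `pixel_spacing_um`. Relative image/ROI paths are
#' resolved against the metadata file's directory.
#'
#' @param path Path to the CSV file.
#' @return A data frame with resolved paths.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "site", "image_path", "roi_path",
            "pixel_spacing_um")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("metadata table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(md) == 0L) stop("metadata table is empty")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  md$image_path <- resolve(md$image_path)
  md$roi_path <- resolve(md$roi_path)
  md
}
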