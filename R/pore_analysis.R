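# Particle analysis of the binary pore phase: 8-connected component
# labelling, per-pore measurement (area, boundary-chain perimeter,
# circularity, Feret width), retention filters and remodelling-stage
# classification.

# ---- labelling ------------------------------------------------------------

# Build the pixel-adjacency graph of TRUE pixels and take its connected
# components. Returns a list of integer vectors of linear (column-major)
# pixel indices with attribute "dim".
.label_components <- function(grid, connectivity = 8L) {
  nr <- nrow(grid); nc <- ncol(grid)
  idx <- which(grid)
  if (length(idx) == 0L) return(structure(list(), image_dim = dim(grid)))
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  e1 <- integer(0); e2 <- integer(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
    r2 <- r1 + abs(dr); c2 <- c1 + abs(dc)
    if (dc < 0) { tmp <- c1; c1 <- c2; c2 <- tmp }   # down-left pairing
    if (!length(r1) || !length(c1)) next
    both <- grid[r1, c1, drop = FALSE] & grid[r2, c2, drop = FALSE]
    w <- which(both)
    if (!length(w)) next
    i <- (w - 1L) %% length(r1) + 1L
    j <- (w - 1L) %/% length(r1) + 1L
    e1 <- c(e1, r1[i] + (c1[j] - 1L) * nr)
    e2 <- c(e2, r2[i] + (c2[j] - 1L) * nr)
  }
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(e1)) {
    g <- igraph::add_edges(g, rbind(vid[e1], vid[e2]))
  }
  memb <- igraph::components(g)$membership
  comps <- unname(split(idx, memb))
  # deterministic ordering by raster (row-major) position of the
  # topmost-leftmost pixel of each component
  key <- vapply(comps, function(v) {
    min(((v - 1L) %% nr) * nc + (v - 1L) %/% nr)
  }, numeric(1))
  comps <- comps[order(key)]
  comps <- lapply(comps, function(v) {
    v <- sort(v)
    attr(v, "image_dim") <- c(nr, nc)
    v
  })
  structure(comps, image_dim = c(nr, nc))
}

#' Label individual pores in a binary phase image
#'
#' Finds connected components of pore-phase pixels under 8-connectivity (the
#' behaviour of standard particle-analysis tools: diagonal contact joins).
#' Components are returned in deterministic raster order of their
#' topmost-leftmost pixel.
#'
#' @param pore_grid Logical matrix, `TRUE` for pore-phase pixels.
#' @param connectivity 8 (default) or 4.
#' @return List of components; each is a sorted integer vector of linear
#'   (column-major) pixel indices carrying an `image_dim` attribute.
#' @export
label_pores <- function(pore_grid, connectivity = 8L) {
  stopifnot(is.matrix(pore_grid), is.logical(pore_grid),
            connectivity %in% c(4L, 8L))
  .label_components(pore_grid, as.integer(connectivity))
}

# ---- boundary tracing -----------------------------------------------------

# Moore neighbourhood in clockwise order (image coordinates, y down),
# starting at W: W NW N NE E SE S SW as (dr, dc).
.moore_dirs <- rbind(
  c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
  c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
)

# Moore-neighbour tracing of the outer boundary of a single filled component
# in a logical matrix padded with a FALSE border. Returns the closed chain of
# boundary pixels (rows, cols) and the chain length in pixel units with
# diagonal steps counting sqrt(2). Termination follows Jacob's criterion:
# stop when the first move of the trace (start pixel, first successor) is
# about to repeat, which closes the tour exactly once even on pixel-thin
# limbs that the chain traverses in both directions.
.boundary_chain <- function(bw) {
  rc <- which(bw, arr.ind = TRUE)
  if (nrow(rc) == 1L) {
    return(list(path = rc, perim_px = 0))
  }
  ord <- order(rc[, 1], rc[, 2])
  s <- rc[ord[1], ]
  p <- s
  bdir <- 1L  # backtrack lies W of the topmost-leftmost start pixel
  path_r <- integer(0); path_c <- integer(0)
  perim <- 0
  first_from <- NULL
  first_to <- NULL
  max_iter <- 8L * nrow(rc) + 8L
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- (bdir + k - 1L) %% 8L + 1L
      q <- p + .moore_dirs[d, ]
      if (bw[q[1], q[2]]) {
        if (!is.null(first_from) &&
            p[1] == first_from[1] && p[2] == first_from[2] &&
            q[1] == first_to[1] && q[2] == first_to[2]) {
          # tour closed: the opening move is about to repeat
          return(list(path = cbind(row = path_r, col = path_c),
                      perim_px = perim))
        }
        if (is.null(first_from)) {
          first_from <- p
          first_to <- q
        }
        path_r <- c(path_r, p[1]); path_c <- c(path_c, p[2])
        diag_step <- all(.moore_dirs[d, ] != 0L)
        perim <- perim + if (diag_step) sqrt(2) else 1
        # new backtrack is the last background neighbour examined
        bprev <- (bdir + k - 2L) %% 8L + 1L
        bpix <- p + .moore_dirs[bprev, ]
        p <- q
        off <- bpix - p
        bdir <- which(.moore_dirs[, 1] == off[1] & .moore_dirs[, 2] == off[2])
        found <- TRUE
        break
      }
    }
    if (!found) break  # no foreground neighbour: isolated pixel
  }
  list(path = cbind(row = path_r, col = path_c), perim_px = perim)
}

# Fill interior holes of a component rendered in a padded logical matrix:
# 4-connected background components not touching the border are holes.
.fill_holes <- function(bw) {
  bg <- .label_components(!bw, 4L)
  nr <- nrow(bw); nc <- ncol(bw)
  border <- c(seq_len(nr), seq_len(nr) + (nc - 1L) * nr,
              (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr)
  for (comp in bg) {
    if (!any(comp %in% border)) bw[comp] <- TRUE
  }
  bw
}

# ---- measurement ----------------------------------------------------------

#' Measure one pore component
#'
#' Interior holes are filled before measurement, so a canal with a central
#' bone island counts its full lumen. Area is the filled pixel count times
#' the pixel area; perimeter is the 8-connected boundary chain length with
#' edge steps of one pixel spacing and diagonal steps of spacing times
#' sqrt(2); circularity is `4*pi*A/P^2` clipped to 1 (digitisation can push
#' the ratio above 1 for very small particles); the equivalent diameter
#' Ca.Dm is that of a circle of equal area; the maximum Feret width is the
#' largest centre-to-centre distance between boundary pixels. A single-pixel
#' component is assigned the perimeter of its pixel square, `4 * spacing`.
#'
#' @param component Integer vector of linear pixel indices with an
#'   `image_dim` attribute, as produced by [label_pores()].
#' @param pixel_spacing_um Pixel edge length in micrometres.
#' @param dim Image dimensions `c(nrow, ncol)`; defaults to the component's
#'   `image_dim` attribute.
#' @param id Integer identifier stored in the record.
#' @return One-row data frame with columns `id`, `n_px`, `area_mm2`,
#'   `perimeter_um`, `circularity`, `x_px`, `y_px`, `eq_diameter_um`,
#'   `feret_max_um`, `canal_class`, plus a `boundary` list column of global
#'   boundary pixel coordinates (x, y) used by [exclude_endosteal()].
#' @export
measure_pore <- function(component, pixel_spacing_um,
                         dim = attr(component, "image_dim"), id = 1L) {
  stopifnot(length(component) >= 1L, !is.null(dim), pixel_spacing_um > 0)
  nr <- dim[1]
  r <- (component - 1L) %% nr + 1L
  c <- (component - 1L) %/% nr + 1L
  # local frame padded with one background row/column on every side
  r0 <- min(r) - 2L; c0 <- min(c) - 2L
  bw <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
  bw[cbind(r - r0, c - c0)] <- TRUE
  bw <- .fill_holes(bw)
  n_px <- sum(bw)
  s_mm <- pixel_spacing_um / 1e3
  area_mm2 <- n_px * s_mm^2
  rcf <- which(bw, arr.ind = TRUE)
  # global pixel-centre coordinates (origin top-left, 0-based)
  gx <- rcf[, 2] + c0 - 1L
  gy <- rcf[, 1] + r0 - 1L
  if (n_px == 1L) {
    perim_px <- 4
    bx <- gx; by <- gy
  } else {
    tr <- .boundary_chain(bw)
    perim_px <- tr$perim_px
    bx <- tr$path[, 2] + c0 - 1L
    by <- tr$path[, 1] + r0 - 1L
  }
  circ <- min(1, 4 * pi * n_px / perim_px^2)
  bpts <- unique(cbind(x = bx, y = by))
  feret_px <- if (nrow(bpts) == 1L) 1 else {
    hull <- if (nrow(bpts) > 3L) {
      bpts[grDevices::chull(bpts), , drop = FALSE]
    } else bpts
    max(stats::dist(hull))
  }
  rec <- data.frame(
    id = as.integer(id),
    n_px = n_px,
    area_mm2 = area_mm2,
    perimeter_um = perim_px * pixel_spacing_um,
    circularity = circ,
    x_px = mean(gx),
    y_px = mean(gy),
    eq_diameter_um = 2 * sqrt(area_mm2 / pi) * 1e3,
    feret_max_um = feret_px * pixel_spacing_um,
    canal_class = as.character(classify_canal(area_mm2)),
    stringsAsFactors = FALSE
  )
  rec$boundary <- list(bpts)
  rec
}

#' Measure all labelled pores of a section
#'
#' @param components List of components from [label_pores()].
#' @param pixel_spacing_um Pixel edge length in micrometres.
#' @return Data frame with one [measure_pore()] row per component, ids
#'   numbered in raster order. Zero components give a zero-row frame with the
#'   full column set.
#' @export
measure_pores <- function(components, pixel_spacing_um) {
  if (length(components) == 0L) {
    out <- data.frame(
      id = integer(0), n_px = integer(0), area_mm2 = numeric(0),
      perimeter_um = numeric(0), circularity = numeric(0),
      x_px = numeric(0), y_px = numeric(0), eq_diameter_um = numeric(0),
      feret_max_um = numeric(0), canal_class = character(0),
      stringsAsFactors = FALSE
    )
    out$boundary <- list()
    return(out)
  }
  rows <- lapply(seq_along(components), function(i) {
    measure_pore(components[[i]], pixel_spacing_um, id = i)
  })
  do.call(rbind, rows)
}

# ---- filtering and classification ----------------------------------------

#' Pore retention filter configuration
#'
#' Defaults implement the retention rule used for canal analysis: keep
#' particles with circularity in `[0.3, 1.0]` and area strictly greater than
#' 0.002 mm^2 (particles at or below 0.002 mm^2 are taken to be mature
#' Haversian canals and dropped from canal statistics). Canals above
#' 0.04 mm^2 are cutting cones. Endosteal-margin macro-porosities wider than
#' 600 um whose boundary comes within `endosteal_margin_um` of an endosteal
#' contour are excluded as transition to cancellous bone.
#'
#' @param circ_min,circ_max Circularity retention band.
#' @param area_min_mm2 Strict lower area bound for retention, mm^2.
#' @param cutting_min_mm2 Strict lower area bound of the cutting-cone class,
#'   mm^2.
#' @param endosteal_width_um Minimum maximum-Feret width of an
#'   endosteal-margin macro-pore, um.
#' @param endosteal_margin_um Maximum distance from an endosteal contour at
#'   which the width rule applies, um.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(circ_min = 0.3, circ_max = 1.0,
                          area_min_mm2 = 0.002, cutting_min_mm2 = 0.04,
                          endosteal_width_um = 600,
                          endosteal_margin_um = 100) {
  stopifnot(circ_min >= 0, circ_min <= circ_max, circ_max <= 1,
            area_min_mm2 > 0, area_min_mm2 < cutting_min_mm2,
            endosteal_width_um > 0, endosteal_margin_um >= 0)
  structure(list(circ_min = circ_min, circ_max = circ_max,
                 area_min_mm2 = area_min_mm2,
                 cutting_min_mm2 = cutting_min_mm2,
                 endosteal_width_um = endosteal_width_um,
                 endosteal_margin_um = endosteal_margin_um),
            class = "filter_config")
}

#' Apply circularity and minimum-area retention filters
#'
#' Populates the `excluded_by` set and the `retained` flag. A record is
#' retained iff `circ_min <= circularity <= circ_max` and
#' `area > area_min_mm2` (strict). All failing criteria are recorded;
#' exclusion flags never alter measured values, and the operation is
#' idempotent.
#'
#' @param records Data frame from [measure_pores()].
#' @param config A [filter_config()].
#' @return `records` with `excluded_by` (string set, `"none"` when retained)
#'   and `retained` columns.
#' @export
filter_pores <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  flags <- lapply(seq_len(nrow(records)), function(i) {
    f <- character(0)
    if (records$circularity[i] < config$circ_min ||
        records$circularity[i] > config$circ_max) {
      f <- c(f, "circularity")
    }
    if (!(records$area_mm2[i] > config$area_min_mm2)) f <- c(f, "min_area")
    # preserve a previously set endosteal flag (idempotence under re-filtering)
    if (!is.null(records$excluded_by) &&
        grepl("endosteal", records$excluded_by[i])) {
      f <- c(f, "endosteal")
    }
    f
  })
  records$excluded_by <- vapply(flags, function(f) {
    if (length(f)) paste(f, collapse = ";") else "none"
  }, character(1))
  records$retained <- records$excluded_by == "none"
  if (nrow(records)) {
    records$canal_class <- classify_canal(records$area_mm2,
                                          config$area_min_mm2,
                                          config$cutting_min_mm2)
  }
  records
}

#' Flag endosteal-margin macro-porosities
#'
#' Automates the manual exclusion of large, smooth pores at the endosteal
#' margin that reflect transition to cancellous bone: a record is flagged
#' `endosteal` iff its maximum Feret width exceeds
#' `config$endosteal_width_um` and its boundary comes within
#' `config$endosteal_margin_um` of an endosteal contour. Flags are additive
#' to circularity/area exclusions. An explicit `manual_ids` vector is also
#' honoured for exact replication of a manually curated exclusion list.
#'
#' @param records Filtered records from [filter_pores()] (must carry the
#'   `boundary` list column).
#' @param contours A [contour_set()].
#' @param config A [filter_config()].
#' @param pixel_spacing_um Pixel edge length in micrometres.
#' @param manual_ids Optional integer ids to flag unconditionally.
#' @return `records` with updated `excluded_by` and `retained`.
#' @export
exclude_endosteal <- function(records, contours, config = filter_config(),
                              pixel_spacing_um, manual_ids = integer(0)) {
  stopifnot(inherits(contours, "contour_set"),
            inherits(config, "filter_config"))
  if (nrow(records) == 0L || length(contours$endosteal) == 0L) {
    return(records)
  }
  margin_px <- config$endosteal_margin_um / pixel_spacing_um
  hit <- records$id %in% manual_ids
  wide <- records$feret_max_um > config$endosteal_width_um
  for (i in which(wide & !hit)) {
    b <- records$boundary[[i]]
    near <- FALSE
    for (e in contours$endosteal) {
      if (min(.dist_to_polyline(b[, 1], b[, 2], e)) <= margin_px) {
        near <- TRUE
        break
      }
    }
    hit[i] <- near
  }
  if (any(hit)) {
    has_flag <- grepl("endosteal", records$excluded_by)
    add <- hit & !has_flag
    records$excluded_by[add] <- ifelse(
      records$excluded_by[add] == "none", "endosteal",
      paste0(records$excluded_by[add], ";endosteal")
    )
    records$retained <- records$excluded_by == "none"
  }
  records
}

#' Classify a canal by remodelling stage from its cross-sectional area
#'
#' The classification partitions positive areas: mature Haversian canal for
#' `Ca.Ar <= 0.002` mm^2, closing cone for `0.002 < Ca.Ar <= 0.04` mm^2, and
#' cutting cone for `Ca.Ar > 0.04` mm^2 (strict upper boundaries).
#'
#' @param area_mm2 Numeric vector of positive canal areas in mm^2.
#' @param area_min_mm2 Mature/closing boundary, mm^2.
#' @param cutting_min_mm2 Closing/cutting boundary, mm^2.
#' @return Character vector with values `"mature"`, `"closing_cone"`,
#'   `"cutting_cone"`.
#' @export
classify_canal <- function(area_mm2, area_min_mm2 = 0.002,
                           cutting_min_mm2 = 0.04) {
  if (any(is.na(area_mm2)) || any(area_mm2 <= 0)) {
    stop("canal areas must be positive")
  }
  ifelse(area_mm2 > cutting_min_mm2, "cutting_cone",
         ifelse(area_mm2 > area_min_mm2, "closing_cone", "mature"))
}

#' Run the full per-section pore analysis
#'
#' Convenience chain: cortical mask, triangle threshold, binarisation,
#' labelling, measurement, retention filters and endosteal exclusion.
#'
#' @param img A [microradiograph()].
#' @param contours A [contour_set()].
#' @param config A [filter_config()].
#' @param threshold_mode `"roi"` or `"full"` (see [threshold_section()]).
#' @param side Pore polarity (see [threshold_section()]).
#' @param manual_ids Manual endosteal exclusion ids.
#' @return List with `mask`, `threshold`, `pores` (measured, flagged
#'   records).
#' @export
analyze_section <- function(img, contours, config = filter_config(),
                            threshold_mode = "roi", side = "pores_below",
                            manual_ids = integer(0)) {
  mask <- cortical_mask(contours, dim(img$pixels), img$pixel_spacing_um)
  thr <- threshold_section(img, mask, mode = threshold_mode, side = side)
  pore_grid <- binarize_pores(img, mask, thr)
  comps <- label_pores(pore_grid)
  pores <- measure_pores(comps, img$pixel_spacing_um)
  pores <- filter_pores(pores, config)
  pores <- exclude_endosteal(pores, contours, config, img$pixel_spacing_um,
                             manual_ids = manual_ids)
  list(mask = mask, threshold = thr, pores = pores)
}

#' Write a pore table to CSV (dropping the boundary list column)
#'
#' @param records Pore records.
#' @param path Output path.
#' @param extra Named list of constant columns (e.g. subject_id, site,
#'   group) prepended to the table.
#' @return `path`, invisibly.
#' @export
write_pores_csv <- function(records, path, extra = list()) {
  records$boundary <- NULL
  if (length(extra)) {
    records <- cbind(as.data.frame(extra, stringsAsFactors = FALSE),
                     records, row.names = NULL)
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
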