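# Seeded synthetic microradiograph generator. Emulates transverse cortical
# sections as rendered by point-projection X-ray microscopy: a radiopaque
# annular (or half-annular) cortex containing radiolucent near-circular
# canals of the three remodelling-stage size classes, elongated
# low-circularity Volkmann-like distractors, large irregular macro-pores at
# the endosteal margin, a multiplicative background-intensity gradient
# (uneven sample thickness) and additive Gaussian noise. Every stamped pore
# is logged in a ground-truth table for recovery testing.

#' Idealised section geometry for each sampling site
#'
#' Annulus radii chosen so the analytic cortical area matches the scale of
#' real sections at each site (rib about 77 mm^2, tibia about 820 mm^2,
#' metacarpal diaphysis about 773 mm^2, metacarpal metaphysis half-section
#' about 240 mm^2), with the pixel spacing each site was imaged at
#' (10.0 / 25.0 / 25.0 / 16.7 um). `scale` shrinks radii linearly (area by
#' `scale^2`) for reduced-size test sections.
#'
#' @param site One of `"rib"`, `"tibia"`, `"mc_diaphysis"`,
#'   `"mc_metaphysis"`.
#' @param scale Linear scale factor on the radii.
#' @return List with `outer_mm`, `inner_mm`, `half_section`,
#'   `pixel_spacing_um`, `ct_ar_mm2` (analytic cortical area).
#' @export
site_geometry <- function(site = c("rib", "tibia", "mc_diaphysis",
                                   "mc_metaphysis"), scale = 1) {
  site <- match.arg(site)
  g <- switch(site,
    rib = list(outer_mm = 6.0, inner_mm = 3.4, half_section = FALSE,
               pixel_spacing_um = 10.0),
    tibia = list(outer_mm = 19.0, inner_mm = 10.0, half_section = FALSE,
                 pixel_spacing_um = 25.0),
    mc_diaphysis = list(outer_mm = 18.5, inner_mm = 9.8, half_section = FALSE,
                        pixel_spacing_um = 25.0),
    mc_metaphysis = list(outer_mm = 14.5, inner_mm = 7.6, half_section = TRUE,
                         pixel_spacing_um = 16.7)
  )
  g$outer_mm <- g$outer_mm * scale
  g$inner_mm <- g$inner_mm * scale
  area <- pi * (g$outer_mm^2 - g$inner_mm^2)
  g$ct_ar_mm2 <- if (g$half_section) area / 2 else area
  g
}

#' Specification of one synthetic section
#'
#' Canal areas are drawn from per-class truncated lognormals (median and
#' geometric SD in mm^2), with guard bands inside the class intervals so
#' rasterisation cannot push a stamped canal across a class boundary.
#'
#' @param site Sampling site (sets the default geometry and pixel spacing).
#' @param scale Linear geometry scale factor.
#' @param n_mature,n_closing,n_cutting Canal counts per class.
#' @param n_volkmann Number of elongated (aspect ratio >= 8) Volkmann-like
#'   distractors.
#' @param n_endosteal Number of large irregular endosteal-margin macro-pores
#'   (Feret width > 600 um).
#' @param matrix_intensity Mean 8-bit level of mineralised matrix.
#' @param pore_intensity Mean 8-bit level of pores (radiolucent, darker).
#' @param background_gradient Peak-to-peak fractional intensity variation of
#'   the multiplicative background across the frame.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param class_areas Named list of per-class `c(median, gsd, lo, hi)` area
#'   laws in mm^2.
#' @param pixel_spacing_um,outer_mm,inner_mm,half_section Geometry overrides.
#' @return List of class `synthetic_section_spec`.
#' @export
synthetic_section_spec <- function(site = "rib", scale = 1,
                                   n_mature = 40L, n_closing = 30L,
                                   n_cutting = 4L, n_volkmann = 2L,
                                   n_endosteal = 1L,
                                   matrix_intensity = 180,
                                   pore_intensity = 60,
                                   background_gradient = 0.2,
                                   noise_sd = 6,
                                   class_areas = list(
                                     mature = c(5e-4, 1.6, 1e-4, 1.5e-3),
                                     closing_cone = c(6e-3, 1.8, 2.8e-3, 3.8e-2),
                                     cutting_cone = c(6e-2, 1.3, 4.4e-2, 1.2e-1)
                                   ),
                                   pixel_spacing_um = NULL, outer_mm = NULL,
                                   inner_mm = NULL, half_section = NULL) {
  geo <- site_geometry(site, scale)
  if (!is.null(pixel_spacing_um)) geo$pixel_spacing_um <- pixel_spacing_um
  if (!is.null(outer_mm)) geo$outer_mm <- outer_mm
  if (!is.null(inner_mm)) geo$inner_mm <- inner_mm
  if (!is.null(half_section)) geo$half_section <- half_section
  stopifnot(geo$outer_mm > geo$inner_mm, geo$inner_mm > 0,
            matrix_intensity >= 0, matrix_intensity <= 255,
            pore_intensity >= 0, pore_intensity <= 255,
            pore_intensity != matrix_intensity,
            background_gradient >= 0, noise_sd >= 0,
            n_mature >= 0, n_closing >= 0, n_cutting >= 0,
            n_volkmann >= 0, n_endosteal >= 0)
  area <- pi * (geo$outer_mm^2 - geo$inner_mm^2)
  structure(
    list(site = site, outer_mm = geo$outer_mm, inner_mm = geo$inner_mm,
         half_section = geo$half_section,
         pixel_spacing_um = geo$pixel_spacing_um,
         ct_ar_mm2 = if (geo$half_section) area / 2 else area,
         n_mature = as.integer(n_mature), n_closing = as.integer(n_closing),
         n_cutting = as.integer(n_cutting),
         n_volkmann = as.integer(n_volkmann),
         n_endosteal = as.integer(n_endosteal),
         matrix_intensity = matrix_intensity,
         pore_intensity = pore_intensity,
         background_gradient = background_gradient, noise_sd = noise_sd,
         class_areas = class_areas),
    class = "synthetic_section_spec"
  )
}

# Truncated lognormal sampling via inverse-CDF on the truncated quantile
# range; medians/gsd in mm^2.
.rtrunc_lnorm <- function(n, median, gsd, lo, hi) {
  if (n == 0L) return(numeric(0))
  mu <- log(median); sig <- log(gsd)
  plo <- stats::plnorm(lo, mu, sig)
  phi <- stats::plnorm(hi, mu, sig)
  stats::qlnorm(stats::runif(n, plo, phi), mu, sig)
}

# Stamp a filled disc of radius r (pixels) at 0-based centre (cx, cy);
# returns linear indices of stamped pixels (at least the centre pixel).
.disc_pixels <- function(cx, cy, r, nr, nc) {
  r0 <- max(1L, floor(cy - r) + 1L); r1 <- min(nr, ceiling(cy + r) + 1L)
  c0 <- max(1L, floor(cx - r) + 1L); c1 <- min(nc, ceiling(cx + r) + 1L)
  rows <- r0:r1; cols <- c0:c1
  yy <- rep(rows - 1L, times = length(cols))
  xx <- rep(cols - 1L, each = length(rows))
  keep <- (xx - cx)^2 + (yy - cy)^2 <= r^2
  idx <- (rep(cols, each = length(rows)) - 1L) * nr + rep(rows, length(cols))
  idx <- idx[keep]
  if (!length(idx)) {
    idx <- (round(cx)) * nr + round(cy) + 1L
  }
  idx
}

# Rotated filled ellipse (semi-axes a >= b in pixels, orientation theta).
.ellipse_pixels <- function(cx, cy, a, b, theta, nr, nc) {
  ext <- a
  r0 <- max(1L, floor(cy - ext) + 1L); r1 <- min(nr, ceiling(cy + ext) + 1L)
  c0 <- max(1L, floor(cx - ext) + 1L); c1 <- min(nc, ceiling(cx + ext) + 1L)
  rows <- r0:r1; cols <- c0:c1
  yy <- rep(rows - 1L, times = length(cols)) - cy
  xx <- rep(cols - 1L, each = length(rows)) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  idx <- (rep(cols, each = length(rows)) - 1L) * nr + rep(rows, length(cols))
  idx[keep]
}

# Circle polygon (0-based pixel coordinates), n vertices.
.circle_poly <- function(cx, cy, r, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Upper half-annulus boundary arcs (y <= cy), closed by the section crop.
.half_arc_poly <- function(cx, cy, r, y_chord, n = 120L) {
  delta <- asin(min(1, max(0, (cy - y_chord) / r)))
  th <- seq(pi + delta, 2 * pi - delta, length.out = n)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate one synthetic microradiograph section with ground truth
#'
#' Renders the cortex at the matrix intensity under a multiplicative linear
#' background gradient of random direction, stamps non-overlapping pores
#' (discs for canals, high-aspect ellipses for Volkmann-like distractors,
#' irregular multi-disc blobs straddling the endosteal margin) at the pore
#' intensity, then adds rounded, clipped Gaussian noise. A minimum 2-px gap
#' between pores keeps component labelling unambiguous. Identical seeds give
#' byte-identical output; the caller's RNG stream is left untouched.
#'
#' @param spec A [synthetic_section_spec()].
#' @param seed Integer seed.
#' @return List with `image` ([microradiograph()]), `contours`
#'   ([contour_set()]), `truth` (per-pore table: `id`, `class`, `x_px`,
#'   `y_px`, `area_mm2` analytic, `n_px` stamped pixel count,
#'   `area_px_mm2 = n_px * spacing^2`, `volkmann`, `endosteal`),
#'   `ct_ar_mm2` (analytic), `spec`, `seed`.
#' @export
generate_section <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_section_spec"))
  .with_seed(seed, {
    s_um <- spec$pixel_spacing_um
    s_mm <- s_um / 1e3
    r_out <- spec$outer_mm / s_mm
    r_in <- spec$inner_mm / s_mm
    margin <- 8
    cx <- r_out + margin
    nc <- ceiling(2 * (r_out + margin)) + 1L
    if (spec$half_section) {
      cy <- r_out + margin
      nr <- ceiling(cy + margin) + 1L
    } else {
      cy <- r_out + margin
      nr <- nc
    }

    # contours
    if (spec$half_section) {
      peri <- .half_arc_poly(cx, cy, r_out, cy)
      endo <- .half_arc_poly(cx, cy, r_in, cy - 2)
    } else {
      peri <- .circle_poly(cx, cy, r_out)
      endo <- .circle_poly(cx, cy, r_in)
    }
    contours <- contour_set(peri, list(endo))

    # background: cortex at matrix intensity with a linear multiplicative
    # gradient; medullary cavity and frame exterior slightly dark (thin
    # matrix projected), which the ROI-restricted histogram never sees
    phi <- stats::runif(1, 0, 2 * pi)
    xs <- (seq_len(nc) - 1)
    ys <- (seq_len(nr) - 1)
    proj <- outer(ys, xs, function(y, x) x * cos(phi) + y * sin(phi))
    u <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
    base <- spec$matrix_intensity * (1 + spec$background_gradient * (u - 0.5))
    img <- base

    placed <- matrix(numeric(0), 0, 3)  # x, y, effective radius
    truth <- list()
    gap <- 3  # centre-distance slack beyond radii: >= 2-px separation

    place_one <- function(r_eff, y_top_clear) {
      for (try in seq_len(500L)) {
        rad <- stats::runif(1, r_in + r_eff + gap, r_out - r_eff - gap)
        th <- stats::runif(1, 0, 2 * pi)
        x <- cx + rad * cos(th)
        y <- cy + rad * sin(th)
        if (spec$half_section && y > cy - r_eff - y_top_clear) next
        if (nrow(placed) &&
            any((placed[, 1] - x)^2 + (placed[, 2] - y)^2 <
                  (placed[, 3] + r_eff + gap)^2)) next
        return(c(x, y))
      }
      stop("could not place a pore of radius ", round(r_eff, 1),
           " px without overlap; reduce counts or sizes")
    }

    add_truth <- function(class, x, y, area_mm2, n_px, volkmann = FALSE,
                          endosteal = FALSE) {
      truth[[length(truth) + 1L]] <<- data.frame(
        id = length(truth) + 1L, class = class, x_px = x, y_px = y,
        area_mm2 = area_mm2, n_px = n_px, area_px_mm2 = n_px * s_mm^2,
        volkmann = volkmann, endosteal = endosteal, stringsAsFactors = FALSE
      )
    }

    # endosteal macro-pores first (they are the largest structures)
    if (spec$n_endosteal > 0L) {
      rb <- 350 / s_um  # main blob radius, px (~700 um across)
      for (i in seq_len(spec$n_endosteal)) {
        for (try in seq_len(500L)) {
          th <- stats::runif(1, 0, 2 * pi)
          if (spec$half_section) th <- stats::runif(1, pi * 1.15, pi * 1.85)
          rad <- r_in + 0.3 * rb
          x <- cx + rad * cos(th); y <- cy + rad * sin(th)
          r_eff <- 2.2 * rb
          if (nrow(placed) &&
              any((placed[, 1] - x)^2 + (placed[, 2] - y)^2 <
                    (placed[, 3] + r_eff + gap)^2)) next
          idx <- .disc_pixels(x, y, rb, nr, nc)
          out_dir <- th  # satellites biased toward the cortex side
          for (k in 1:3) {
            ang <- out_dir + stats::runif(1, -pi / 3, pi / 3)
            off <- 0.8 * rb
            idx <- c(idx, .disc_pixels(x + off * cos(ang), y + off * sin(ang),
                                       0.5 * rb, nr, nc))
          }
          idx <- unique(idx)
          img[idx] <- spec$pore_intensity
          placed <- rbind(placed, c(x, y, r_eff))
          add_truth("endosteal", x, y, length(idx) * s_mm^2, length(idx),
                    endosteal = TRUE)
          break
        }
      }
    }

    # canals: cutting, closing, mature (discs)
    stamp_class <- function(n, class) {
      law <- spec$class_areas[[class]]
      areas <- .rtrunc_lnorm(n, law[1], law[2], law[3], law[4])
      for (a in areas) {
        r_px <- sqrt(a / pi) / s_mm
        p <- place_one(max(r_px, 0.5), 2)
        idx <- .disc_pixels(p[1], p[2], r_px, nr, nc)
        img[idx] <<- spec$pore_intensity
        placed <<- rbind(placed, c(p[1], p[2], max(r_px, 0.5)))
        add_truth(class, p[1], p[2], a, length(idx))
      }
    }
    stamp_class(spec$n_cutting, "cutting_cone")
    stamp_class(spec$n_closing, "closing_cone")
    stamp_class(spec$n_mature, "mature")

    # Volkmann-like distractors: thin rotated ellipses, aspect >= 8
    if (spec$n_volkmann > 0L) {
      for (i in seq_len(spec$n_volkmann)) {
        b <- 1.5
        aspect <- stats::runif(1, 8, 12)
        a_px <- aspect * b
        p <- place_one(a_px, 2)
        th <- stats::runif(1, 0, pi)
        idx <- .ellipse_pixels(p[1], p[2], a_px, b, th, nr, nc)
        img[idx] <- spec$pore_intensity
        placed <- rbind(placed, c(p[1], p[2], a_px))
        add_truth("volkmann", p[1], p[2], pi * a_px * b * s_mm^2,
                  length(idx), volkmann = TRUE)
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    }
    img <- matrix(as.integer(pmin(255, pmax(0, floor(img + 0.5)))), nr, nc)

    truth <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(id = integer(0), class = character(0), x_px = numeric(0),
                 y_px = numeric(0), area_mm2 = numeric(0), n_px = integer(0),
                 area_px_mm2 = numeric(0), volkmann = logical(0),
                 endosteal = logical(0), stringsAsFactors = FALSE)
    }
    list(
      image = microradiograph(img, s_um, site = spec$site),
      contours = contours,
      truth = truth,
      ct_ar_mm2 = spec$ct_ar_mm2,
      spec = spec,
      seed = seed
    )
  })
}

#' Default per-site, per-group canal density and size parameters
#'
#' Densities (canals per mm^2 of cortex) and per-class area laws calibrated
#' so generated group means land near the observed site-by-group means of
#' the study design this generator emulates: closing-cone densities of about
#' 1.8-3.2 canals/mm^2 everywhere, cutting-cone densities that are similar
#' between groups in the rib but 5-19 times higher in rested than exercised
#' metacarpal sites.
#'
#' @return Data frame with `site`, `group`, `d_close`, `d_cut` (per mm^2),
#'   `a_close_med`, `a_cut_med` (lognormal medians, mm^2), `a_close_gsd`,
#'   `a_cut_gsd`.
#' @export
default_study_params <- function() {
  p <- rbind(
    data.frame(site = "rib", group = "exercised", d_close = 2.78,
               d_cut = 0.040, a_close_med = 0.0042, a_cut_med = 0.048),
    data.frame(site = "rib", group = "rested", d_close = 3.21,
               d_cut = 0.060, a_close_med = 0.0042, a_cut_med = 0.048),
    data.frame(site = "tibia", group = "exercised", d_close = 1.84,
               d_cut = 0.020, a_close_med = 0.0046, a_cut_med = 0.048),
    data.frame(site = "tibia", group = "rested", d_close = 2.15,
               d_cut = 0.060, a_close_med = 0.0063, a_cut_med = 0.048),
    data.frame(site = "mc_diaphysis", group = "exercised", d_close = 1.75,
               d_cut = 0.020, a_close_med = 0.0051, a_cut_med = 0.068),
    data.frame(site = "mc_diaphysis", group = "rested", d_close = 1.81,
               d_cut = 0.110, a_close_med = 0.0065, a_cut_med = 0.062),
    data.frame(site = "mc_metaphysis", group = "exercised", d_close = 2.016,
               d_cut = 0.014, a_close_med = 0.0046, a_cut_med = 0.062),
    data.frame(site = "mc_metaphysis", group = "rested", d_close = 2.65,
               d_cut = 0.260, a_close_med = 0.0098, a_cut_med = 0.056)
  )
  p$a_close_gsd <- 1.8
  p$a_cut_gsd <- 1.3
  p
}

#' Generate a complete synthetic two-group study
#'
#' Emulates the study design: two groups (exercised, rested) of
#' `n_per_group` subjects sampled at up to four sites, with per-cell canal
#' densities and size laws from `params`. With `drop_missing = TRUE` one
#' rested subject loses its tibia and metacarpal-diaphysis sections
#' (mirroring a damaged specimen), leaving n = 5 in those cells. Canal
#' counts are Poisson in density times cortical area with a lognormal
#' between-section multiplier (`subject_cv`); canal areas follow the
#' per-cell truncated lognormal laws. With `render = FALSE` (default) the
#' truth-level section indices are returned without rasterising images; with
#' `render = TRUE` every section is rendered with [generate_section()] and
#' written to `dir` as TIFF + JSON contours, with `metadata.csv` and
#' `truth.csv`, ready for [run_study()].
#'
#' @param params Parameter table as from [default_study_params()].
#' @param seed Integer seed (deterministic output).
#' @param n_per_group Subjects per group.
#' @param sites Sites to generate.
#' @param drop_missing Drop the two damaged rested sections.
#' @param render Rasterise images (else truth-level indices only).
#' @param dir Output directory (required when `render = TRUE`).
#' @param scale Linear geometry scale for rendered sections.
#' @param subject_cv Coefficient of variation of the between-section density
#'   multiplier.
#' @param ct_ar_cv Coefficient of variation of cortical area between
#'   subjects.
#' @param noise_sd,background_gradient Image confounders for rendered
#'   sections (see [synthetic_section_spec()]).
#' @return List with `sections` (truth-derived index table in the
#'   [section_morphometry()] schema, both selections), `metadata` (rendered
#'   runs: the metadata table with file paths), `truth` (per-pore table,
#'   rendered runs), `params`, `seed`.
#' @export
generate_study <- function(params = default_study_params(), seed = 1L,
                           n_per_group = 6L,
                           sites = unique(params$site),
                           drop_missing = TRUE, render = FALSE, dir = NULL,
                           scale = 1, subject_cv = 0.35, ct_ar_cv = 0.05,
                           noise_sd = 6, background_gradient = 0.2) {
  stopifnot(all(c("site", "group", "d_close", "d_cut", "a_close_med",
                  "a_cut_med", "a_close_gsd", "a_cut_gsd") %in% names(params)))
  if (render && is.null(dir)) stop("`dir` is required when render = TRUE")
  if (render) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(seed, {
    sections <- list()
    meta <- list()
    truth_all <- list()
    sig_s <- sqrt(log(1 + subject_cv^2))
    sig_c <- sqrt(log(1 + ct_ar_cv^2))
    for (site in sites) {
      geo <- site_geometry(site, scale)
      for (group in c("exercised", "rested")) {
        row <- params[params$site == site & params$group == group, ]
        if (nrow(row) != 1L) stop("params must have one row per site x group")
        for (subj in seq_len(n_per_group)) {
          subject_id <- sprintf("%s%02d", if (group == "exercised") "E" else "R",
                                subj)
          if (drop_missing && group == "rested" && subj == 5L &&
              site %in% c("tibia", "mc_diaphysis")) {
            next
          }
          m <- stats::rlnorm(1, -sig_s^2 / 2, sig_s)
          ct_ar <- geo$ct_ar_mm2 * stats::rlnorm(1, -sig_c^2 / 2, sig_c)
          n_close <- stats::rpois(1, row$d_close * m * ct_ar)
          n_cut <- stats::rpois(1, row$d_cut * m * ct_ar)
          a_close <- .rtrunc_lnorm(n_close, row$a_close_med, row$a_close_gsd,
                                   2.8e-3, 3.8e-2)
          a_cut <- .rtrunc_lnorm(n_cut, row$a_cut_med, row$a_cut_gsd,
                                 4.4e-2, 1.2e-1)
          if (render) {
            spec <- synthetic_section_spec(
              site = site, scale = scale,
              n_mature = stats::rpois(1, 0.5 * ct_ar),
              n_closing = n_close, n_cutting = n_cut,
              n_volkmann = 2L, n_endosteal = 1L,
              noise_sd = noise_sd, background_gradient = background_gradient,
              class_areas = list(
                mature = c(5e-4, 1.6, 1e-4, 1.5e-3),
                closing_cone = c(row$a_close_med, row$a_close_gsd,
                                 2.8e-3, 3.8e-2),
                cutting_cone = c(row$a_cut_med, row$a_cut_gsd,
                                 4.4e-2, 1.2e-1)
              )
            )
            sec_seed <- (seed * 1009 + length(meta) * 7919) %% 2147483647L
            sec <- generate_section(spec, sec_seed)
            stem <- sprintf("%s_%s", subject_id, site)
            img_path <- file.path(dir, paste0(stem, ".tif"))
            roi_path <- file.path(dir, paste0(stem, "_roi.json"))
            write_microradiograph(sec$image, img_path)
            write_contours(sec$contours, roi_path)
            tr <- sec$truth
            tr$subject_id <- subject_id
            tr$site <- site
            tr$group <- group
            truth_all[[length(truth_all) + 1L]] <- tr
            meta[[length(meta) + 1L]] <- data.frame(
              subject_id = subject_id, group = group, site = site,
              image_path = img_path, roi_path = roi_path,
              pixel_spacing_um = spec$pixel_spacing_um,
              stringsAsFactors = FALSE
            )
            # truth-level indices for a rendered section reflect what was
            # actually stamped
            a_close <- tr$area_mm2[tr$class == "closing_cone"]
            a_cut <- tr$area_mm2[tr$class == "cutting_cone"]
            ct_ar <- spec$ct_ar_mm2
            n_close <- length(a_close)
            n_cut <- length(a_cut)
          }
          for (selection in c("combined", "cutting_only")) {
            n_ca <- if (selection == "combined") n_close + n_cut else n_cut
            tt <- if (selection == "combined") {
              sum(a_close) + sum(a_cut)
            } else {
              sum(a_cut)
            }
            sections[[length(sections) + 1L]] <- data.frame(
              subject_id = subject_id, site = site, group = group,
              selection = selection, Ct_Ar_mm2 = ct_ar,
              N_Ca = as.integer(n_ca), Tt_Ca_Ar_mm2 = tt,
              N_Ca_per_Ct_Ar = n_ca / ct_ar,
              Tt_Ca_Ar_per_Ct_Ar = tt / ct_ar,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    out <- list(sections = do.call(rbind, sections), params = params,
                seed = seed)
    if (render) {
      out$metadata <- do.call(rbind, meta)
      out$truth <- do.call(rbind, truth_all)
      md_path <- file.path(dir, "metadata.csv")
      utils::write.csv(out$metadata, md_path, row.names = FALSE)
      utils::write.csv(out$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
      out$metadata_path <- md_path
    }
    out
  })
}
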