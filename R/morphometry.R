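# Section-level histomorphometric indices and size/derived-quantity helpers.
# Index names follow standard bone histomorphometry nomenclature: Ct.Ar
# (cortical area), N.Ca (canal count), Tt.Ca.Ar (total canal area),
# N.Ca/Ct.Ar (numerical density), Tt.Ca.Ar/Ct.Ar (area fraction).

#' Canal diameter from cross-sectional area
#'
#' Ca.Dm assuming a circular cross-section: `2 * sqrt(A / pi)`, returned in
#' micrometres for an area in mm^2.
#'
#' @param area_mm2 Non-negative areas, mm^2.
#' @return Diameters, um.
#' @export
canal_diameter <- function(area_mm2) {
  if (any(is.na(area_mm2)) || any(area_mm2 < 0)) stop("areas must be >= 0")
  2000 * sqrt(area_mm2 / pi)
}

#' Class-boundary area from a canal diameter
#'
#' Inverts [canal_diameter()]: `A = pi * (d/2)^2`, reported at one
#' significant figure, the precision at which the class cut-offs are quoted
#' (50 um -> 0.002 mm^2; 225 um -> 0.04 mm^2).
#'
#' @param diameter_um Non-negative diameters, um.
#' @return Areas in mm^2, rounded to one significant figure.
#' @export
area_cutoff_from_diameter <- function(diameter_um) {
  if (any(is.na(diameter_um)) || any(diameter_um < 0)) {
    stop("diameters must be >= 0")
  }
  signif(pi * (diameter_um / 2000)^2, 1)
}

#' Minimum resolvable canal diameter at a given pixel spacing
#'
#' The equivalent circular diameter of a single pixel, `2 * s / sqrt(pi)`,
#' reported to two decimals. This is the smallest Ca.Dm a one-pixel pore can
#' represent at spacing `s`; it is distinct from the 50-um retention cut-off,
#' which is twice the largest pixel spacing used across imaging sites.
#'
#' @param pixel_spacing_um Pixel edge lengths, um (> 0).
#' @return Diameters, um, rounded to 2 decimals.
#' @export
min_resolvable_diameter <- function(pixel_spacing_um) {
  if (any(is.na(pixel_spacing_um)) || any(pixel_spacing_um <= 0)) {
    stop("pixel spacing must be > 0")
  }
  round(2 * pixel_spacing_um / sqrt(pi), 2)
}

#' Section-level morphometric indices for a canal-class selection
#'
#' Computes N.Ca, Tt.Ca.Ar and their Ct.Ar-normalised forms over the retained
#' records of one section. The `"combined"` selection covers cutting plus
#' closing cones (Ca.Ar > 0.002 mm^2, i.e. every retained canal); the
#' `"cutting_only"` selection restricts to cutting cones
#' (Ca.Ar > 0.04 mm^2).
#'
#' @param records Filtered pore records (with `retained` and `canal_class`).
#' @param mask A [cortical_mask()] (or a single Ct.Ar value in mm^2).
#' @param selection `"combined"` or `"cutting_only"`.
#' @param subject_id,site,group Metadata echoed into the row.
#' @return One-row data frame with columns `subject_id`, `site`, `group`,
#'   `selection`, `Ct_Ar_mm2`, `N_Ca`, `Tt_Ca_Ar_mm2`, `N_Ca_per_Ct_Ar`,
#'   `Tt_Ca_Ar_per_Ct_Ar`.
#' @export
section_morphometry <- function(records, mask,
                                selection = c("combined", "cutting_only"),
                                subject_id = NA_character_,
                                site = NA_character_,
                                group = NA_character_) {
  selection <- match.arg(selection)
  ct_ar <- if (inherits(mask, "cortical_mask")) mask$area_mm2 else mask
  if (!is.numeric(ct_ar) || ct_ar <= 0) stop("Ct.Ar must be positive")
  keep <- records$retained
  if (selection == "cutting_only") {
    keep <- keep & records$canal_class == "cutting_cone"
  }
  n_ca <- sum(keep)
  tt <- sum(records$area_mm2[keep])
  data.frame(
    subject_id = subject_id, site = site, group = group,
    selection = selection,
    Ct_Ar_mm2 = ct_ar,
    N_Ca = as.integer(n_ca),
    Tt_Ca_Ar_mm2 = tt,
    N_Ca_per_Ct_Ar = n_ca / ct_ar,
    Tt_Ca_Ar_per_Ct_Ar = tt / ct_ar,
    stringsAsFactors = FALSE
  )
}

#' Canal-size histogram
#'
#' Counts retained canals per area bin under the right-open convention
#' `[lo, hi)`; counts are summable across sections and groups.
#'
#' @param records Pore records (only `retained` rows are counted when the
#'   column is present).
#' @param edges Strictly increasing bin edges, mm^2; values outside
#'   `[edges[1], edges[n])` are not counted.
#' @return Data frame with `lo`, `hi`, `count`.
#' @export
size_histogram <- function(records, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("`edges` must be strictly increasing")
  }
  a <- records$area_mm2
  if (!is.null(records$retained)) a <- a[records$retained]
  k <- length(edges) - 1L
  counts <- integer(k)
  if (length(a)) {
    bin <- findInterval(a, edges, rightmost.closed = FALSE)
    bin <- bin[bin >= 1L & bin <= k & a < edges[length(edges)]]
    counts <- tabulate(bin, nbins = k)
  }
  data.frame(lo = edges[-length(edges)], hi = edges[-1], count = counts)
}

#' Logarithmic bin edges for canal-size distributions
#'
#' Thirty log-spaced bins from the retention cut-off to the largest observed
#' area, the binning used for pooled size-distribution plots.
#'
#' @param max_area_mm2 Largest observed canal area, mm^2.
#' @param min_area_mm2 Lower edge (default the 0.002 mm^2 cut-off).
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` edges.
#' @export
log_area_edges <- function(max_area_mm2, min_area_mm2 = 0.002, n_bins = 30L) {
  stopifnot(max_area_mm2 > min_area_mm2, min_area_mm2 > 0)
  exp(seq(log(min_area_mm2), log(max_area_mm2), length.out = n_bins + 1L))
}

#' Group summary of section-level indices (mean and SD)
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' index per site, group and selection cell. A single-section cell reports
#' SD 0 with `sd_defined = FALSE`.
#'
#' @param sections Data frame of [section_morphometry()] rows.
#' @param indices Index columns to summarise.
#' @return Long data frame with `site`, `group`, `selection`, `index`, `n`,
#'   `mean`, `sd`, `sd_defined`.
#' @export
group_summary <- function(sections,
                          indices = c("Ct_Ar_mm2", "N_Ca", "Tt_Ca_Ar_mm2",
                                      "N_Ca_per_Ct_Ar",
                                      "Tt_Ca_Ar_per_Ct_Ar")) {
  stopifnot(nrow(sections) > 0L)
  cells <- unique(sections[, c("site", "group", "selection")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- sections$site == cells$site[i] &
      sections$group == cells$group[i] &
      sections$selection == cells$selection[i]
    for (ix in indices) {
      v <- sections[[ix]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        site = cells$site[i], group = cells$group[i],
        selection = cells$selection[i], index = ix,
        n = length(v), mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        sd_defined = length(v) > 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
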