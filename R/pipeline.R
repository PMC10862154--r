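# Full-study orchestration: load -> mask -> threshold -> label -> measure ->
# filter -> exclude -> classify -> morphometry -> group stats, for both canal
# selections, with CSV outputs, figures and a run manifest.

#' Read a run configuration from YAML or JSON
#'
#' Recognised fields: `metadata` (path to the metadata CSV, required),
#' `out_dir` (required), `threshold_mode` (`"roi"`/`"full"`), `side`
#' (`"pores_below"`/`"pores_above"`), `filter` (named overrides for
#' [filter_config()]), `selections`, `stats_method`, `plots` (logical),
#' `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

.default_config <- function(config) {
  defaults <- list(threshold_mode = "roi", side = "pores_below",
                   selections = c("combined", "cutting_only"),
                   stats_method = "asymptotic_cc", plots = TRUE, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$metadata)) stop("config lacks `metadata`")
  if (is.null(config$out_dir)) stop("config lacks `out_dir`")
  if (length(config$selections) == 0L) stop("config lists no selections")
  config
}

#' Run the full study analysis
#'
#' Processes every section listed in the metadata table through the whole
#' chain and writes `pores.csv`, `sections.csv`, one
#' `comparisons_<selection>.csv` per canal selection, figures (polar canal
#' maps and pooled size distributions) and `manifest.json` to
#' `config$out_dir`. Any stage failure aborts with the stage name and
#' section id. Identical inputs and config produce byte-identical CSVs.
#'
#' @param config Config list (see [read_run_config()]) or a path to one.
#' @return Invisibly, a list with `pores`, `sections`, `comparisons`,
#'   `summary` and `manifest`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .default_config(config)
  md <- read_metadata(config$metadata)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fcfg <- do.call(filter_config, as.list(config$filter))
  pores_all <- list()
  sections_all <- list()
  stage_counts <- list()
  for (i in seq_len(nrow(md))) {
    sid <- paste(md$subject_id[i], md$site[i], sep = "/")
    stage <- "load"
    res <- tryCatch({
      img <- load_microradiograph(md$image_path[i], md$pixel_spacing_um[i],
                                  site = md$site[i],
                                  subject_id = md$subject_id[i],
                                  group = md$group[i])
      contours <- load_contours(md$roi_path[i])
      stage <- "analyze"
      an <- analyze_section(img, contours, fcfg,
                            threshold_mode = config$threshold_mode,
                            side = config$side)
      stage <- "morphometry"
      secs <- lapply(config$selections, function(sel) {
        section_morphometry(an$pores, an$mask, sel,
                            subject_id = md$subject_id[i], site = md$site[i],
                            group = md$group[i])
      })
      list(an = an, secs = secs)
    }, error = function(e) {
      stop("stage '", stage, "' failed for section ", sid, ": ",
           conditionMessage(e), call. = FALSE)
    })
    p <- res$an$pores
    p$boundary <- NULL
    if (nrow(p)) {
      p <- cbind(data.frame(subject_id = md$subject_id[i], site = md$site[i],
                            group = md$group[i], stringsAsFactors = FALSE),
                 p, row.names = NULL)
      ctr <- res$an$mask$centroid
      pol <- to_polar(res$an$pores, ctr, md$pixel_spacing_um[i])
      p$radius_mm <- pol$radius_mm
      p$angle_deg <- pol$angle_deg
      pores_all[[length(pores_all) + 1L]] <- p
    }
    sections_all <- c(sections_all, res$secs)
    stage_counts[[sid]] <- list(
      threshold = res$an$threshold$level,
      n_components = nrow(res$an$pores),
      n_retained = sum(res$an$pores$retained),
      ct_ar_mm2 = res$an$mask$area_mm2
    )
    message(sprintf("[%s] threshold %d, %d components, %d retained canals",
                    sid, res$an$threshold$level, nrow(res$an$pores),
                    sum(res$an$pores$retained)))
  }
  pores <- if (length(pores_all)) {
    do.call(rbind, pores_all)
  } else {
    data.frame()
  }
  sections <- do.call(rbind, sections_all)
  comparisons <- compare_groups(sections, method = config$stats_method)
  summary_tab <- group_summary(sections)

  utils::write.csv(pores, file.path(config$out_dir, "pores.csv"),
                   row.names = FALSE)
  utils::write.csv(sections, file.path(config$out_dir, "sections.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_tab, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  for (sel in unique(comparisons$selection)) {
    utils::write.csv(comparisons[comparisons$selection == sel, ],
                     file.path(config$out_dir,
                               paste0("comparisons_", sel, ".csv")),
                     row.names = FALSE)
  }
  if (isTRUE(config$plots) && nrow(pores)) {
    try(plot_polar_canals(pores, config$out_dir), silent = TRUE)
    try(plot_size_distribution(pores, config$out_dir), silent = TRUE)
  }

  cfg_path <- file.path(config$out_dir, "config_echo.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    package = "canalmorph",
    version = as.character(utils::packageVersion("canalmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_sections = nrow(md),
    stages = stage_counts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pores = pores, sections = sections,
                 comparisons = comparisons, summary = summary_tab,
                 manifest = manifest))
}

#' Polar coordinates of pores about the section centre of mass
#'
#' Radius is the Euclidean pixel distance to the cortical-mask centroid
#' scaled to mm; angle is measured in degrees from anatomical top (0 deg,
#' the image's upward direction) increasing clockwise, in `[0, 360)`. An
#' `orientation_deg` offset rotates the zero direction to match a section's
#' mounting.
#'
#' @param records Pore records with `x_px`, `y_px`.
#' @param centroid Mask centroid `c(x, y)` in pixel coordinates.
#' @param pixel_spacing_um Pixel edge length, um.
#' @param orientation_deg Clockwise offset added to the angle.
#' @return Data frame with `id`, `radius_mm`, `angle_deg`, `canal_class`.
#' @export
to_polar <- function(records, centroid, pixel_spacing_um,
                     orientation_deg = 0) {
  dx <- records$x_px - centroid[[1]]
  dy <- records$y_px - centroid[[2]]
  r_mm <- sqrt(dx^2 + dy^2) * pixel_spacing_um / 1e3
  # y grows downward, so "up" is -y; clockwise from up means +x is 90 deg
  ang <- (atan2(dx, -dy) * 180 / pi + orientation_deg) %% 360
  data.frame(id = records$id, radius_mm = r_mm, angle_deg = ang,
             canal_class = records$canal_class, stringsAsFactors = FALSE)
}

#' Inverse of [to_polar()]
#'
#' @param polar Data frame with `radius_mm`, `angle_deg`.
#' @inheritParams to_polar
#' @return Data frame with `x_px`, `y_px`.
#' @export
from_polar <- function(polar, centroid, pixel_spacing_um,
                       orientation_deg = 0) {
  th <- (polar$angle_deg - orientation_deg) * pi / 180
  r_px <- polar$radius_mm * 1e3 / pixel_spacing_um
  data.frame(x_px = centroid[[1]] + r_px * sin(th),
             y_px = centroid[[2]] - r_px * cos(th))
}

#' Polar map of the largest canals per site
#'
#' One panel per site, cutting cones drawn at their polar position about the
#' section centroid, coloured by subject, faceted by group.
#'
#' @param pores Combined pore table from [run_study()] (needs `radius_mm`,
#'   `angle_deg`).
#' @param out_dir Output directory for `polar_<site>.png`.
#' @return Invisibly, the paths written.
#' @export
plot_polar_canals <- function(pores, out_dir) {
  paths <- character(0)
  cut <- pores[pores$retained & pores$canal_class == "cutting_cone", ]
  for (site in unique(cut$site)) {
    d <- cut[cut$site == site, ]
    if (!nrow(d)) next
    gp <- ggplot2::ggplot(d, ggplot2::aes(x = angle_deg,
                                          y = radius_mm,
                                          colour = subject_id)) +
      ggplot2::geom_point(size = 1.6, alpha = 0.8) +
      ggplot2::coord_polar(start = 0, direction = 1) +
      ggplot2::scale_x_continuous(limits = c(0, 360),
                                  breaks = c(0, 90, 180, 270)) +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(title = paste("Cutting cones:", site),
                    x = NULL, y = "radius (mm)") +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, paste0("polar_", site, ".png"))
    grDevices::png(p, width = 1200, height = 650, res = 140)
    print(gp)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Pooled canal-size distributions by group
#'
#' Canal counts summed within groups versus canal area on a log axis, one
#' panel per site, with the 0.002 and 0.04 mm^2 class boundaries marked.
#'
#' @param pores Combined pore table from [run_study()].
#' @param out_dir Output directory for `size_distribution.png`.
#' @return Invisibly, the path written.
#' @export
plot_size_distribution <- function(pores, out_dir) {
  d <- pores[pores$retained, ]
  if (!nrow(d)) return(invisible(character(0)))
  gp <- ggplot2::ggplot(d, ggplot2::aes(x = area_mm2,
                                        fill = group)) +
    ggplot2::geom_histogram(bins = 30, position = "dodge") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = c(0.002, 0.04), linetype = "dashed") +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(x = "Ca.Ar (mm^2)", y = "N.Ca") +
    ggplot2::theme_minimal()
  p <- file.path(out_dir, "size_distribution.png")
  grDevices::png(p, width = 1400, height = 900, res = 140)
  print(gp)
  grDevices::dev.off()
  invisible(p)
}
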