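# Small section specs keep the suite fast; the rib geometry (10 um spacing)
# is used wherever exact class recovery is asserted because the 0.002 mm^2
# boundary is 20 pixel-areas there, comfortably above rasterisation error.

small_spec <- function(...) {
  synthetic_section_spec(site = "rib", scale = 0.4, ...)
}

test_that("identical seeds give identical sections; different seeds differ", {
  spec <- small_spec(n_mature = 5, n_closing = 5, n_cutting = 1,
                     n_volkmann = 1, n_endosteal = 1)
  s1 <- generate_section(spec, 11)
  s2 <- generate_section(spec, 11)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_section(spec, 12)
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_section(small_spec(n_mature = 2, n_closing = 2,
                                        n_cutting = 0, n_volkmann = 0,
                                        n_endosteal = 0), 5))
  expect_identical(.Random.seed, before)
})

test_that("stamped pixel areas conserve the drawn areas within rasterisation error", {
  spec <- small_spec(n_mature = 0, n_closing = 12, n_cutting = 3,
                     n_volkmann = 0, n_endosteal = 0, noise_sd = 0)
  sec <- generate_section(spec, 21)
  tr <- sec$truth
  expect_equal(nrow(tr), 15L)  # truth count equals stamped count
  # rasterisation tolerance: 5% relative, or 5 pixel-areas for the smallest
  # canals whose digital-disc area fluctuates with sub-pixel centre position
  px_area <- (sec$image$pixel_spacing_um / 1e3)^2
  err <- abs(tr$area_px_mm2 - tr$area_mm2)
  expect_true(all(err < pmax(0.05 * tr$area_mm2, 5 * px_area)))
  # truth areas lie within their class intervals
  expect_true(all(tr$area_mm2[tr$class == "closing_cone"] > 0.002 &
                    tr$area_mm2[tr$class == "closing_cone"] <= 0.04))
  expect_true(all(tr$area_mm2[tr$class == "cutting_cone"] > 0.04))
})

test_that("a flat pore-free section yields zero canals end to end", {
  # a flat field gives a single-bin cortical histogram, whose degenerate
  # triangle threshold leaves no pixel strictly below it; a background
  # gradient without any true pores would instead be cut somewhere inside
  # the unimodal histogram, which is the thresholding failure mode uneven
  # sample thickness causes on real microradiographs
  spec <- small_spec(n_mature = 0, n_closing = 0, n_cutting = 0,
                     n_volkmann = 0, n_endosteal = 0, noise_sd = 0,
                     background_gradient = 0)
  sec <- generate_section(spec, 4)
  an <- analyze_section(sec$image, sec$contours)
  for (sel in c("combined", "cutting_only")) {
    expect_equal(section_morphometry(an$pores, an$mask, sel)$N_Ca, 0L)
  }
})

test_that("noise-free cutting cones are recovered exactly with true areas", {
  spec <- small_spec(
    n_mature = 0, n_closing = 0, n_cutting = 10, n_volkmann = 0,
    n_endosteal = 0, noise_sd = 0,
    class_areas = list(mature = c(5e-4, 1.6, 1e-4, 1.5e-3),
                       closing_cone = c(6e-3, 1.8, 2.8e-3, 3.8e-2),
                       cutting_cone = c(7e-2, 1.2, 5e-2, 1e-1))
  )
  sec <- generate_section(spec, 31)
  an <- analyze_section(sec$image, sec$contours)
  got <- an$pores[an$pores$retained, ]
  expect_equal(nrow(got), 10L)
  expect_true(all(got$canal_class == "cutting_cone"))
  # match each truth pore to the nearest recovered centroid
  px_area <- (sec$image$pixel_spacing_um / 1e3)^2
  for (i in seq_len(nrow(sec$truth))) {
    d <- sqrt((got$x_px - sec$truth$x_px[i])^2 +
                (got$y_px - sec$truth$y_px[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_lte(abs(got$area_mm2[j] - sec$truth$area_px_mm2[i]), 2 * px_area)
  }
})

test_that("elongated Volkmann-like distractors are excluded by circularity", {
  spec <- small_spec(n_mature = 0, n_closing = 0, n_cutting = 0,
                     n_volkmann = 5, n_endosteal = 0, noise_sd = 0)
  sec <- generate_section(spec, 41)
  an <- analyze_section(sec$image, sec$contours)
  expect_equal(nrow(an$pores), 5L)
  expect_true(all(grepl("circularity", an$pores$excluded_by)))
  expect_equal(sum(an$pores$retained), 0L)
})

test_that("truth-level study echoes the design and is seed-deterministic", {
  st <- generate_study(seed = 7, sites = c("rib", "tibia", "mc_metaphysis"))
  secs <- st$sections
  # design echo: 6 per group, except the dropped rested tibia
  tib_re <- secs[secs$site == "tibia" & secs$group == "rested" &
                   secs$selection == "combined", ]
  expect_equal(nrow(tib_re), 5L)
  rib_re <- secs[secs$site == "rib" & secs$group == "rested" &
                   secs$selection == "combined", ]
  expect_equal(nrow(rib_re), 6L)
  st2 <- generate_study(seed = 7, sites = c("rib", "tibia", "mc_metaphysis"))
  expect_identical(st$sections, st2$sections)
  # default calibration: rested cutting-cone density well above exercised at
  # the metacarpal metaphysis, similar in the rib
  cut <- secs[secs$selection == "cutting_only", ]
  mm <- cut[cut$site == "mc_metaphysis", ]
  expect_gt(mean(mm$N_Ca_per_Ct_Ar[mm$group == "rested"]),
            3 * mean(mm$N_Ca_per_Ct_Ar[mm$group == "exercised"]))
})

test_that("study means land near the calibrated group parameters", {
  st <- generate_study(seed = 123, sites = "mc_metaphysis")
  secs <- st$sections[st$sections$selection == "cutting_only", ]
  re <- secs[secs$group == "rested", ]
  # mean cutting-cone density within 3 SE of the calibrated 0.26 / mm^2
  se <- sd(re$N_Ca_per_Ct_Ar) / sqrt(nrow(re))
  expect_lt(abs(mean(re$N_Ca_per_Ct_Ar) - 0.26), 3 * se + 0.02)
})
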