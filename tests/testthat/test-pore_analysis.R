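test_that("labelling follows 8-connectivity with deterministic raster order", {
  g <- matrix(FALSE, 5, 5)
  g[2, 2] <- TRUE; g[3, 3] <- TRUE       # diagonal contact
  expect_length(label_pores(g), 1L)
  expect_length(label_pores(g, connectivity = 4L), 2L)
  expect_length(label_pores(matrix(FALSE, 4, 4)), 0L)

  # ordering: component starting higher in the image comes first
  g2 <- matrix(FALSE, 10, 10)
  g2[8:9, 2:3] <- TRUE
  g2[2, 7] <- TRUE
  comps <- label_pores(g2)
  first_px <- comps[[1]][1]
  expect_equal((first_px - 1L) %% 10L + 1L, 2L)  # row of topmost component
})

test_that("labelling equals a flood-fill oracle on random binary images", {
  set.seed(19)
  for (i in 1:25) {
    g <- matrix(runif(40 * 40) < 0.35, 40, 40)
    got <- canonical_components(label_pores(g))
    want <- components_from_labels(flood_label(g, 8L))
    expect_identical(got, want)
  }
})

test_that("pore measurement matches geometric oracles", {
  # single pixel at 25 um spacing: area 625 um2 = 6.25e-4 mm2
  g <- matrix(FALSE, 5, 5); g[3, 3] <- TRUE
  rec <- measure_pore(label_pores(g)[[1]], 25)
  expect_equal(rec$area_mm2, 6.25e-4)
  expect_equal(rec$eq_diameter_um, 2 * sqrt(6.25e-4 / pi) * 1e3)

  # rasterised disc r = 20 px at 10 um spacing: area near pi*(200 um)^2,
  # high circularity
  g2 <- stamp_disc(matrix(FALSE, 50, 50), 24, 24, 20)
  rec2 <- measure_pore(label_pores(g2)[[1]], 10)
  true_area <- pi * 0.2^2  # mm2
  expect_lt(abs(rec2$area_mm2 - true_area) / true_area, 0.02)
  expect_gte(rec2$circularity, 0.85)
  # pixel-count oracle: area must equal stamped count times pixel area
  expect_equal(rec2$area_mm2, sum(g2) * (10 / 1e3)^2)

  # 1 x 50 px line: strongly elongated, circularity below the 0.3 cut
  g3 <- matrix(FALSE, 5, 60); g3[3, 6:55] <- TRUE
  rec3 <- measure_pore(label_pores(g3)[[1]], 25)
  # chain-length oracle: out and back along 49 steps each way
  expect_equal(rec3$perimeter_um, 2 * 49 * 25)
  expect_lt(rec3$circularity, 0.3)
})

test_that("interior holes are filled before measurement", {
  g <- stamp_disc(matrix(FALSE, 40, 40), 19, 19, 12)
  full <- sum(g)
  g_hole <- g
  g_hole[17:21, 17:21] <- FALSE  # bone island inside the canal
  comps <- label_pores(g_hole)
  expect_length(comps, 1L)
  rec <- measure_pore(comps[[1]], 10)
  expect_equal(rec$n_px, full)   # full lumen counted
})

test_that("retention filters honour the strict area bound and flag all failures", {
  rec <- fake_records(area = c(0.001, 0.01, 0.002, 0.01, 0.001),
                      circ = c(0.9, 0.2, 0.9, 0.9, 0.2))
  out <- filter_pores(rec)
  expect_equal(out$excluded_by,
               c("min_area", "circularity", "min_area", "none",
                 "circularity;min_area"))
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  # idempotent, and flags never change measured values
  out2 <- filter_pores(out)
  expect_identical(out2, out)
  expect_identical(out$area_mm2, rec$area_mm2)
  expect_identical(out$circularity, rec$circularity)
})

test_that("canal classification partitions positive areas at the stated bounds", {
  expect_equal(classify_canal(0.05), "cutting_cone")
  expect_equal(classify_canal(0.01), "closing_cone")
  expect_equal(classify_canal(0.0015), "mature")
  # boundary conventions: inclusive below, strict above
  expect_equal(classify_canal(0.002), "mature")
  expect_equal(classify_canal(0.04), "closing_cone")
  expect_error(classify_canal(0), "positive")
  expect_error(classify_canal(-1), "positive")
  set.seed(5)
  a <- 10^runif(500, -4, 0)
  cls <- classify_canal(a)
  expect_true(all(cls %in% c("mature", "closing_cone", "cutting_cone")))
  expect_equal(sum(cls == "mature") + sum(cls == "closing_cone") +
                 sum(cls == "cutting_cone"), 500L)
})

test_that("endosteal exclusion combines the width and proximity rules", {
  # annular cortex: periosteal r=140, endosteal r=50, centre (150,150),
  # 10 um spacing
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  peri <- cbind(x = 150 + 140 * cos(th), y = 150 + 140 * sin(th))
  endo <- cbind(x = 150 + 50 * cos(th), y = 150 + 50 * sin(th))
  cs <- contour_set(peri, list(endo))
  px <- matrix(200L, 300, 300)
  m <- matrix(FALSE, 300, 300)
  m <- stamp_disc(m, 150, 50, 35)    # 700-um disc mid-cortex, far from margin
  m <- stamp_disc(m, 150, 205, 35)   # 700-um blob straddling the margin
  m <- stamp_disc(m, 212, 150, 5)    # 100-um canal adjacent to the margin
  px[m] <- 40L
  img <- microradiograph(px, 10)
  an <- analyze_section(img, cs)
  p <- an$pores[order(an$pores$y_px), ]
  expect_equal(nrow(p), 3L)
  mid <- p[1, ]          # y ~ 50
  small <- p[2, ]        # y ~ 150
  margin <- p[3, ]       # y ~ 205 (clipped by mask)
  expect_gt(mid$feret_max_um, 600)
  expect_true(mid$retained)                       # wide but far from margin
  expect_false(margin$retained)
  expect_match(margin$excluded_by, "endosteal")   # wide and touching margin
  expect_true(small$retained)                     # small canal near margin
})

test_that("measurement is independent of exclusion order", {
  rec <- fake_records(area = c(0.01, 0.05), circ = c(0.9, 0.95))
  cfg <- filter_config()
  a <- filter_pores(rec, cfg)
  expect_identical(a[, c("area_mm2", "circularity", "canal_class")],
                   rec[, c("area_mm2", "circularity", "canal_class")])
})
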