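test_that("cortical mask computes exact Ct.Ar on axis-aligned squares", {
  cs <- square_contours(side = 100, inner = c(40, 60))
  cm <- cortical_mask(cs, c(100, 100), pixel_spacing_um = 100)
  expect_equal(sum(cm$mask), 10000L - 400L)
  expect_equal(cm$area_mm2, 96)  # (10000 - 400) * 0.01 mm2
  # no endosteal polygon: full periosteal interior
  cm_full <- cortical_mask(contour_set(cs$periosteal), c(100, 100), 100)
  expect_equal(sum(cm_full$mask), 10000L)
  # centroid inside the bounding box of the mask
  expect_true(cm$centroid["x"] >= 0 && cm$centroid["x"] <= 99)
})

test_that("annulus mask pixel count matches brute-force circle containment", {
  r_out <- 200; r_in <- 100; ctr <- 220
  peri <- cbind(x = ctr + r_out * cos(seq(0, 2 * pi, length.out = 181)[-181]),
                y = ctr + r_out * sin(seq(0, 2 * pi, length.out = 181)[-181]))
  endo <- cbind(x = ctr + r_in * cos(seq(0, 2 * pi, length.out = 181)[-181]),
                y = ctr + r_in * sin(seq(0, 2 * pi, length.out = 181)[-181]))
  cm <- cortical_mask(contour_set(peri, list(endo)), c(441, 441), 25)
  # brute-force point-in-circle scan
  xs <- rep(0:440, each = 441); ys <- rep(0:440, times = 441)
  d2 <- (xs - ctr)^2 + (ys - ctr)^2
  oracle <- sum(d2 <= r_out^2 & d2 > r_in^2)
  expect_lt(abs(sum(cm$mask) - oracle) / oracle, 0.01)
  expect_lt(abs(sum(cm$mask) - pi * (r_out^2 - r_in^2)) /
              (pi * (r_out^2 - r_in^2)), 0.01)
})

test_that("Ct.Ar is invariant under translation of section plus contours", {
  cs <- square_contours(side = 60, inner = c(20, 35))
  cm1 <- cortical_mask(cs, c(80, 80), 50)
  shifted <- contour_set(
    sweep(cs$periosteal, 2, c(7, 13), "+"),
    list(sweep(cs$endosteal[[1]], 2, c(7, 13), "+"))
  )
  cm2 <- cortical_mask(shifted, c(90, 90), 50)
  expect_equal(cm1$area_mm2, cm2$area_mm2)
  expect_equal(unname(cm2$centroid - cm1$centroid), c(7, 13))
})

test_that("triangle threshold handles degenerate and constructed histograms", {
  h <- integer(256); h[78] <- 5
  expect_equal(triangle_threshold(h), 77L)  # single-bin fallback

  # convex decaying tail from a peak at bin 200
  b <- 0:200
  h2 <- integer(256); h2[b + 1] <- floor((b / 200)^3 * 1000)
  expect_equal(triangle_threshold(h2), triangle_oracle(h2))

  # mirror symmetry: threshold of the reversed histogram is 255 - threshold
  h3 <- rev(h2)
  expect_equal(triangle_threshold(h3), 255L - triangle_threshold(h2))
})

test_that("triangle threshold equals the exhaustive-distance oracle", {
  set.seed(42)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(triangle_threshold(h), as.integer(triangle_oracle(h)))
  }
})

test_that("binarisation is mask-confined and partitions masked pixels", {
  cs <- square_contours(side = 60, inner = c(25, 35))
  px <- matrix(200L, 60, 60)
  px[10:15, 10:15] <- 40L       # dark pore inside cortex
  px[28:32, 28:32] <- 10L       # dark region inside the medullary cavity
  img <- microradiograph(px, 25)
  cm <- cortical_mask(cs, c(60, 60), 25)
  pore <- binarize_pores(img, cm, level = 120, side = "pores_below")
  expect_equal(sum(pore), 36L)              # 6x6 disc only
  expect_true(all(!pore[!cm$mask]))         # outside mask always FALSE
  bone <- cm$mask & !pore
  expect_equal(sum(pore) + sum(bone), sum(cm$mask))

  # all-bone section yields zero pore pixels
  img2 <- microradiograph(matrix(200L, 60, 60), 25)
  expect_equal(sum(binarize_pores(img2, cm, 120, "pores_below")), 0L)
})

test_that("histogram mode restricts counts to the cortical region", {
  cs <- square_contours(side = 60, inner = c(25, 35))
  px <- matrix(0L, 60, 60)
  cm <- cortical_mask(cs, c(60, 60), 25)
  px[cm$mask] <- 200L
  img <- microradiograph(px, 25)
  h_roi <- intensity_histogram(img, cm)
  expect_equal(sum(h_roi), sum(cm$mask))
  expect_equal(h_roi[201], sum(cm$mask))
  h_full <- intensity_histogram(img)
  expect_equal(sum(h_full), 3600L)
})
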