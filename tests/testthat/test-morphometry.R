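test_that("diameter/area conversions evaluate their closed forms", {
  expect_equal(canal_diameter(0), 0)
  expect_equal(round(canal_diameter(0.002), 2), 50.46)
  expect_equal(round(canal_diameter(0.04), 2), 225.68)
  expect_error(canal_diameter(-1), ">= 0")

  expect_equal(area_cutoff_from_diameter(50), 0.002)
  expect_equal(area_cutoff_from_diameter(225), 0.04)
  expect_equal(area_cutoff_from_diameter(0), 0)

  # round trip: the class boundaries are mutual inverses up to the reported
  # precision
  expect_equal(area_cutoff_from_diameter(canal_diameter(0.002)), 0.002)
  expect_equal(area_cutoff_from_diameter(canal_diameter(0.04)), 0.04)
})

test_that("minimum resolvable diameter is the one-pixel equivalent circle", {
  expect_equal(min_resolvable_diameter(10.0), 11.28)
  expect_equal(min_resolvable_diameter(25.0), 28.21)
  expect_equal(min_resolvable_diameter(16.7), 18.84)
  # homogeneity f(k s) = k f(s), up to the 2-decimal rounding
  s <- c(5, 10, 20, 33)
  expect_equal(min_resolvable_diameter(3 * s), 3 * (2 * s / sqrt(pi)),
               tolerance = 1e-3)
})

test_that("section morphometry computes counts, totals and exact ratios", {
  empty <- fake_records(numeric(0), numeric(0))
  empty <- filter_pores(empty)
  m0 <- section_morphometry(empty, 80, "combined")
  expect_equal(m0$N_Ca, 0L)
  expect_equal(m0$Tt_Ca_Ar_mm2, 0)
  expect_equal(m0$N_Ca_per_Ct_Ar, 0)

  rec <- filter_pores(fake_records(area = c(0.05, 0.05, 0.01),
                                   circ = c(0.9, 0.9, 0.9)))
  m_cut <- section_morphometry(rec, 80, "cutting_only")
  expect_equal(m_cut$N_Ca, 2L)
  expect_equal(m_cut$N_Ca_per_Ct_Ar, 0.025)
  expect_equal(m_cut$Tt_Ca_Ar_per_Ct_Ar, 0.00125)
  m_comb <- section_morphometry(rec, 80, "combined")
  expect_equal(m_comb$N_Ca, 3L)
  # ratios equal their quotients exactly
  expect_identical(m_comb$Tt_Ca_Ar_per_Ct_Ar, m_comb$Tt_Ca_Ar_mm2 / 80)
  expect_error(section_morphometry(rec, 0, "combined"), "positive")
})

test_that("total canal area is additive over any partition of the records", {
  set.seed(3)
  rec <- filter_pores(fake_records(area = runif(30, 0.003, 0.09),
                                   circ = runif(30, 0.5, 1)))
  whole <- section_morphometry(rec, 50, "combined")$Tt_Ca_Ar_mm2
  split_at <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  a <- section_morphometry(rec[split_at, ], 50, "combined")$Tt_Ca_Ar_mm2
  b <- section_morphometry(rec[!split_at, ], 50, "combined")$Tt_Ca_Ar_mm2
  expect_equal(a + b, whole)
})

test_that("size histogram uses right-open bins and sums across sections", {
  rec <- filter_pores(fake_records(area = c(0.01, 0.02, 0.02, 0.035),
                                   circ = rep(0.9, 4)))
  h <- size_histogram(rec, edges = c(0.01, 0.02, 0.03, 0.04))
  # 0.01 and 0.02 fall in the bins they open, not the ones they close
  expect_equal(h$count, c(1L, 2L, 1L))
  expect_error(size_histogram(rec, c(0.04, 0.01)), "increasing")
  none <- size_histogram(filter_pores(fake_records(numeric(0), numeric(0))),
                         c(0.002, 0.01, 0.1))
  expect_equal(none$count, c(0L, 0L))
  edges <- log_area_edges(0.1)
  expect_length(edges, 31L)
  expect_equal(edges[1], 0.002)
})

test_that("group summary reports mean, sample SD and the degenerate flag", {
  secs <- rbind(
    data.frame(subject_id = c("a", "b", "c"), site = "rib",
               group = "exercised", selection = "combined",
               Ct_Ar_mm2 = c(1, 2, 3), N_Ca = 1L, Tt_Ca_Ar_mm2 = 0,
               N_Ca_per_Ct_Ar = 0, Tt_Ca_Ar_per_Ct_Ar = 0),
    data.frame(subject_id = "d", site = "rib", group = "rested",
               selection = "combined", Ct_Ar_mm2 = 5, N_Ca = 1L,
               Tt_Ca_Ar_mm2 = 0, N_Ca_per_Ct_Ar = 0, Tt_Ca_Ar_per_Ct_Ar = 0)
  )
  gs <- group_summary(secs, indices = "Ct_Ar_mm2")
  ex <- gs[gs$group == "exercised", ]
  expect_equal(ex$mean, 2)
  expect_equal(ex$sd, 1)
  expect_true(ex$sd_defined)
  re <- gs[gs$group == "rested", ]
  expect_equal(re$sd, 0)
  expect_false(re$sd_defined)
})
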