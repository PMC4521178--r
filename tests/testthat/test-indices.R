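test_that("HOMA indices match hand arithmetic and guard their domains", {
  expect_equal(homa_ir(5, 4.5), 1)
  expect_equal(homa_ir(4.85, 4.41), 4.85 * 4.41 / 22.5)
  expect_equal(round(homa_ir(4.85, 4.41), 4), 0.9506)
  expect_equal(round(homa_ir(7.54, 4.12), 4), 1.3807)
  expect_equal(homa_b(1, 4.5), 20)
  expect_equal(round(homa_b(4.85, 4.41), 2), 106.59)
  expect_error(homa_b(5, 3.5), "3.5")
  expect_error(homa_ir(-1, 4), "positive")
})

test_that("clamp sensitivity index normalizes by lean mass and insulin", {
  expect_equal(isi_clamp(1, 1, 1, scale = 1), 1)
  expect_equal(round(isi_clamp(560, 56, 70), 2), 14.29)
  # doubling steady-state insulin halves the index
  expect_equal(isi_clamp(560, 56, 140), isi_clamp(560, 56, 70) / 2)
  expect_error(isi_clamp(0, 56, 70), "positive")
})

test_that("composite sensitivity index follows the four-term root", {
  expect_equal(matsuda_isi(4, 5, 100, 50000), 1) # product 1e8, sqrt = 1e4
  expect_equal(round(matsuda_isi(4.41, 4.85, 157, 11138), 3), 1.635)
  # rescaling all insulin quantities by c scales the index by 1/c
  c_ <- 3.7
  expect_equal(matsuda_isi(4.41, 4.85 * c_, 157, 11138 * c_),
               matsuda_isi(4.41, 4.85, 157, 11138) / c_)
  # alternative grouping: root over the fasting product only
  expect_equal(matsuda_isi(4, 4, 10, 10, grouping = "fasting_only"),
               10000 / (4 * 100))
  # the mean-concentration variant is a separate operation
  expect_equal(matsuda_isi_conventional(4, 5, 5, 100),
               10000 / sqrt(4 * 5 * 5 * 100))
  expect_error(matsuda_isi(4, 5, -3, 10), "positive")
})

test_that("insulinogenic index uses the 0-30 min rises and flags degeneracy", {
  grid <- c(0, 30, 60)
  expect_equal(insulinogenic_index(grid, c(4.41, 6.5, 5), c(4.85, 40, 30)),
               35.15 / 2.09)
  expect_equal(insulinogenic_index(grid, c(4, 6, 5), c(10, 10, 12)), 0)
  expect_true(is.na(insulinogenic_index(grid, c(4, 4, 5), c(10, 30, 12))))
  expect_error(insulinogenic_index(c(0, 60, 120), c(4, 6, 5), c(10, 30, 12)),
               "30 min")
})

test_that("secretion index is the AUC ratio and scales with insulin", {
  grid <- c(0, 30, 60, 90, 120, 240)
  expect_equal(insulin_secretion_index(grid, rep(5, 6), rep(10, 6)), 2)
  g <- c(4.2, 6, 6.5, 5.8, 5, 4.3)
  i <- c(5, 35, 40, 30, 18, 6)
  expect_equal(insulin_secretion_index(grid, g, 3 * i),
               3 * insulin_secretion_index(grid, g, i))
  expect_equal(insulin_secretion_index(grid, g, i),
               dense_auc(grid, i) / dense_auc(grid, g), tolerance = 1e-6)
})

test_that("oral disposition index is the exact sensitivity-secretion product", {
  expect_equal(oral_di(1, 7.3), 7.3)
  expect_equal(oral_di(2.70, 10.5), 28.35)
  expect_error(oral_di(0, 2), "positive")
})

test_that("fasting insulin moves HOMA-IR and the Matsuda index in opposite directions", {
  set.seed(31)
  for (rep in 1:50) {
    fg <- runif(1, 3.6, 6.5); fi <- runif(1, 2, 20)
    iaucg <- runif(1, 50, 400); iauci <- runif(1, 2000, 20000)
    step <- runif(1, 0.1, 3)
    expect_gt(homa_ir(fi + step, fg), homa_ir(fi, fg))
    expect_lt(matsuda_isi(fg, fi + step, iaucg, iauci),
              matsuda_isi(fg, fi, iaucg, iauci))
  }
})
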