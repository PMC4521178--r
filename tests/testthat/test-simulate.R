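test_that("simulation is deterministic under a seed and leaves the RNG alone", {
  set.seed(99); before <- runif(1)
  co1 <- simulate_cohort(cohort_presets(), seed = 17)
  co2 <- simulate_cohort(cohort_presets(), seed = 17)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$meal, co2$meal)
  expect_identical(co1$clamp, co2$clamp)
  expect_identical(co1$ground_truth, co2$ground_truth)
  co3 <- simulate_cohort(cohort_presets(), seed = 18)
  expect_false(identical(co1$subjects, co3$subjects))
  # the caller's RNG stream is untouched by the simulator
  set.seed(99); expect_identical(runif(1), before)
  # written CSVs are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a noiseless subject lies exactly on its disposition hyperbola", {
  cfg <- group_config("solo", 4, s_mean = 12, s_sd = 0, k = 130, delta = 1,
                      fg_mean = 4.2, fg_sd = 0, fi_coupling = 72, sigma_fi = 0,
                      age_mean = 26, age_sd = 0, lean_mass_sd = 0,
                      sigma_log = 0, sigma_amp = 0)
  co <- simulate_cohort(cfg, seed = 3)
  gt <- co$ground_truth
  expect_equal(gt$B_true, 130 / gt$S_true)
  expect_lt(max(abs(off_curve_score(gt$S_true, gt$B_true, 130))), 1e-12)
  # the clamp index reconstructs true sensitivity exactly
  panel <- compute_indices(co)
  expect_equal(panel$isi_clamp, gt$S_true, tolerance = 1e-12)
})

test_that("generated meal series always satisfy the series invariants", {
  for (seed in 1:5) {
    co <- simulate_cohort(null_preset(n = 8), seed = seed)
    expect_s3_class(co, "glycohort") # new_cohort re-validates everything
    by_subj <- split(co$meal, co$meal$subject_id)
    for (m in by_subj) {
      expect_equal(sort(m$time_min), c(0, 30, 60, 90, 120, 240))
      expect_true(all(m$glucose_mmol_l > 0 & m$insulin_mU_l > 0))
    }
    expect_true(all(co$subjects$fasting_glucose_mmol_l < 7))
  }
})

test_that("group-mean clamp sensitivity tracks its preset target across seeds", {
  targets <- c(chinese_like = 14.2, malay_like = 12.9, indian_like = 8.8)
  ses <- c(chinese_like = 1.2, malay_like = 1.2, indian_like = 0.6)
  hits <- setNames(numeric(3), names(targets)); n_seeds <- 100L
  for (seed in seq_len(n_seeds)) {
    co <- simulate_cohort(cohort_presets(), seed = seed)
    m <- tapply(co$ground_truth$S_true, co$ground_truth$group, mean)
    ok <- abs(m[names(targets)] - targets) <= 2 * ses
    hits <- hits + ok
  }
  for (g in names(targets)) expect_gte(hits[[g]] / n_seeds, 0.9)
})

test_that("impossible configurations are rejected before sampling", {
  expect_error(group_config("x", 0, s_mean = 10, s_sd = 1, k = 100,
                            fg_mean = 4, fg_sd = 0.3, fi_coupling = 70,
                            age_mean = 25, age_sd = 2), "n must be")
  expect_error(group_config("x", 5, s_mean = 10, s_sd = 1, k = 100, delta = 1.4,
                            fg_mean = 4, fg_sd = 0.3, fi_coupling = 70,
                            age_mean = 25, age_sd = 2), "delta")
  expect_error(group_config("x", 5, s_mean = 10, s_sd = 1, k = 100,
                            fg_mean = 8, fg_sd = 0.3, fi_coupling = 70,
                            age_mean = 25, age_sd = 2), "normoglycemic")
  expect_error(group_config("x", 5, s_mean = -10, s_sd = 1, k = 100,
                            fg_mean = 4, fg_sd = 0.3, fi_coupling = 70,
                            age_mean = 25, age_sd = 2), "positive")
})
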