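test_that("points exactly on B = 12/S give k = 12 under both scales", {
  d <- tibble::tibble(S = c(2, 4, 6, 10), B = 12 / c(2, 4, 6, 10))
  expect_equal(fit_di_hyperbola(d, S, B, scale = "log")$k, 12)
  expect_equal(fit_di_hyperbola(d, S, B, scale = "linear")$k, 12)
  fit <- fit_di_hyperbola(d, S, B)
  expect_equal(fit$residuals$score, rep(0, 4))
})

test_that("log-scale estimator is the geometric mean of products, with mean-zero residuals", {
  set.seed(41)
  for (rep in 1:10) {
    d <- tibble::tibble(S = rlnorm(40, 2, 0.4), B = rlnorm(40, 1, 0.5))
    fit <- fit_di_hyperbola(d, S, B, scale = "log")
    expect_equal(fit$k, exp(mean(log(d$S * d$B))))
    expect_lt(abs(mean(fit$residuals$score)), 1e-12)
  }
})

test_that("both estimators agree with a brute-force grid search over k", {
  set.seed(42)
  d <- tibble::tibble(S = rlnorm(60, 2.5, 0.3),
                      B = 18 / rlnorm(60, 2.5, 0.3) * exp(rnorm(60, 0, 0.25)))
  grid_min <- function(loss) {
    ks <- seq(5, 60, by = 0.001)
    ks[which.min(vapply(ks, loss, numeric(1)))]
  }
  k_log <- fit_di_hyperbola(d, S, B, scale = "log")$k
  k_log_grid <- grid_min(function(k) sum((log(d$B) - (log(k) - log(d$S)))^2))
  expect_lt(abs(k_log / k_log_grid - 1), 1e-3) # grid resolution bound
  k_lin <- fit_di_hyperbola(d, S, B, scale = "linear")$k
  k_lin_grid <- grid_min(function(k) sum((d$B - k / d$S)^2))
  expect_lt(abs(k_lin / k_lin_grid - 1), 1e-3)
})

test_that("rescaling secretion rescales k exactly (equivariance)", {
  set.seed(43)
  d <- tibble::tibble(S = rlnorm(30, 2, 0.4), B = rlnorm(30, 1.5, 0.4))
  for (scale in c("log", "linear")) {
    k1 <- fit_di_hyperbola(d, S, B, scale = scale)$k
    d2 <- dplyr::mutate(d, B = 2.5 * B)
    expect_equal(fit_di_hyperbola(d2, S, B, scale = scale)$k, 2.5 * k1)
  }
})

test_that("off-curve scores are log ratios against the curve", {
  d <- tibble::tibble(S = c(2, 4, 6), B = 12 / c(2, 4, 6))
  fit <- fit_di_hyperbola(d, S, B)
  expect_equal(off_curve_score(4, 3, fit), 0)
  expect_equal(off_curve_score(4, 1.5, fit), -log(2))
  expect_error(off_curve_score(-1, 3, fit), "positive")
})

test_that("group placement ranks groups by compensation and ignores row order", {
  set.seed(44)
  n <- 60
  d <- tibble::tibble(
    group = rep(c("ref1", "deficit", "ref2"), each = n),
    S = rlnorm(3 * n, 2.4, 0.3))
  delta <- ifelse(d$group == "deficit", 0.6, 1)
  d$B <- delta * 130 / d$S * exp(rnorm(3 * n, 0, 0.2))
  pl <- place_groups(d, S, B, group)
  expect_equal(pl$group[pl$rank_score == 1], "deficit")
  pl_perm <- place_groups(d[sample(nrow(d)), ], S, B, group)
  expect_equal(dplyr::arrange(pl_perm, group), dplyr::arrange(pl, group))
  # scoring against an external reference curve shifts scores, not ranks
  pl_ref <- place_groups(d, S, B, group, fit = 130)
  expect_equal(pl_ref$rank_score, pl$rank_score[match(pl_ref$group, pl$group)])
})

test_that("single on-curve group scores zero against its own fit", {
  d <- tibble::tibble(group = "only", S = c(2, 4, 8), B = 20 / c(2, 4, 8))
  pl <- place_groups(d, S, B, group)
  expect_equal(pl$mean_score, 0)
})

test_that("invalid inputs are rejected", {
  expect_error(fit_di_hyperbola(tibble::tibble(S = c(1, 2), B = c(1, 2)), S, B),
               "at least 3")
  expect_error(fit_di_hyperbola(tibble::tibble(S = c(1, 2, -1), B = c(1, 2, 3)),
                                S, B), "positive")
})

test_that("tidy and glance expose the fit as tibbles", {
  d <- tibble::tibble(S = c(2, 4, 6, 8), B = 12 / c(2, 4, 6, 8))
  fit <- fit_di_hyperbola(d, S, B)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("subject_id", "sensitivity", "secretion", "score"))
  gl <- glance(fit)
  expect_equal(gl$k, 12)
  expect_equal(gl$n, 4L)
})
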