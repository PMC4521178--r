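make_long <- function(ymat, groups, times) {
  tibble::tibble(
    subject_id = rep(sprintf("s%02d", seq_len(nrow(ymat))), each = length(times)),
    group = rep(groups, each = length(times)),
    time = rep(times, nrow(ymat)),
    y = as.vector(t(ymat))
  )
}

test_that("interaction F on a 2x2 design equals the squared t on difference scores", {
  set.seed(61)
  n1 <- 6; n2 <- 8
  y1 <- cbind(rnorm(n1, 5), rnorm(n1, 7))
  y2 <- cbind(rnorm(n2, 5), rnorm(n2, 8.5))
  d <- make_long(rbind(y1, y2), rep(c("a", "b"), c(n1, n2)), c(0, 30))
  res <- rm_anova(d, y, time, group, subject_id)
  diffs1 <- y1[, 2] - y1[, 1]; diffs2 <- y2[, 2] - y2[, 1]
  t_or <- t.test(diffs1, diffs2, var.equal = TRUE)$statistic
  f_int <- res$table$statistic[res$table$term == "time:group"]
  expect_equal(f_int, unname(t_or^2), tolerance = 1e-8)
})

test_that("sums of squares partition exactly", {
  set.seed(62)
  n_j <- c(5, 7, 9); T_ <- 6
  ymat <- matrix(rnorm(sum(n_j) * T_, 5, 2), ncol = T_) +
    rnorm(sum(n_j), 0, 1.5) # subject intercepts
  d <- make_long(ymat, rep(c("a", "b", "c"), n_j), seq_len(T_) * 30)
  res <- rm_anova(d, y, time, group, subject_id)
  ss <- res$ss_check
  expect_equal(ss[["between_subjects"]] + ss[["within"]], ss[["total"]],
               tolerance = 1e-8)
  expect_equal(ss[["time"]] + ss[["interaction"]] + ss[["error"]],
               ss[["within"]], tolerance = 1e-8)
})

test_that("the whole table matches the base-R split-plot aov on unbalanced groups", {
  set.seed(63)
  n_j <- c(6, 9, 12); T_ <- 4
  grp <- rep(c("a", "b", "c"), n_j)
  ymat <- matrix(rnorm(sum(n_j) * T_, 5, 1), ncol = T_)
  ymat <- ymat + outer(ifelse(grp == "b", 1, 0), c(0, 0.5, 1, 1.5)) # interaction
  d <- make_long(ymat, grp, c(0, 30, 60, 90))
  res <- rm_anova(d, y, time, group, subject_id)
  ref <- summary(stats::aov(y ~ factor(group) * factor(time) +
                              Error(subject_id), data = d))
  between <- ref$`Error: subject_id`[[1]]
  within <- ref$`Error: Within`[[1]]
  tab <- res$table
  expect_equal(tab$statistic[tab$term == "group"], between$`F value`[1],
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "time"], within$`F value`[1],
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "time:group"], within$`F value`[2],
               tolerance = 1e-8)
  expect_equal(tab$df, c(2, sum(n_j) - 3, 3, 6, (sum(n_j) - 3) * 3))
})

test_that("Greenhouse-Geisser epsilon stays in its admissible range and scales df", {
  set.seed(64)
  T_ <- 5
  ymat <- matrix(rnorm(30 * T_), ncol = T_)
  ymat[, 1] <- ymat[, 1] * 3 # break sphericity
  d <- make_long(ymat, rep(c("a", "b"), each = 15), seq_len(T_))
  res <- rm_anova(d, y, time, group, subject_id)
  expect_gt(res$epsilon, 1 / (T_ - 1))
  expect_lte(res$epsilon, 1)
  tab <- res$table
  p_int <- tab$p_value[tab$term == "time:group"]
  f_int <- tab$statistic[tab$term == "time:group"]
  expect_equal(tab$p_gg[tab$term == "time:group"],
               pf(f_int, (2 - 1) * (T_ - 1) * res$epsilon,
                  (30 - 2) * (T_ - 1) * res$epsilon, lower.tail = FALSE))
})

test_that("a subject-constant covariate adjusts only the between-subject stratum", {
  set.seed(65)
  n <- 20; T_ <- 3
  age <- rnorm(n, 26, 4)
  ymat <- matrix(rnorm(n * T_), ncol = T_) + 0.2 * age
  d <- make_long(ymat, rep(c("a", "b"), each = n / 2), c(0, 30, 60))
  d$age <- rep(age, each = T_)
  unadj <- rm_anova(d, y, time, group, subject_id)
  adj <- rm_anova(d, y, time, group, subject_id, covariate = age)
  w <- c("time", "time:group")
  expect_equal(adj$table$statistic[adj$table$term %in% w],
               unadj$table$statistic[unadj$table$term %in% w])
  expect_false(is.null(adj$group_adjusted))
  expect_false(isTRUE(all.equal(adj$group_adjusted$f_statistic,
                                unadj$table$statistic[1])))
})

test_that("missing cells are refused rather than imputed", {
  d <- make_long(matrix(rnorm(12), ncol = 2), rep(c("a", "b"), each = 3), c(0, 30))
  expect_error(rm_anova(d[-1, ], y, time, group, subject_id), "every timepoint")
})

test_that("excursion comparison on a simulated cohort returns interaction and pairwise tests", {
  co <- simulate_cohort(cohort_presets(), seed = 5)
  res <- compare_excursion(co, "glucose")
  gl <- glance(res)
  expect_true(is.finite(gl$f_interaction))
  expect_equal(gl$n, 59L)
  expect_equal(gl$n_timepoints, 5L) # post-baseline grid
  expect_true(all(res$pairwise_by_time$p_bonferroni <= 1))
  expect_equal(sort(unique(res$pairwise_by_time$time)), c(30, 60, 90, 120, 240))
})
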