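#' Split-plot repeated-measures ANOVA with a time-by-group interaction
#'
#' Classic univariate mixed between-within ANOVA by sums-of-squares
#' decomposition: group is the between-subject factor, time the
#' within-subject factor. Every subject must have a value at every timepoint
#' (no imputation; subjects with missing cells must be excluded by the
#' caller). Group sizes may differ; the weighted (cell-mean) decomposition
#' is used, under which the within-subject partition
#' `SS_within = SS_time + SS_interaction + SS_error` is exact.
#'
#' Sphericity of the within-subject covariance is not assumed silently: the
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance matrix and the time and interaction tests are reported both
#' uncorrected and with epsilon-scaled degrees of freedom.
#'
#' When a covariate is supplied it enters the between-subject stratum only
#' (classic split-plot ANCOVA on subject means). A subject-constant
#' covariate cannot alter the within-subject stratum, so the time and
#' interaction tests are identical with and without adjustment; the group
#' test is reported both ways.
#'
#' @param data Long-format data frame: one row per subject x timepoint.
#' @param value,time,subject Columns (tidy-eval) holding the measurement,
#'   the timepoint and the subject id.
#' @param group Between-subject factor column (tidy-eval).
#' @param covariate Optional subject-level numeric covariate (tidy-eval);
#'   must be constant within subject.
#' @return Object of class `rm_anova` with the ANOVA table, epsilon,
#'   adjusted/unadjusted group tests and per-timepoint pairwise contrasts;
#'   see [tidy.rm_anova()].
#' @export
rm_anova <- function(data, value, time, group = group, subject = subject_id,
                     covariate = NULL) {
  v_quo <- enquo(value); t_quo <- enquo(time); g_quo <- enquo(group)
  s_quo <- enquo(subject); c_quo <- enquo(covariate)
  d <- tibble(y = dplyr::pull(data, !!v_quo),
              t = dplyr::pull(data, !!t_quo),
              g = factor(dplyr::pull(data, !!g_quo)),
              id = as.character(dplyr::pull(data, !!s_quo)))
  has_cov <- !quo_is_null(c_quo)
  if (has_cov) d$x <- dplyr::pull(data, !!c_quo)
  if (anyNA(d)) abort("missing cells: exclude incomplete subjects before calling rm_anova (no imputation)")

  times <- sort(unique(d$t))
  T_ <- length(times)
  # complete-grid check, and reshape to subject x time matrix
  wide <- d %>% select(all_of(c("id", "g", "t", "y"))) %>%
    tidyr::pivot_wider(names_from = "t", values_from = "y")
  ymat <- as.matrix(wide[, as.character(times)])
  if (anyNA(ymat) || nrow(d) != nrow(wide) * T_) {
    abort("every subject needs a value at every timepoint: exclude incomplete subjects (no imputation)")
  }
  gfac <- droplevels(wide$g)
  J <- nlevels(gfac)
  if (J < 2) abort("need at least 2 groups")
  N <- nrow(ymat)
  n_j <- as.integer(table(gfac))

  grand <- mean(ymat)
  subj_means <- rowMeans(ymat)
  time_means <- colMeans(ymat)
  grp_means <- as.numeric(tapply(subj_means, gfac, mean))
  cell_means <- apply(ymat, 2, function(col) tapply(col, gfac, mean))  # J x T
  if (J == 1) cell_means <- matrix(cell_means, nrow = 1)

  ss_total <- sum((ymat - grand)^2)
  ss_bs <- T_ * sum((subj_means - grand)^2)
  ss_group <- T_ * sum(n_j * (grp_means - grand)^2)
  ss_subj <- ss_bs - ss_group
  ss_time <- N * sum((time_means - grand)^2)
  ss_int <- sum(n_j * (cell_means - outer(grp_means, rep(1, T_)) -
                         outer(rep(1, J), time_means) + grand)^2)
  resid_mat <- ymat - subj_means - cell_means[as.integer(gfac), , drop = FALSE] +
    grp_means[as.integer(gfac)]
  ss_err <- sum(resid_mat^2)
  ss_within <- ss_total - ss_bs

  df_group <- J - 1; df_subj <- N - J
  df_time <- T_ - 1; df_int <- (J - 1) * (T_ - 1); df_err <- (N - J) * (T_ - 1)
  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_subj, df_subj)
  f_time <- ms(ss_time, df_time) / ms(ss_err, df_err)
  f_int <- ms(ss_int, df_int) / ms(ss_err, df_err)

  eps <- gg_epsilon(ymat, gfac)

  table <- tibble(
    term = c("group", "subjects_within_group", "time", "time:group", "error_within"),
    df = c(df_group, df_subj, df_time, df_int, df_err),
    sumsq = c(ss_group, ss_subj, ss_time, ss_int, ss_err),
    statistic = c(f_group, NA, f_time, f_int, NA),
    p_value = c(pf(f_group, df_group, df_subj, lower.tail = FALSE), NA,
                pf(f_time, df_time, df_err, lower.tail = FALSE),
                pf(f_int, df_int, df_err, lower.tail = FALSE), NA),
    p_gg = c(NA, NA,
             pf(f_time, df_time * eps, df_err * eps, lower.tail = FALSE),
             pf(f_int, df_int * eps, df_err * eps, lower.tail = FALSE), NA)
  )

  # age-adjusted between-subject test: ANCOVA on subject means
  group_adjusted <- NULL
  if (has_cov) {
    cov_by_subj <- d %>% distinct(.data$id, .data$x)
    if (anyDuplicated(cov_by_subj$id)) {
      abort("covariate must be constant within subject")
    }
    sm <- tibble(id = wide$id, g = gfac, m = subj_means) %>%
      left_join(cov_by_subj, by = "id")
    group_adjusted <- compare_groups(sm, m, g, covariate = x)
  }

  pairwise_by_time <- pairwise_at_timepoints(d)

  structure(
    list(table = table, epsilon = eps, n_per_group = setNames(n_j, levels(gfac)),
         times = times, covariate = if (has_cov) as_name(c_quo) else NA_character_,
         group_adjusted = group_adjusted,
         pairwise_by_time = pairwise_by_time,
         ss_check = c(total = ss_total, between_subjects = ss_bs,
                      within = ss_within, time = ss_time,
                      interaction = ss_int, error = ss_err)),
    class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance
gg_epsilon <- function(ymat, gfac) {
  T_ <- ncol(ymat)
  J <- nlevels(gfac)
  pooled <- matrix(0, T_, T_)
  for (lev in levels(gfac)) {
    rows <- ymat[gfac == lev, , drop = FALSE]
    if (nrow(rows) > 1) pooled <- pooled + stats::cov(rows) * (nrow(rows) - 1)
  }
  pooled <- pooled / (nrow(ymat) - J)
  C <- diag(T_) - 1 / T_
  Sc <- C %*% pooled %*% C
  eps <- sum(diag(Sc))^2 / ((T_ - 1) * sum(Sc^2))
  min(1, max(1 / (T_ - 1), eps))
}

# pairwise group contrasts at each timepoint, pooled within-timepoint error,
# Bonferroni over pairs only
pairwise_at_timepoints <- function(d) {
  purrr::map_dfr(sort(unique(d$t)), function(tp) {
    dt <- d[d$t == tp, ]
    res <- tryCatch(compare_groups(dt, y, g), error = function(e) NULL)
    if (is.null(res)) return(tibble())
    mutate(tidy(res), time = tp, .before = 1)
  })
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> split-plot repeated-measures ANOVA\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n_per_group), x$n_per_group),
                    collapse = ", ")))
  print(x$table)
  cat(sprintf("  Greenhouse-Geisser epsilon = %.3f\n", x$epsilon))
  if (!is.null(x$group_adjusted)) {
    cat(sprintf("  group test adjusted for %s: F = %.4g, p = %.4g\n",
                x$covariate, x$group_adjusted$f_statistic,
                x$group_adjusted$p_value))
  }
  invisible(x)
}

#' Tidy methods for repeated-measures ANOVA results
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return `tidy()`: the ANOVA table (term, df, sums of squares, F,
#'   uncorrected p and Greenhouse-Geisser-corrected p). `glance()`: one row
#'   with the interaction test, epsilon and sample sizes.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  int <- x$table[x$table$term == "time:group", ]
  tibble(f_interaction = int$statistic, p_interaction = int$p_value,
         p_interaction_gg = int$p_gg, epsilon = x$epsilon,
         n = sum(x$n_per_group), n_groups = length(x$n_per_group),
         n_timepoints = length(x$times), covariate = x$covariate,
         p_group_adjusted = if (is.null(x$group_adjusted)) NA_real_
         else x$group_adjusted$p_value)
}

#' Post-meal excursion comparison between groups
#'
#' Builds the incremental change from baseline (value at each post-baseline
#' timepoint minus the fasting value) for every subject and runs the
#' split-plot repeated-measures ANOVA with group as the between-subject
#' factor, time as the within-subject factor, and (by default) age as a
#' between-subject covariate. Subjects without a complete series on the
#' common grid are excluded with a warning.
#'
#' @param cohort A `glycohort` with a meal table.
#' @param signal `"glucose"` or `"insulin"`.
#' @param adjust_for_age Include `age_years` as the between-subject
#'   covariate (default `TRUE`).
#' @return An `rm_anova` object.
#' @export
compare_excursion <- function(cohort, signal = c("glucose", "insulin"),
                              adjust_for_age = TRUE) {
  stopifnot(inherits(cohort, "glycohort"))
  if (is.null(cohort$meal)) abort("cohort has no meal series")
  signal <- match.arg(signal)
  col <- if (signal == "glucose") "glucose_mmol_l" else "insulin_mU_l"

  grid <- sort(unique(cohort$meal$time_min))
  deltas <- cohort$meal %>%
    select(all_of(c("subject_id", "time_min", col))) %>%
    rename(value = all_of(col)) %>%
    group_by(.data$subject_id) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    filter(dplyr::n() == length(grid)) %>%
    mutate(delta = .data$value - .data$value[1]) %>%
    ungroup() %>%
    filter(.data$time_min > 0)
  dropped <- setdiff(unique(cohort$meal$subject_id), unique(deltas$subject_id))
  if (length(dropped)) {
    warn(sprintf("subjects without a complete series excluded: %s",
                 paste(dropped, collapse = ", ")))
  }
  deltas <- deltas %>%
    left_join(select(cohort$subjects, all_of(c("subject_id", "group", "age_years"))),
              by = "subject_id")
  if (adjust_for_age) {
    rm_anova(deltas, value = delta, time = time_min, group = group,
             subject = subject_id, covariate = age_years)
  } else {
    rm_anova(deltas, value = delta, time = time_min, group = group,
             subject = subject_id)
  }
}

#' Plot mean post-meal excursions by group
#'
#' Mean incremental change from baseline per group with standard-error bars,
#' mirroring how post-meal glycemic excursions are usually displayed.
#'
#' @inheritParams compare_excursion
#' @return A ggplot object.
#' @export
plot_excursion <- function(cohort, signal = c("glucose", "insulin")) {
  stopifnot(inherits(cohort, "glycohort"))
  signal <- match.arg(signal)
  col <- if (signal == "glucose") "glucose_mmol_l" else "insulin_mU_l"
  d <- cohort$meal %>%
    rename(value = all_of(col)) %>%
    group_by(.data$subject_id) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    mutate(delta = .data$value - .data$value[1]) %>%
    ungroup() %>%
    left_join(select(cohort$subjects, all_of(c("subject_id", "group"))),
              by = "subject_id") %>%
    group_by(.data$group, .data$time_min) %>%
    summarise(mean = mean(.data$delta),
              se = sd(.data$delta) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$mean,
                                  colour = .data$group, group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("incremental change in %s", signal)) +
    ggplot2::theme_minimal()
}
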