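#' Age-adjusted group comparison with Bonferroni post hoc tests
#'
#' One-way comparison of a continuous outcome between groups, optionally
#' adjusted for a numeric covariate (classic ANCOVA: linear model with group
#' indicators plus the covariate). Reports the F test of the group factor
#' (covariate entered first), covariate-adjusted group means evaluated at the
#' grand covariate mean, and all pairwise contrasts of adjusted means with
#' Bonferroni correction over the number of pairs.
#'
#' A covariate with zero variance carries no information and the model
#' reduces exactly to one-way ANOVA; this is handled explicitly rather than
#' left to rank-deficient fitting.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Outcome column (tidy-eval).
#' @param group Grouping column (tidy-eval), default `group`.
#' @param covariate Optional numeric covariate column (tidy-eval), e.g. age.
#' @param alpha Significance annotation threshold recorded on the result
#'   (never used to filter), default 0.05.
#' @return Object of class `group_comparison`; see [tidy.group_comparison()].
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6),
#'                     group = rep(c("a", "b"), each = 3),
#'                     age = c(25, 26, 27, 25, 26, 27))
#' compare_groups(d, y, group, covariate = age)
#' @export
compare_groups <- function(data, outcome, group = group, covariate = NULL,
                           alpha = 0.05) {
  y_quo <- enquo(outcome); g_quo <- enquo(group); c_quo <- enquo(covariate)
  d <- tibble(y = dplyr::pull(data, !!y_quo),
              g = factor(dplyr::pull(data, !!g_quo)))
  has_cov <- !quo_is_null(c_quo)
  if (has_cov) d$x <- dplyr::pull(data, !!c_quo)
  d <- d[complete.cases(d), ]
  d$g <- droplevels(d$g)

  counts <- table(d$g)
  if (length(counts) < 2) abort("need at least 2 groups")
  if (any(counts < 2)) {
    abort(sprintf("every group needs >= 2 subjects; too small: %s",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  if (var(d$y) == 0) abort("outcome is constant; group F statistic undefined")
  if (has_cov && var(d$x) == 0) has_cov <- FALSE   # constant covariate: plain ANOVA

  fit <- if (has_cov) lm(y ~ x + g, data = d) else lm(y ~ g, data = d)
  reduced <- if (has_cov) lm(y ~ x, data = d) else lm(y ~ 1, data = d)
  ftab <- anova(reduced, fit)
  f_stat <- ftab$F[2]
  p_val <- ftab$`Pr(>F)`[2]
  df <- c(ftab$Df[2], ftab$Res.Df[2])

  # adjusted means at the grand covariate mean
  newd <- tibble(g = factor(levels(d$g), levels = levels(d$g)))
  if (has_cov) newd$x <- mean(d$x)
  adj_means <- tibble(group = levels(d$g),
                      n = as.integer(counts),
                      adjusted_mean = as.numeric(predict(fit, newdata = newd)))

  # pairwise contrasts of adjusted means from the fitted model's vcov
  pairs <- utils::combn(levels(d$g), 2, simplify = FALSE)
  V <- vcov(fit); beta <- coef(fit)
  contrast_row <- function(lev) {
    cv <- setNames(numeric(length(beta)), names(beta))
    nm <- paste0("g", lev)
    if (nm %in% names(cv)) cv[nm] <- 1   # baseline level has no coefficient
    cv
  }
  pw <- purrr::map_dfr(pairs, function(p) {
    cv <- contrast_row(p[2]) - contrast_row(p[1])
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tval <- est / se
    praw <- 2 * pt(-abs(tval), df = fit$df.residual)
    tibble(group1 = p[1], group2 = p[2], estimate = est, se = se,
           statistic = tval, p_raw = praw,
           p_bonferroni = pmin(1, praw * length(pairs)))
  })

  structure(
    list(outcome = as_name(y_quo),
         covariate = if (has_cov) as_name(c_quo) else NA_character_,
         f_statistic = f_stat, p_value = p_val, df = df,
         adjusted_means = adj_means, pairwise = pw, alpha = alpha,
         model = fit),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by group%s\n", x$outcome,
              if (!is.na(x$covariate)) paste0(", adjusted for ", x$covariate) else ""))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  print(x$adjusted_means)
  cat("  pairwise (Bonferroni):\n")
  print(x$pairwise[c("group1", "group2", "estimate", "p_bonferroni")])
  invisible(x)
}

#' Tidy methods for group comparisons
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the pairwise-contrast tibble (one row per group pair,
#'   Bonferroni-adjusted p-values). `glance()`: one row with the group F
#'   test, its df, the covariate used and group sizes.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(outcome = x$outcome, covariate = x$covariate,
         f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value, n = sum(x$adjusted_means$n),
         significant = x$p_value < x$alpha)
}

#' Plot adjusted group means with pairwise significance
#'
#' Bar chart of covariate-adjusted group means; pairs whose Bonferroni
#' p-value falls below the comparison's alpha are listed in the subtitle.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  sig <- object$pairwise %>% filter(.data$p_bonferroni < object$alpha)
  sub <- if (nrow(sig)) {
    paste("significant pairs:",
          paste(sprintf("%s vs %s (p=%.3g)", sig$group1, sig$group2,
                        sig$p_bonferroni), collapse = ", "))
  } else "no significant pairs"
  ggplot2::ggplot(object$adjusted_means,
                  ggplot2::aes(.data$group, .data$adjusted_mean, fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = paste("adjusted mean", object$outcome),
                  subtitle = sub) +
    ggplot2::theme_minimal()
}
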