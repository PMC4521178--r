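#' Fit the hyperbolic secretion-versus-sensitivity relationship
#'
#' Appropriate beta-cell compensation implies that insulin secretion `B` and
#' insulin sensitivity `S` trade off along a rectangular hyperbola
#' `B = k / S`; the constant `k` is the disposition index of the cohort.
#' Both fits have closed forms (the exponent is fixed at -1; no free-exponent
#' power law is estimated):
#' * `scale = "log"` (default): least squares on `log B = log k - log S`,
#'   giving `k = exp(mean(log(S_i * B_i)))` — the geometric mean of the
#'   per-subject products. Residuals are log-compensation scores with mean
#'   zero by construction.
#' * `scale = "linear"`: `k` minimizing `sum((B_i - k / S_i)^2)`, i.e.
#'   `k = sum(B_i / S_i) / sum(1 / S_i^2)`.
#'
#' @param data Data frame with one row per subject.
#' @param sensitivity,secretion Columns of `data` (tidy-eval) holding the
#'   positive sensitivity and secretion measures; defaults mirror the common
#'   pairing of clamp sensitivity with the meal-test secretion index.
#' @param scale `"log"` or `"linear"`.
#' @param group Optional grouping column used later by [place_groups()];
#'   carried through to the residual table.
#' @return An object of class `di_fit`: list with `k`, `scale`, the axis
#'   names, and `residuals`, a tibble of per-subject log-compensation scores
#'   `log(S * B) - log(k)`.
#' @seealso [off_curve_score()], [place_groups()], [autoplot.di_fit()]
#' @examples
#' d <- tibble::tibble(S = c(4, 6, 2), B = 12 / c(4, 6, 2))
#' fit_di_hyperbola(d, S, B)$k # 12
#' @export
fit_di_hyperbola <- function(data, sensitivity = isi_clamp,
                             secretion = insulin_secretion_index,
                             scale = c("log", "linear"), group = NULL) {
  scale <- match.arg(scale)
  s_quo <- enquo(sensitivity); b_quo <- enquo(secretion); g_quo <- enquo(group)
  d <- tibble(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id
    else as.character(seq_len(nrow(data))),
    s = dplyr::pull(data, !!s_quo),
    b = dplyr::pull(data, !!b_quo)
  )
  if (!quo_is_null(g_quo)) d$group <- dplyr::pull(data, !!g_quo)
  d <- d %>% filter(!is.na(.data$s) & !is.na(.data$b))
  if (nrow(d) < 3) abort("hyperbola fit needs at least 3 subjects with both measures")
  if (any(d$s <= 0 | d$b <= 0)) abort("sensitivity and secretion must be positive")

  k <- if (scale == "log") {
    exp(mean(log(d$s * d$b)))
  } else {
    sum(d$b / d$s) / sum(1 / d$s^2)
  }
  d$score <- log(d$s * d$b) - log(k)

  structure(
    list(k = k, scale = scale,
         sensitivity = as_name(s_quo), secretion = as_name(b_quo),
         residuals = d),
    class = "di_fit")
}

#' Log-compensation score relative to a fitted disposition-index curve
#'
#' `r = log(S * B) - log(k)`: zero on the curve, negative below it
#' ("falling off the DI curve", beta-cell under-compensation for the
#' prevailing sensitivity), positive above.
#'
#' @param sensitivity,secretion Positive numeric vectors.
#' @param fit A `di_fit` object, or a positive scalar `k`.
#' @return Numeric log-ratio scores.
#' @export
off_curve_score <- function(sensitivity, secretion, fit) {
  k <- if (inherits(fit, "di_fit")) fit$k else fit
  check_positive(sensitivity = sensitivity, secretion = secretion, k = k)
  log(sensitivity * secretion) - log(k)
}

#' Group placement on the disposition-index curve
#'
#' Arithmetic group means of the sensitivity/secretion coordinates and of the
#' per-subject off-curve scores, with groups ranked by mean score (rank 1 =
#' lowest score = furthest below the curve). By default the hyperbola is the
#' one fitted to all subjects in `data`; pass `fit` to score against a
#' reference curve instead (e.g. one fitted to a subset known to compensate
#' appropriately).
#'
#' @inheritParams fit_di_hyperbola
#' @param group Grouping column (tidy-eval), default `group`.
#' @param fit Optional `di_fit` (or scalar k) defining the curve.
#' @param scale Fit scale when `fit` is not supplied.
#' @return Tibble with one row per group: `group`, `n`, `mean_sensitivity`,
#'   `mean_secretion`, `mean_score`, `rank_score`. The curve constant is in
#'   attribute `k`. Groups with no complete pairs are dropped with a warning.
#' @export
place_groups <- function(data, sensitivity = isi_clamp,
                         secretion = insulin_secretion_index, group = group,
                         fit = NULL, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  s_quo <- enquo(sensitivity); b_quo <- enquo(secretion); g_quo <- enquo(group)
  d <- tibble(group = dplyr::pull(data, !!g_quo),
              s = dplyr::pull(data, !!s_quo),
              b = dplyr::pull(data, !!b_quo))
  complete <- !is.na(d$s) & !is.na(d$b)
  dropped <- setdiff(unique(d$group), unique(d$group[complete]))
  if (length(dropped)) {
    warn(sprintf("group(s) without complete sensitivity/secretion pairs omitted: %s",
                 paste(dropped, collapse = ", ")))
  }
  d <- d[complete, ]
  if (is.null(fit)) fit <- fit_di_hyperbola(d, s, b, scale = scale)
  k <- if (inherits(fit, "di_fit")) fit$k else fit

  out <- d %>%
    mutate(score = off_curve_score(.data$s, .data$b, k)) %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              mean_sensitivity = mean(.data$s),
              mean_secretion = mean(.data$b),
              mean_score = mean(.data$score),
              .groups = "drop") %>%
    mutate(rank_score = rank(.data$mean_score))
  attr(out, "k") <- k
  out
}

#' @export
print.di_fit <- function(x, ...) {
  cat(sprintf("<di_fit> B = k/S hyperbola, %s-scale least squares\n", x$scale))
  cat(sprintf("  axes: %s (S) vs %s (B)\n", x$sensitivity, x$secretion))
  cat(sprintf("  k = %.4g over %d subjects\n", x$k, nrow(x$residuals)))
  invisible(x)
}

#' Tidy a fitted disposition-index curve
#'
#' @param x A `di_fit` object.
#' @param ... Unused.
#' @return `tidy()`: per-subject tibble of coordinates and log-compensation
#'   scores. `glance()`: one-row tibble with `k`, `scale`, `n`, and the
#'   residual log-scale spread `sigma_log`.
#' @method tidy di_fit
#' @export
tidy.di_fit <- function(x, ...) {
  out <- rename(x$residuals, sensitivity = "s", secretion = "b")
  as_tibble(out)
}

#' @rdname tidy.di_fit
#' @method glance di_fit
#' @export
glance.di_fit <- function(x, ...) {
  tibble(k = x$k, scale = x$scale, n = nrow(x$residuals),
         sigma_log = sd(x$residuals$score))
}

#' Plot a disposition-index curve fit
#'
#' Scatter of secretion against sensitivity with the fitted hyperbola
#' `B = k/S`; when the fit carries a grouping, points are colored by group
#' and filled symbols mark group mean coordinates.
#'
#' @param object A `di_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot di_fit
#' @export
autoplot.di_fit <- function(object, ...) {
  d <- tidy(object)
  curve_d <- tibble(
    sensitivity = seq(min(d$sensitivity) * 0.8, max(d$sensitivity) * 1.1,
                      length.out = 200)
  ) %>% mutate(secretion = object$k / .data$sensitivity)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$sensitivity, .data$secretion)) +
    ggplot2::geom_line(data = curve_d, linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = object$sensitivity, y = object$secretion,
                  title = sprintf("Hyperbolic fit, k = %.3g (%s scale)",
                                  object$k, object$scale))
  if ("group" %in% names(d)) {
    means <- d %>% group_by(.data$group) %>%
      summarise(sensitivity = mean(.data$sensitivity),
                secretion = mean(.data$secretion), .groups = "drop")
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$group), shape = 1) +
      ggplot2::geom_point(data = means,
                          ggplot2::aes(fill = .data$group), shape = 21, size = 3)
  } else {
    p <- p + ggplot2::geom_point(shape = 1)
  }
  p + ggplot2::theme_minimal()
}
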