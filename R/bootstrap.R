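#' Bootstrap percentile confidence intervals for group disposition-index means
#'
#' Nonparametric bootstrap resampling subjects with replacement within each
#' group; percentile interval of the group mean. Reproducible under `seed`.
#'
#' @param panel Index panel from [compute_indices()] (any data frame with a
#'   `group` column works).
#' @param outcome Column to summarise (tidy-eval), default `oral_di`.
#' @param n_boot Number of bootstrap replicates, at least 100.
#' @param level Interval coverage, default 0.95.
#' @param seed Integer seed (local to this call; the caller's RNG state is
#'   untouched).
#' @return Tibble per group: `n`, `mean`, `ci_lower`, `ci_upper`. Groups of
#'   size 1 get `NA` bounds with a warning.
#' @export
bootstrap_group_di <- function(panel, outcome = oral_di, n_boot = 2000,
                               level = 0.95, seed = 1L) {
  if (n_boot < 100) abort("n_boot must be at least 100")
  y_quo <- enquo(outcome)
  d <- tibble(group = panel$group, y = dplyr::pull(panel, !!y_quo)) %>%
    filter(!is.na(.data$y))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  qtl <- function(x, p) if (all(is.na(x))) NA_real_ else unname(quantile(x, p))
  out <- d %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean = mean(.data$y),
              boots = list(if (dplyr::n() > 1) {
                replicate(n_boot, mean(sample(.data$y, replace = TRUE)))
              } else NA_real_),
              .groups = "drop") %>%
    mutate(ci_lower = purrr::map_dbl(.data$boots, qtl, probs[1]),
           ci_upper = purrr::map_dbl(.data$boots, qtl, probs[2])) %>%
    select(-all_of("boots"))
  if (any(out$n == 1)) {
    warn(sprintf("group(s) of size 1 have undefined bootstrap CIs: %s",
                 paste(out$group[out$n == 1], collapse = ", ")))
    out$ci_lower[out$n == 1] <- NA_real_
    out$ci_upper[out$n == 1] <- NA_real_
  }
  out
}
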