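#' Compute the full per-subject index panel for a cohort
#'
#' Derives every index the fasting, clamp and meal-test data support for each
#' subject: HOMA-IR, HOMA-B, ISI-clamp, total and incremental AUCs, the
#' Matsuda-type composite sensitivity index, the insulinogenic index, the
#' insulin secretion index and the oral disposition index
#' (`oral_di = isi_mat * insulin_secretion_index`, exact product).
#'
#' Missing inputs or per-index domain failures (fasting glucose at the HOMA-B
#' singularity, zero 0-30 min glucose change, non-positive net incremental
#' AUC) never abort the cohort: the affected index is `NA` and the reason is
#' recorded in `exclusion_reason`. AUCs are computed once and reused.
#'
#' @param cohort A `glycohort` from [read_cohort()], [new_cohort()] or
#'   [simulate_cohort()].
#' @param iauc_convention Incremental-AUC convention fed to the Matsuda
#'   index, `"net"` (default) or `"positive_only"`; both are reported in the
#'   output regardless.
#' @param matsuda_grouping Root grouping for [matsuda_isi()], `"full"`
#'   (default) or `"fasting_only"`.
#' @param isi_clamp_scale Display scale for [isi_clamp()], default 100.
#' @return A tibble with one row per subject: `subject_id`, `group`, the
#'   index columns, and `exclusion_reason` (`NA` when complete). Options
#'   used are attached as attributes `iauc_convention`, `matsuda_grouping`
#'   and `isi_clamp_scale`.
#' @examples
#' cohort <- simulate_cohort(cohort_presets(), seed = 1)
#' panel <- compute_indices(cohort)
#' dplyr::glimpse(panel)
#' @export
compute_indices <- function(cohort,
                            iauc_convention = c("net", "positive_only"),
                            matsuda_grouping = c("full", "fasting_only"),
                            isi_clamp_scale = 100) {
  stopifnot(inherits(cohort, "glycohort"))
  iauc_convention <- match.arg(iauc_convention)
  matsuda_grouping <- match.arg(matsuda_grouping)

  subjects <- cohort$subjects
  panel <- subjects %>%
    select(all_of(c("subject_id", "group",
                    "fasting_glucose_mmol_l", "fasting_insulin_mU_l")))

  excl <- tibble(subject_id = subjects$subject_id, reasons = vector("list", nrow(subjects)))
  note <- function(id, msg) {
    i <- match(id, excl$subject_id)
    excl$reasons[[i]] <<- c(excl$reasons[[i]], msg)
  }

  # fasting indices
  panel <- panel %>%
    mutate(homa_ir = homa_ir(.data$fasting_insulin_mU_l, .data$fasting_glucose_mmol_l),
           homa_b = NA_real_)
  ok_b <- panel$fasting_glucose_mmol_l > 3.5
  panel$homa_b[ok_b] <- homa_b(panel$fasting_insulin_mU_l[ok_b],
                               panel$fasting_glucose_mmol_l[ok_b])
  for (id in panel$subject_id[!ok_b]) note(id, "homa_b: fasting glucose <= 3.5 mmol/l")

  # clamp index
  if (!is.null(cohort$clamp)) {
    clamp_idx <- cohort$clamp %>%
      filter(.data$mean_gir_mg_min > 0) %>%
      mutate(isi_clamp = isi_clamp(.data$mean_gir_mg_min, .data$lean_body_mass_kg,
                                   .data$steady_state_insulin_mU_l,
                                   scale = isi_clamp_scale)) %>%
      select(all_of(c("subject_id", "isi_clamp")))
    panel <- left_join(panel, clamp_idx, by = "subject_id")
    zero_gir <- cohort$clamp$subject_id[cohort$clamp$mean_gir_mg_min <= 0]
    for (id in zero_gir) note(id, "isi_clamp: non-positive glucose infusion rate")
  } else {
    panel$isi_clamp <- NA_real_
  }
  for (id in setdiff(panel$subject_id,
                     if (is.null(cohort$clamp)) character() else cohort$clamp$subject_id)) {
    note(id, "isi_clamp: no clamp record")
  }

  # meal-test indices
  if (!is.null(cohort$meal)) {
    aucs <- auc_summary(cohort$meal)
    igi <- cohort$meal %>%
      group_by(.data$subject_id) %>%
      arrange(.data$time_min, .by_group = TRUE) %>%
      summarise(
        insulinogenic_index = insulinogenic_index(.data$time_min, .data$glucose_mmol_l,
                                                  .data$insulin_mU_l),
        insulin_secretion_index = insulin_secretion_index(.data$time_min,
                                                          .data$glucose_mmol_l,
                                                          .data$insulin_mU_l),
        .groups = "drop")
    panel <- panel %>%
      left_join(aucs, by = "subject_id") %>%
      left_join(igi, by = "subject_id")
    for (id in panel$subject_id[!is.na(panel$auc_glucose) &
                                  is.na(panel$insulinogenic_index)]) {
      note(id, "insulinogenic_index: zero 0-30 min glucose change")
    }
  } else {
    panel[c("auc_glucose", "auc_insulin", "iauc_glucose", "iauc_insulin",
            "iauc_glucose_pos", "iauc_insulin_pos",
            "insulinogenic_index", "insulin_secretion_index")] <- NA_real_
  }
  for (id in setdiff(panel$subject_id,
                     if (is.null(cohort$meal)) character() else cohort$meal$subject_id)) {
    note(id, "meal indices: no meal series")
  }

  # composite sensitivity and disposition index
  iaucg <- if (iauc_convention == "net") panel$iauc_glucose else panel$iauc_glucose_pos
  iauci <- if (iauc_convention == "net") panel$iauc_insulin else panel$iauc_insulin_pos
  ok_mat <- !is.na(iaucg) & !is.na(iauci) & iaucg > 0 & iauci > 0
  panel$isi_mat <- NA_real_
  panel$isi_mat[ok_mat] <- matsuda_isi(panel$fasting_glucose_mmol_l[ok_mat],
                                       panel$fasting_insulin_mU_l[ok_mat],
                                       iaucg[ok_mat], iauci[ok_mat],
                                       grouping = matsuda_grouping)
  for (id in panel$subject_id[!ok_mat & !is.na(iaucg)]) {
    note(id, "isi_mat: non-positive incremental AUC")
  }
  panel$oral_di <- panel$isi_mat * panel$insulin_secretion_index

  reasons <- purrr::map_chr(excl$reasons,
                            ~ if (is.null(.x)) NA_character_ else paste(.x, collapse = "; "))
  panel$exclusion_reason <- reasons[match(panel$subject_id, excl$subject_id)]

  panel <- panel %>% select(-all_of(c("fasting_glucose_mmol_l", "fasting_insulin_mU_l")))
  attr(panel, "iauc_convention") <- iauc_convention
  attr(panel, "matsuda_grouping") <- matsuda_grouping
  attr(panel, "isi_clamp_scale") <- isi_clamp_scale
  panel
}
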