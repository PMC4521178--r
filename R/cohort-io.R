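#' Read a cohort from its three CSV tables
#'
#' A cohort is the join of three tidy tables on `subject_id`:
#' * `subjects.csv` — `subject_id, group, age_years, bmi, waist_cm,
#'   percent_body_fat, lean_body_mass_kg, fasting_glucose_mmol_l,
#'   fasting_insulin_mU_l`
#' * `meal_timeseries.csv` (long) — `subject_id, time_min, glucose_mmol_l,
#'   insulin_mU_l`
#' * `clamp.csv` — `subject_id, mean_gir_mg_min, steady_state_insulin_mU_l,
#'   lean_body_mass_kg`
#'
#' Subjects missing a meal or clamp record are kept; downstream index
#' computation leaves the affected indices `NA` with an exclusion reason.
#' A warning lists such subjects. Units are canonical (mmol/l glucose,
#' mU/l insulin); use [convert_glucose()] / [convert_insulin()] before
#' writing the CSVs if your lab reports otherwise.
#'
#' @param subjects_path,meal_path,clamp_path Paths to the three CSV files;
#'   `meal_path` and `clamp_path` may be `NULL`.
#' @return An object of class `glycohort`: a list with tibbles `subjects`,
#'   `meal`, `clamp` (the latter two possibly `NULL`).
#' @export
read_cohort <- function(subjects_path, meal_path = NULL, clamp_path = NULL) {
  subjects <- readr::read_csv(subjects_path, show_col_types = FALSE,
                              progress = FALSE)
  meal <- if (!is.null(meal_path)) {
    readr::read_csv(meal_path, show_col_types = FALSE, progress = FALSE)
  }
  clamp <- if (!is.null(clamp_path)) {
    readr::read_csv(clamp_path, show_col_types = FALSE, progress = FALSE)
  }
  new_cohort(subjects, meal, clamp)
}

#' Assemble a cohort from in-memory tables
#'
#' @param subjects,meal,clamp Tibbles in the schemas documented in
#'   [read_cohort()]; `meal` and `clamp` optional.
#' @param ground_truth Optional per-subject generative parameters (attached
#'   by [simulate_cohort()]).
#' @return A `glycohort` object.
#' @export
new_cohort <- function(subjects, meal = NULL, clamp = NULL, ground_truth = NULL) {
  check_subjects_schema(subjects)
  if (!is.null(meal)) {
    check_meal_schema(meal)
    check_meal_values(meal)
  }
  if (!is.null(clamp)) check_clamp_schema(clamp)
  warn_missing_slots(subjects, meal, clamp)
  structure(
    list(subjects = as_tibble(subjects),
         meal = if (!is.null(meal)) as_tibble(meal),
         clamp = if (!is.null(clamp)) as_tibble(clamp),
         ground_truth = if (!is.null(ground_truth)) as_tibble(ground_truth)),
    class = "glycohort"
  )
}

#' Write a cohort to a directory of CSV files
#'
#' Inverse of [read_cohort()]: writes `subjects.csv`, `meal_timeseries.csv`
#' and `clamp.csv` (the latter two only if present). If the cohort carries
#' simulator ground truth it is written as `ground_truth.csv`.
#'
#' @param cohort A `glycohort` object.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glycohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), progress = FALSE)
  if (!is.null(cohort$meal)) {
    readr::write_csv(cohort$meal, file.path(dir, "meal_timeseries.csv"), progress = FALSE)
  }
  if (!is.null(cohort$clamp)) {
    readr::write_csv(cohort$clamp, file.path(dir, "clamp.csv"), progress = FALSE)
  }
  if (!is.null(cohort$ground_truth)) {
    readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.glycohort <- function(x, ...) {
  cat("<glycohort> ", nrow(x$subjects), " subjects (",
      paste(sprintf("%s: %d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      ")\n", sep = "")
  cat("  meal series: ", if (is.null(x$meal)) "absent" else
    paste0(dplyr::n_distinct(x$meal$subject_id), " subjects"), "\n", sep = "")
  cat("  clamp records: ", if (is.null(x$clamp)) "absent" else
    nrow(x$clamp), "\n", sep = "")
  if (!is.null(x$ground_truth)) cat("  simulator ground truth attached\n")
  invisible(x)
}

# ---- schema & invariant checks ------------------------------------------

subjects_cols <- c("subject_id", "group", "age_years", "bmi", "waist_cm",
                   "percent_body_fat", "lean_body_mass_kg",
                   "fasting_glucose_mmol_l", "fasting_insulin_mU_l")
meal_cols <- c("subject_id", "time_min", "glucose_mmol_l", "insulin_mU_l")
clamp_cols <- c("subject_id", "mean_gir_mg_min", "steady_state_insulin_mU_l",
                "lean_body_mass_kg")

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s table is missing columns: %s", what,
                  paste(missing, collapse = ", ")))
  }
}

check_subjects_schema <- function(subjects) {
  require_cols(subjects, subjects_cols, "subjects")
  if (anyDuplicated(subjects$subject_id)) {
    abort("duplicate subject_id in subjects table")
  }
  bad <- with(subjects, fasting_glucose_mmol_l <= 0 | fasting_insulin_mU_l <= 0 |
                lean_body_mass_kg <= 0 | age_years <= 0)
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("non-positive fasting glucose/insulin, lean mass or age for subject(s): %s",
                  paste(subjects$subject_id[which(bad)], collapse = ", ")))
  }
  invisible(TRUE)
}

check_meal_schema <- function(meal) {
  require_cols(meal, meal_cols, "meal time series")
  dup <- duplicated(meal[c("subject_id", "time_min")])
  if (any(dup)) {
    abort(sprintf("duplicate (subject_id, time_min) rows in meal table: %s",
                  paste(unique(meal$subject_id[dup]), collapse = ", ")))
  }
  invisible(TRUE)
}

# per-subject series invariants: first time 0, strictly increasing, positive values
check_meal_values <- function(meal) {
  bad <- meal %>%
    group_by(.data$subject_id) %>%
    arrange(.data$time_min, .by_group = TRUE) %>%
    summarise(
      ok = .data$time_min[1] == 0 && all(diff(.data$time_min) > 0) &&
        all(.data$glucose_mmol_l > 0) && all(.data$insulin_mU_l > 0),
      .groups = "drop"
    ) %>%
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf(
      "invalid meal series (first time must be 0, times increasing, values positive) for: %s",
      paste(bad$subject_id, collapse = ", ")))
  }
  invisible(TRUE)
}

check_clamp_schema <- function(clamp) {
  require_cols(clamp, clamp_cols, "clamp")
  if (anyDuplicated(clamp$subject_id)) abort("duplicate subject_id in clamp table")
  bad <- with(clamp, mean_gir_mg_min < 0 | steady_state_insulin_mU_l <= 0 |
                lean_body_mass_kg <= 0)
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("invalid clamp record (GIR < 0 or non-positive insulin/lean mass) for: %s",
                  paste(clamp$subject_id[which(bad)], collapse = ", ")))
  }
  invisible(TRUE)
}

warn_missing_slots <- function(subjects, meal, clamp) {
  if (!is.null(meal)) {
    no_meal <- setdiff(subjects$subject_id, meal$subject_id)
    if (length(no_meal)) {
      warn(sprintf("subjects without meal series: %s",
                   paste(no_meal, collapse = ", ")))
    }
  }
  if (!is.null(clamp)) {
    no_clamp <- setdiff(subjects$subject_id, clamp$subject_id)
    if (length(no_clamp)) {
      warn(sprintf("subjects without clamp record: %s",
                   paste(no_clamp, collapse = ", ")))
    }
  }
}
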