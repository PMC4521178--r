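# three-subject hand-built cohort used across I/O and panel tests
tiny_subjects <- function() {
  tibble::tibble(
    subject_id = c("S1", "S2", "S3"),
    group = c("a", "a", "b"),
    age_years = c(25, 30, 28),
    bmi = c(21, 22, 20.5),
    waist_cm = c(75, 78, 74),
    percent_body_fat = c(18, 20, 17),
    lean_body_mass_kg = c(52, 55, 50),
    fasting_glucose_mmol_l = c(4.4, 4.1, 4.2),
    fasting_insulin_mU_l = c(4.9, 6.0, 7.5)
  )
}

tiny_meal <- function(ids = c("S1", "S2", "S3")) {
  grid <- c(0, 30, 60, 90, 120, 240)
  tidyr::expand_grid(subject_id = ids, time_min = grid) |>
    dplyr::group_by(subject_id) |>
    dplyr::mutate(
      glucose_mmol_l = 4.3 + 1.5 * sin(pi * pmin(time_min, 180) / 180),
      insulin_mU_l = 5 + 30 * sin(pi * pmin(time_min, 200) / 200) +
        match(subject_id[1], c("S1", "S2", "S3"))
    ) |>
    dplyr::ungroup()
}

tiny_clamp <- function(ids = c("S1", "S2", "S3")) {
  tibble::tibble(
    subject_id = ids,
    mean_gir_mg_min = c(560, 610, 420)[seq_along(ids)],
    steady_state_insulin_mU_l = c(70, 65, 75)[seq_along(ids)],
    lean_body_mass_kg = c(52, 55, 50)[seq_along(ids)]
  )
}

tiny_cohort <- function() {
  new_cohort(tiny_subjects(), tiny_meal(), tiny_clamp())
}

# dense-grid integration of the piecewise-linear interpolant (independent
# AUC oracle), step in minutes
dense_auc <- function(times, values, clip_baseline = FALSE, step = 0.001) {
  xs <- seq(min(times), max(times), by = step)
  ys <- approx(times, values, xout = xs)$y
  if (clip_baseline) ys <- pmax(ys - values[1], 0)
  sum((ys[-1] + ys[-length(ys)]) / 2) * step
}
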