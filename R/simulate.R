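#' Group configuration for the synthetic-cohort generator
#'
#' One row of generator settings for a single group. The generative model
#' (see [simulate_cohort()]) draws a true insulin sensitivity `S_i`
#' (lognormal on the clamp index scale) and a true secretion capacity
#' `B_i = delta * k / S_i * exp(eps)`, `eps ~ N(0, sigma_log^2)`: subjects
#' sit on the group's disposition hyperbola `B = k/S` up to multiplicative
#' noise, shifted below it by the compensation deficit `delta < 1`.
#'
#' @param label Group label.
#' @param n Subjects in the group (>= 1).
#' @param s_mean,s_sd Mean and SD of true sensitivity on the clamp-index
#'   scale (mg per kg lean mass per min per mU/l, x100).
#' @param k Disposition hyperbola constant (sensitivity x secretion).
#' @param delta Compensation deficit in (0, 1]; 1 = appropriate
#'   compensation, smaller values place the group below the curve.
#' @param fg_mean,fg_sd Fasting glucose, mmol/l (normoglycemic draws are
#'   enforced by resampling below 7 mmol/l).
#' @param fi_coupling Constant `c` of the fasting-insulin model
#'   `FI = c / S * exp(noise)` (mU/l times sensitivity units), encoding the
#'   anti-correlation of fasting insulin with sensitivity.
#' @param sigma_fi Log-SD of the fasting-insulin noise.
#' @param age_mean,age_sd Age, years (resampled above 18).
#' @param lean_mass_mean,lean_mass_sd Lean body mass, kg.
#' @param bmi_mean,bmi_sd,waist_mean,waist_sd,body_fat_mean,body_fat_sd
#'   Anthropometry (BMI resampled into the lean range below 23 kg/m2).
#' @param iauc_glucose_target Target group-mean incremental glucose AUC
#'   (mmol min/l) used to freeze the excursion-amplitude constant.
#' @param sigma_log Log-SD of the secretion noise `eps`.
#' @param sigma_amp Log-SD of the per-subject excursion-amplitude noise.
#' @return One-row tibble of settings.
#' @export
group_config <- function(label, n,
                         s_mean, s_sd, k, delta = 1,
                         fg_mean, fg_sd,
                         fi_coupling, sigma_fi = 0.35,
                         age_mean, age_sd,
                         lean_mass_mean = 52, lean_mass_sd = 5,
                         bmi_mean = 21.3, bmi_sd = 1.2,
                         waist_mean = 76, waist_sd = 4.4,
                         body_fat_mean = 19, body_fat_sd = 4.8,
                         iauc_glucose_target = 220,
                         sigma_log = 0.25, sigma_amp = 0.2) {
  cfg <- tibble(label = label, n = as.integer(n),
                s_mean = s_mean, s_sd = s_sd, k = k, delta = delta,
                fg_mean = fg_mean, fg_sd = fg_sd,
                fi_coupling = fi_coupling, sigma_fi = sigma_fi,
                age_mean = age_mean, age_sd = age_sd,
                lean_mass_mean = lean_mass_mean, lean_mass_sd = lean_mass_sd,
                bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                waist_mean = waist_mean, waist_sd = waist_sd,
                body_fat_mean = body_fat_mean, body_fat_sd = body_fat_sd,
                iauc_glucose_target = iauc_glucose_target,
                sigma_log = sigma_log, sigma_amp = sigma_amp)
  check_config(cfg)
  cfg
}

check_config <- function(cfg) {
  with(cfg, {
    if (any(n < 1)) abort("group size n must be >= 1")
    if (any(delta <= 0 | delta > 1)) abort("delta must be in (0, 1]")
    if (any(c(s_mean, k, fg_mean, fi_coupling, age_mean, lean_mass_mean,
              iauc_glucose_target) <= 0)) {
      abort("distribution means and constants must be positive")
    }
    if (any(fg_mean >= 7)) abort("fg_mean must be below the 7 mmol/l normoglycemic bound")
    if (any(c(s_sd, fg_sd, age_sd, lean_mass_sd, sigma_log, sigma_amp, sigma_fi) < 0)) {
      abort("standard deviations must be non-negative")
    }
  })
  invisible(cfg)
}

#' Calibrated three-group presets and a null preset
#'
#' `cohort_presets()` returns generator settings for three groups emulating
#' the published group summaries of a lean male Singaporean cohort
#' (n = 14/21/24): clamp sensitivity means 14.2/12.9/8.8, fasting glucose
#' 4.41/4.12/4.12 mmol/l, fasting insulin 4.85/5.93/7.54 mU/l and
#' incremental glucose AUC targets 157.0/306.0/224.6 mmol min/l for the
#' `chinese_like` / `malay_like` / `indian_like` groups. Between-subject SDs
#' are reconstructed from printed standard errors times sqrt(n). The
#' `chinese_like` and `indian_like` groups compensate appropriately
#' (delta = 1, hyperbola constants 149.1 and 108.2 = mean sensitivity x mean
#' secretion index); the `malay_like` group shares the `chinese_like`
#' reference hyperbola with a compensation deficit delta = 117.4/149.1
#' (about 0.79), reproducing the "falling off the DI curve" pattern.
#'
#' `null_preset()` returns identical groups differing only in label, for
#' type-I-error studies.
#'
#' @param n Per-group size for `null_preset()`.
#' @param labels Group labels for `null_preset()`.
#' @return Tibble of group configurations for [simulate_cohort()].
#' @export
cohort_presets <- function() {
  bind_rows(
    group_config("chinese_like", 14, s_mean = 14.2, s_sd = 1.2 * sqrt(14),
                 k = 14.2 * 10.5, delta = 1,
                 fg_mean = 4.41, fg_sd = 0.09 * sqrt(14),
                 fi_coupling = 4.85 * 14.2,
                 age_mean = 29.6, age_sd = 1.7 * sqrt(14),
                 bmi_mean = 21.5, bmi_sd = 0.4 * sqrt(14),
                 waist_mean = 75.8, waist_sd = 1.1 * sqrt(14),
                 body_fat_mean = 19.4, body_fat_sd = 1.4 * sqrt(14),
                 iauc_glucose_target = 157.0),
    group_config("malay_like", 21, s_mean = 12.9, s_sd = 1.2 * sqrt(21),
                 k = 14.2 * 10.5, delta = (12.9 * 9.1) / (14.2 * 10.5),
                 fg_mean = 4.12, fg_sd = 0.10 * sqrt(21),
                 fi_coupling = 5.93 * 12.9,
                 age_mean = 25.2, age_sd = 0.7 * sqrt(21),
                 bmi_mean = 20.9, bmi_sd = 0.3 * sqrt(21),
                 waist_mean = 73.9, waist_sd = 1.0 * sqrt(21),
                 body_fat_mean = 17.5, body_fat_sd = 1.0 * sqrt(21),
                 iauc_glucose_target = 306.0),
    group_config("indian_like", 24, s_mean = 8.8, s_sd = 0.6 * sqrt(24),
                 k = 8.8 * 12.3, delta = 1,
                 fg_mean = 4.12, fg_sd = 0.07 * sqrt(24),
                 fi_coupling = 7.54 * 8.8,
                 age_mean = 24.3, age_sd = 0.7 * sqrt(24),
                 bmi_mean = 21.6, bmi_sd = 0.3 * sqrt(24),
                 waist_mean = 78.7, waist_sd = 0.9 * sqrt(24),
                 body_fat_mean = 20.4, body_fat_sd = 1.0 * sqrt(24),
                 iauc_glucose_target = 224.6)
  )
}

#' @rdname cohort_presets
#' @export
null_preset <- function(n = 20, labels = c("g1", "g2", "g3")) {
  purrr::map_dfr(labels, function(lab) {
    group_config(lab, n, s_mean = 12, s_sd = 4, k = 130, delta = 1,
                 fg_mean = 4.2, fg_sd = 0.35, fi_coupling = 72,
                 age_mean = 26, age_sd = 4, iauc_glucose_target = 220)
  })
}

# unimodal post-meal excursion kernel: gamma-density shape, peak value 1 at
# `peak` minutes, zero at t <= 0 and effectively zero again by 240 min
meal_kernel <- function(t, peak = 45, shape = 2) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / peak)^shape * exp(shape * (1 - t[pos] / peak))
  out
}

# truncated-normal draw by resampling (preserves shape near the bound)
draw_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1
    if (guard > 10000) abort("truncation bounds incompatible with distribution")
  }
  x
}

# lognormal parameterized by arithmetic mean and SD
draw_lognorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a cohort with known ground truth
#'
#' Generates subjects, LMMTT glucose/insulin series on the canonical
#' 0/30/60/90/120/240-min grid and clamp steady-state records, from the
#' generative model:
#' * true sensitivity `S_i` ~ lognormal matching the group mean/SD;
#' * true secretion `B_i = delta * k / S_i * exp(eps)`,
#'   `eps ~ N(0, sigma_log^2)`;
#' * fasting insulin `FI_i = fi_coupling / S_i * exp(nu)` (anti-correlated
#'   with sensitivity), fasting glucose truncated-normal below 7 mmol/l;
#' * glucose curve `G(t) = FG_i + A_i h(t)` with a fixed unimodal kernel `h`
#'   peaking at 45 min (`h(0) = 0`, `h(240)` negligible) and amplitude
#'   `A_i` proportional to `1 / (S_i B_i)` — low disposition index means
#'   high excursion — with the proportionality constant frozen per group
#'   from its incremental-AUC target;
#' * insulin curve `I(t) = FI_i + B_i A_i h(t - lag)` with a 15-min lag;
#' * clamp record with steady-state insulin ~ N(70, 8^2) mU/l under the
#'   standard 40 mU/m2/min infusion and glucose infusion rate
#'   `M_i = S_i I_ss LBM / 100`, so the clamp index recovers `S_i` exactly.
#'
#' All positivity and inclusion bounds (normoglycemic fasting glucose, lean
#' BMI, adult age) are enforced by resampling, not clipping. The draw is
#' fully reproducible under `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param configs Tibble of group settings from [group_config()],
#'   [cohort_presets()] or [null_preset()].
#' @param seed Integer seed.
#' @param insulin_lag Lag of the insulin excursion behind glucose, minutes.
#' @return A `glycohort` whose `ground_truth` tibble stores `S_true`,
#'   `B_true`, the group `k` and `delta`, the amplitude draw and the seed.
#' @examples
#' cohort <- simulate_cohort(cohort_presets(), seed = 42)
#' cohort
#' @export
simulate_cohort <- function(configs, seed, insulin_lag = 15) {
  check_config(configs)
  if (anyDuplicated(configs$label)) abort("duplicate group labels")
  stopifnot(length(seed) == 1, is.finite(seed))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  grid <- lmmtt_grid
  h_g <- meal_kernel(grid)
  h_i <- meal_kernel(grid - insulin_lag)
  # trapezoid integral of the kernel on the sampling grid; the glucose
  # incremental AUC of a generated subject is exactly A_i * kernel_auc
  kernel_auc <- total_auc(grid, h_g)

  parts <- purrr::map(seq_len(nrow(configs)), function(j) {
    cfg <- configs[j, ]
    n <- cfg$n
    id <- sprintf("%s_%03d", cfg$label, seq_len(n))

    S <- draw_lognorm(n, cfg$s_mean, cfg$s_sd)
    eps <- rnorm(n, 0, cfg$sigma_log)
    B <- cfg$delta * cfg$k / S * exp(eps)
    fg <- draw_trunc(n, cfg$fg_mean, cfg$fg_sd, lower = 2.5, upper = 7)
    fi <- cfg$fi_coupling / S * exp(rnorm(n, 0, cfg$sigma_fi) - cfg$sigma_fi^2 / 2)

    # amplitude constant frozen from the group IAUC target, with lognormal
    # mean corrections for the eps and amplitude noise terms
    amp_const <- cfg$iauc_glucose_target / kernel_auc * cfg$delta * cfg$k *
      exp(-(cfg$sigma_log^2 + cfg$sigma_amp^2) / 2)
    A <- amp_const / (S * B) * exp(rnorm(n, 0, cfg$sigma_amp))

    age <- draw_trunc(n, cfg$age_mean, cfg$age_sd, lower = 18)
    lbm <- draw_trunc(n, cfg$lean_mass_mean, cfg$lean_mass_sd, lower = 30)
    bmi <- draw_trunc(n, cfg$bmi_mean, cfg$bmi_sd, lower = 17, upper = 23)
    waist <- draw_trunc(n, cfg$waist_mean, cfg$waist_sd, lower = 50)
    fat <- draw_trunc(n, cfg$body_fat_mean, cfg$body_fat_sd, lower = 5, upper = 45)

    subjects <- tibble(subject_id = id, group = cfg$label, age_years = age,
                       bmi = bmi, waist_cm = waist, percent_body_fat = fat,
                       lean_body_mass_kg = lbm,
                       fasting_glucose_mmol_l = fg, fasting_insulin_mU_l = fi)

    meal <- tidyr::expand_grid(subject_id = id, time_min = grid) %>%
      mutate(i = match(.data$subject_id, id),
             glucose_mmol_l = fg[.data$i] + A[.data$i] * h_g[match(.data$time_min, grid)],
             insulin_mU_l = fi[.data$i] + B[.data$i] * A[.data$i] *
               h_i[match(.data$time_min, grid)]) %>%
      select(-all_of("i"))

    iss <- draw_trunc(n, 70, 8, lower = 1)
    clamp <- tibble(subject_id = id,
                    mean_gir_mg_min = S * iss * lbm / 100,
                    steady_state_insulin_mU_l = iss,
                    lean_body_mass_kg = lbm,
                    insulin_infusion_rate_mU_m2_min = 40,
                    target_glucose_mmol_l = 5)

    truth <- tibble(subject_id = id, group = cfg$label, S_true = S, B_true = B,
                    k = cfg$k, delta = cfg$delta, amplitude = A,
                    seed = as.integer(seed))
    list(subjects = subjects, meal = meal, clamp = clamp, truth = truth)
  })

  new_cohort(subjects = purrr::map_dfr(parts, "subjects"),
             meal = purrr::map_dfr(parts, "meal"),
             clamp = purrr::map_dfr(parts, "clamp"),
             ground_truth = purrr::map_dfr(parts, "truth"))
}
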