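#' Fasting-state surrogate indices (homeostatic model assessment)
#'
#' `homa_ir()` estimates insulin resistance as
#' `FI * FG / 22.5`; `homa_b()` estimates beta-cell function as
#' `20 * FI / (FG - 3.5)`. Inputs are fasting insulin in mU/l and fasting
#' glucose in mmol/l. HOMA-B has a singularity at FG = 3.5 mmol/l; values at
#' or below it (hypoglycemic fasting glucose) are a domain error.
#'
#' @param fi Fasting insulin, mU/l (> 0).
#' @param fg Fasting glucose, mmol/l (> 0; > 3.5 for `homa_b`).
#' @return Dimensionless index, vectorized over inputs.
#' @examples
#' homa_ir(5, 4.5)   # 1
#' homa_b(4.85, 4.41)
#' @export
homa_ir <- function(fi, fg) {
  check_positive(fi = fi, fg = fg)
  fi * fg / 22.5
}

#' @rdname homa_ir
#' @export
homa_b <- function(fi, fg) {
  check_positive(fi = fi)
  if (any(fg <= 3.5, na.rm = TRUE)) {
    abort("HOMA-B undefined for fasting glucose <= 3.5 mmol/l (model singularity at hypoglycemic fasting glucose)")
  }
  20 * fi / (fg - 3.5)
}

#' Clamp insulin sensitivity index per kg lean body mass
#'
#' From the euglycemic-hyperinsulinemic clamp: the mean glucose infusion rate
#' over the final 30 min steady state, normalized by lean body mass and by
#' the steady-state insulin concentration,
#' `(M / LBM) / I_ss * scale`. The default `scale = 100` puts physiologic
#' values (roughly 10 mg kg^-1 min^-1 at 70 mU/l) on the conventional
#' reporting magnitude of ~14; set `scale = 1` for the raw ratio. The scale
#' used is recorded as an attribute on pipeline output.
#'
#' @param mean_gir Mean glucose (dextrose) infusion rate, mg/min, > 0.
#' @param lean_body_mass kg, > 0.
#' @param steady_state_insulin mU/l, > 0.
#' @param scale Display scaling factor, default 100.
#' @return Sensitivity in (mg per kg lean mass per min) per (mU/l), x scale.
#' @examples
#' isi_clamp(560, 56, 70) # ~14.29
#' @export
isi_clamp <- function(mean_gir, lean_body_mass, steady_state_insulin, scale = 100) {
  check_positive(mean_gir = mean_gir, lean_body_mass = lean_body_mass,
                 steady_state_insulin = steady_state_insulin, scale = scale)
  (mean_gir / lean_body_mass) / steady_state_insulin * scale
}

#' Matsuda-type composite insulin sensitivity index from a meal test
#'
#' Computed as `10000 / sqrt(FG * FI * IAUC_glucose * IAUC_insulin)` with the
#' square root over the full four-term product (`grouping = "full"`, the
#' default, matching the dimensional structure of the original composite
#' index). The alternative reading with the root over the fasting product
#' only, `10000 / (sqrt(FG * FI) * IAUC_glucose * IAUC_insulin)`, is
#' available as `grouping = "fasting_only"`. This formulation uses the
#' incremental AUCs over the full test; the conventional variant built on
#' mean concentrations is [matsuda_isi_conventional()] so the two can never
#' be silently conflated.
#'
#' @param fg Fasting glucose, mmol/l.
#' @param fi Fasting insulin, mU/l.
#' @param iauc_glucose Incremental glucose AUC, mmol min/l, > 0.
#' @param iauc_insulin Incremental insulin AUC, mU min/l, > 0.
#' @param grouping `"full"` or `"fasting_only"` (see Details).
#' @return Dimensionless sensitivity index.
#' @examples
#' matsuda_isi(4.41, 4.85, 157, 11138)
#' @export
matsuda_isi <- function(fg, fi, iauc_glucose, iauc_insulin,
                        grouping = c("full", "fasting_only")) {
  grouping <- match.arg(grouping)
  check_positive(fg = fg, fi = fi, iauc_glucose = iauc_glucose,
                 iauc_insulin = iauc_insulin)
  if (grouping == "full") {
    10000 / sqrt(fg * fi * iauc_glucose * iauc_insulin)
  } else {
    10000 / (sqrt(fg * fi) * iauc_glucose * iauc_insulin)
  }
}

#' @rdname matsuda_isi
#' @param mean_glucose,mean_insulin Mean concentrations over the meal test
#'   (total AUC / duration), mmol/l and mU/l.
#' @export
matsuda_isi_conventional <- function(fg, fi, mean_glucose, mean_insulin) {
  check_positive(fg = fg, fi = fi, mean_glucose = mean_glucose,
                 mean_insulin = mean_insulin)
  10000 / sqrt(fg * fi * mean_glucose * mean_insulin)
}

#' Early-phase insulin response: the insulinogenic index
#'
#' `(Insulin30 - Insulin0) / (Glucose30 - Glucose0)` from the meal-test
#' series. Requires samples at exactly 0 and 30 min; no interpolation is
#' performed. When the 0-30 min glucose change is zero the index is
#' undefined and `NA` is returned (pipeline code records an exclusion
#' reason rather than producing an infinity).
#'
#' @param times Sampling times in minutes (must contain 0 and 30).
#' @param glucose,insulin Concentrations at `times`, mmol/l and mU/l.
#' @return mU/mmol, or `NA` when the glucose denominator is zero.
#' @export
insulinogenic_index <- function(times, glucose, insulin) {
  check_series(times, glucose)
  check_series(times, insulin)
  i0 <- match(0, times); i30 <- match(30, times)
  if (is.na(i0) || is.na(i30)) {
    abort("insulinogenic index needs samples at 0 and 30 min; refusing to interpolate")
  }
  dg <- glucose[i30] - glucose[i0]
  if (dg == 0) return(NA_real_)
  (insulin[i30] - insulin[i0]) / dg
}

#' Total insulin response: the insulin secretion index
#'
#' Ratio of total insulin AUC to total glucose AUC over the meal test.
#'
#' @inheritParams insulinogenic_index
#' @return mU/mmol.
#' @export
insulin_secretion_index <- function(times, glucose, insulin) {
  total_auc(times, insulin) / total_auc(times, glucose)
}

#' Oral disposition index
#'
#' Beta-cell function relative to prevailing insulin sensitivity: the product
#' of the Matsuda-type sensitivity index and the insulin secretion index.
#' Along the hyperbola of appropriate compensation this product is constant;
#' see [fit_di_hyperbola()].
#'
#' @param isi_mat Composite sensitivity index, > 0.
#' @param secretion_index Insulin secretion index, mU/mmol, > 0.
#' @return Dimensionless disposition index.
#' @export
oral_di <- function(isi_mat, secretion_index) {
  check_positive(isi_mat = isi_mat, secretion_index = secretion_index)
  isi_mat * secretion_index
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v)) abort(sprintf("%s must be numeric", nm))
    if (any(v <= 0, na.rm = TRUE)) {
      abort(sprintf("%s must be strictly positive", nm))
    }
  }
  invisible(TRUE)
}
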