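#' Convert glucose concentrations between mg/dl and mmol/l
#'
#' The conversion factor is fixed at 18.0 mg/dl per mmol/l so that the common
#' clinical equivalence 90 mg/dl = 5 mmol/l holds exactly. All internal
#' computations in glycurve use mmol/l; conversion belongs at the I/O boundary.
#'
#' @param x Numeric vector of concentrations (must be non-negative).
#' @param from,to Unit strings, one of `"mg/dl"` or `"mmol/l"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_glucose(90, "mg/dl", "mmol/l") # 5
#' @export
convert_glucose <- function(x, from, to) {
  convert_conc(x, from, to, units = c("mg/dl", "mmol/l"),
               factor = 18, base = "mmol/l", what = "glucose")
}

#' Convert insulin concentrations between pmol/l and mU/l
#'
#' Uses the clinical convention of 6.0 pmol/l per mU/l. Canonical internal
#' unit is mU/l.
#'
#' @inheritParams convert_glucose
#' @param from,to Unit strings, one of `"pmol/l"` or `"mU/l"`.
#' @param factor pmol/l per mU/l; 6.0 by convention, exposed for labs that
#'   calibrate differently.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_insulin(45.24, "pmol/l", "mU/l")
#' @export
convert_insulin <- function(x, from, to, factor = 6) {
  convert_conc(x, from, to, units = c("pmol/l", "mU/l"),
               factor = factor, base = "mU/l", what = "insulin")
}

convert_conc <- function(x, from, to, units, factor, base, what) {
  from <- match_unit(from, units, what)
  to <- match_unit(to, units, what)
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) {
    abort(paste0("negative ", what, " concentration"))
  }
  if (from == to) return(x)
  # units[1] is the mass/molar alternative, `base` the canonical unit
  if (from == base) x * factor else x / factor
}

match_unit <- function(u, units, what) {
  if (!is.character(u) || length(u) != 1 || !u %in% units) {
    abort(sprintf("unknown %s unit '%s'; expected one of: %s",
                  what, paste(u, collapse = ", "),
                  paste(units, collapse = ", ")))
  }
  u
}
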