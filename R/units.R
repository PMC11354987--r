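#' Unit conversion for thyroid laboratory values
#'
#' Thyroid function tests are reported in a mixture of SI (molar) and
#' conventional (mass) units.  Canonical units in this package are pmol/L
#' for the free hormones (fT3, fT4) and mU/L for TSH.  Mass-to-molar
#' conversion uses the molar masses of the hormones themselves:
#' thyroxine (T4) 776.87 g/mol, triiodothyronine (T3) 650.97 g/mol
#' (standard reference values).  TSH is measured in international units
#' only and has no mass/molar conversion; all its registered units are
#' synonymous with mU/L.
#'
#' Conversion factors are assembled from exact scale chains
#' (SI prefix x volume x molar mass) rather than hard-coded decimals, so
#' precision is limited only by the molar-mass constants, and every
#' conversion is linear with zero offset.
#'
#' @section Registered units:
#' \describe{
#'   \item{fT3}{pmol/L (canonical), pg/mL, ng/dL, pg/dL, ng/L}
#'   \item{fT4}{pmol/L (canonical), ng/dL, pg/mL, ng/L}
#'   \item{TSH}{mU/L (canonical), uIU/mL, mIU/L, uU/mL}
#' }
#' The micro prefix may be written "u", "µ" (micro sign) or
#' "μ" (Greek mu).
#'
#' @name thyroid_units
NULL

MOLAR_MASS_T4 <- 776.87   # g/mol, thyroxine
MOLAR_MASS_T3 <- 650.97   # g/mol, triiodothyronine

## factor taking 1 <mass unit> to pmol/L for molar mass M:
## (grams per litre implied by the unit) / M mol/L * 1e12 pmol/mol
.mass_to_pmol <- function(g_per_L, M) g_per_L / M * 1e12

.unit_registry <- function() {
  t3 <- MOLAR_MASS_T3
  t4 <- MOLAR_MASS_T4
  list(
    fT3 = c("pmol/L" = 1,
            "pg/mL"  = .mass_to_pmol(1e-12 / 1e-3, t3),
            "ng/dL"  = .mass_to_pmol(1e-9 / 1e-1, t3),
            "pg/dL"  = .mass_to_pmol(1e-12 / 1e-1, t3),
            "ng/L"   = .mass_to_pmol(1e-9, t3)),
    fT4 = c("pmol/L" = 1,
            "ng/dL"  = .mass_to_pmol(1e-9 / 1e-1, t4),
            "pg/mL"  = .mass_to_pmol(1e-12 / 1e-3, t4),
            "ng/L"   = .mass_to_pmol(1e-9, t4)),
    TSH = c("mU/L"   = 1,
            "uIU/mL" = 1,
            "mIU/L"  = 1,
            "uU/mL"  = 1)
  )
}

.canonical_unit <- c(fT3 = "pmol/L", fT4 = "pmol/L", TSH = "mU/L")

.normalize_unit_symbol <- function(unit) {
  unit <- gsub("µ|μ", "u", unit)
  gsub("\\s+", "", unit)
}

.unit_factor <- function(analyte, unit) {
  reg <- .unit_registry()
  if (!analyte %in% names(reg))
    stop(sprintf("unknown analyte '%s' (expected fT3, fT4 or TSH)", analyte),
         call. = FALSE)
  u <- .normalize_unit_symbol(unit)
  tab <- reg[[analyte]]
  if (!u %in% names(tab))
    stop(sprintf("unit '%s' is not registered for analyte %s (supported: %s)",
                 unit, analyte, paste(names(tab), collapse = ", ")),
         call. = FALSE)
  unname(tab[[u]])
}

#' A thyroid laboratory quantity
#'
#' @param value non-negative numeric value(s).
#' @param analyte one of \code{"fT3"}, \code{"fT4"}, \code{"TSH"}.
#' @param unit unit symbol registered for the analyte
#'   (see \link{thyroid_units}).
#' @return an object of class \code{"thyro_quantity"}.
#' @export
quantity <- function(value, analyte = c("fT3", "fT4", "TSH"), unit) {
  analyte <- match.arg(analyte)
  if (any(!is.finite(value)) || any(value < 0))
    stop("quantity values must be finite and non-negative", call. = FALSE)
  .unit_factor(analyte, unit)  # validates the unit
  structure(list(value = value, analyte = analyte,
                 unit = .normalize_unit_symbol(unit)),
            class = "thyro_quantity")
}

#' @export
print.thyro_quantity <- function(x, ...) {
  cat(sprintf("%s: %s %s\n", x$analyte,
              paste(signif(x$value, 6), collapse = ", "), x$unit))
  invisible(x)
}

#' Convert a thyroid quantity between registered units
#'
#' @param q a \code{\link{quantity}}.
#' @param target_unit unit symbol registered for \code{q$analyte}.
#' @return a \code{thyro_quantity} in the target unit.
#' @examples
#' convert(quantity(1, "fT4", "ng/dL"), "pmol/L")  # 12.87 pmol/L
#' @export
convert <- function(q, target_unit) {
  stopifnot(inherits(q, "thyro_quantity"))
  f_from <- .unit_factor(q$analyte, q$unit)
  f_to <- .unit_factor(q$analyte, target_unit)
  quantity(q$value * f_from / f_to, q$analyte, target_unit)
}

#' Express a thyroid measurement in canonical units
#'
#' Canonical units are pmol/L for fT3/fT4 and mU/L for TSH.
#'
#' @param value numeric value(s).
#' @param analyte \code{"fT3"}, \code{"fT4"} or \code{"TSH"}.
#' @param unit the unit the value is expressed in.
#' @return numeric value(s) in the canonical unit.
#' @export
to_canonical <- function(value, analyte, unit) {
  q <- quantity(value, analyte, unit)
  convert(q, .canonical_unit[[analyte]])$value
}

#' Table of registered units and conversion factors
#'
#' @return a data.frame with columns \code{analyte}, \code{unit},
#'   \code{to_canonical} (multiplicative factor into the canonical unit)
#'   and \code{canonical_unit}.
#' @export
unit_table <- function() {
  reg <- .unit_registry()
  do.call(rbind, lapply(names(reg), function(a) {
    data.frame(analyte = a, unit = names(reg[[a]]),
               to_canonical = unname(reg[[a]]),
               canonical_unit = .canonical_unit[[a]],
               row.names = NULL)
  }))
}
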