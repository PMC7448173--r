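# Dose unit normalization and the dose-error factor.
#
# A dose unit is an amount unit optionally divided by weight/BSA and/or time
# denominators ("mg", "mcg/kg/min", "units/h"). Amount units convert within a
# dimension (mass, activity, volume, amount-of-substance); denominators must
# match after canonicalization. Incompatible dimensions (mass vs volume with
# no concentration to bridge) yield NA rather than a guess; doses with no
# unit recorded are treated as unitless and excluded.

#' Dose-unit conversion table
#'
#' Maps amount-unit spellings to a dimension and a factor into that
#' dimension's canonical unit (mg, units, mL, mmol).
#'
#' @return data frame with columns `unit`, `dimension`, `factor`.
#' @export
dose_unit_table <- function() {
  data.frame(
    unit = c("ng", "mcg", "ug", "µg", "mg", "g", "kg",
             "milliunits", "mu", "units", "unit", "u", "iu",
             "ml", "l",
             "mmol", "mol", "meq"),
    dimension = c(rep("mass", 7), rep("activity", 6), rep("volume", 2),
                  rep("substance", 3)),
    factor = c(1e-6, 1e-3, 1e-3, 1e-3, 1, 1e3, 1e6,
               1e-3, 1e-3, 1, 1, 1, 1,
               1, 1e3,
               1, 1e3, 1),
    stringsAsFactors = FALSE
  )
}

canonical_denominator <- function(d) {
  d <- tolower(trimws(d))
  d[d %in% c("h", "hr", "hour")] <- "h"
  d[d %in% c("min", "minute")] <- "min"
  d[d %in% c("d", "day", "24h")] <- "24h"
  d[d %in% c("m2", "m^2")] <- "m2"
  d
}

parse_dose_unit <- function(unit, table = dose_unit_table()) {
  unit <- ifelse(is.na(unit), "", trimws(unit))
  parts <- strsplit(tolower(unit), "/", fixed = TRUE)
  amount <- vapply(parts, function(p) if (length(p)) p[1] else "", character(1))
  denom <- vapply(parts, function(p)
    paste(canonical_denominator(p[-1]), collapse = "/"), character(1))
  m <- match(trimws(amount), table$unit)
  data.frame(dimension = table$dimension[m], factor = table$factor[m],
             denominator = denom, stringsAsFactors = FALSE)
}

#' Dose-error factor
#'
#' Ratio of the cancelled (erroneous) dose to the corrected dose after unit
#' normalization -- the "times the corrected dose" statistic. A factor above
#' 1 is a potential overdose, below 1 a potential underdose; both are
#' retained. Vectorized; returns `NA` (with a warning) where the units are of
#' incompatible dimensions, have mismatched denominators, or are missing, and
#' where either dose is absent or the corrected dose is zero.
#'
#' @param cancelled_dose,corrected_dose numeric dose values.
#' @param cancelled_unit,corrected_unit unit strings (e.g. `"mg"`,
#'   `"mcg/kg/min"`).
#' @param unit_table conversion table, see [dose_unit_table()].
#' @return positive numeric vector of factors with `NA` for incomparable
#'   pairs.
#' @export
#' @examples
#' dose_error_factor(15, "mg", 10, "mg")      # 1.5
#' dose_error_factor(1000, "mcg", 1, "mg")    # 1
#' dose_error_factor(50, "mg", 0.1, "mg")     # 500
dose_error_factor <- function(cancelled_dose, cancelled_unit,
                              corrected_dose, corrected_unit,
                              unit_table = dose_unit_table()) {
  n <- max(length(cancelled_dose), length(corrected_dose))
  cancelled_dose <- rep_len(as.numeric(cancelled_dose), n)
  corrected_dose <- rep_len(as.numeric(corrected_dose), n)
  a <- parse_dose_unit(rep_len(as.character(cancelled_unit), n), unit_table)
  b <- parse_dose_unit(rep_len(as.character(corrected_unit), n), unit_table)
  comparable <- !is.na(a$dimension) & !is.na(b$dimension) &
    a$dimension == b$dimension & a$denominator == b$denominator
  valid <- comparable & !is.na(cancelled_dose) & !is.na(corrected_dose) &
    corrected_dose > 0 & cancelled_dose >= 0
  out <- rep(NA_real_, n)
  out[valid] <- (cancelled_dose[valid] * a$factor[valid]) /
    (corrected_dose[valid] * b$factor[valid])
  n_bad <- sum(!comparable & !is.na(cancelled_dose) & !is.na(corrected_dose))
  if (n_bad) warnf("%d dose pair(s) had incompatible or missing units; factor set to NA",
                   n_bad)
  out
}

# rel-tol equality of two doses after unit normalization; NA-safe (NA pairs
# and incomparable units count as "not demonstrably different")
doses_equal <- function(d1, u1, d2, u2, tol = 1e-6,
                        unit_table = dose_unit_table()) {
  f <- suppressWarnings(dose_error_factor(d1, u1, d2, u2, unit_table))
  !is.na(f) & abs(f - 1) <= tol
}

# incomparable units are never taken as evidence of a dose change
doses_differ <- function(d1, u1, d2, u2, tol = 1e-6,
                         unit_table = dose_unit_table()) {
  f <- suppressWarnings(dose_error_factor(d1, u1, d2, u2, unit_table))
  !is.na(f) & abs(f - 1) > tol
}
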