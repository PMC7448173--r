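# Formulary (DERS master library) model and IO.
#
# A formulary entry is keyed by (profile, core_name, therapy_name). The pump
# interface caps the medication name at 20 characters, with an optional
# therapy line of a further 20 characters below it; both caps are enforced at
# construction. TALLman forms are stored verbatim (capitals preserved) and all
# comparisons elsewhere go through normalize_name().

formulary_columns <- function() {
  c("profile", "core_name", "therapy_name", "tallman_form",
    "soft_min", "soft_max", "hard_min", "hard_max",
    "conc_min", "conc_max", "standard_concentrations")
}

#' Construct a formulary
#'
#' Validates entries against the pump's character caps and key uniqueness.
#' Entries whose `core_name` or `therapy_name` exceeds 20 characters, or whose
#' `tallman_form` does not case-fold to `core_name`, are rejected with a
#' validation message (kept in `attr(x, "rejected")`), mirroring what the
#' pump's library editor would refuse. Duplicate (profile, core_name,
#' therapy_name) keys are a fatal error.
#'
#' @param entries data frame with columns `profile`, `core_name`, and
#'   optionally `therapy_name`, `tallman_form`, soft/hard dose limits
#'   (`soft_min`, `soft_max`, `hard_min`, `hard_max`), concentration limits
#'   (`conc_min`, `conc_max`) and `standard_concentrations` (list column or
#'   semicolon-separated string). An empty `standard_concentrations` together
#'   with concentration limits is the "wildcard"/custom-concentration set-up.
#' @return a `pump_formulary` data frame.
#' @export
formulary <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1)
  f <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(f$therapy_name)) f$therapy_name <- ""
  if (is.null(f$tallman_form)) f$tallman_form <- ""
  for (col in c("soft_min", "soft_max", "hard_min", "hard_max",
                "conc_min", "conc_max"))
    if (is.null(f[[col]])) f[[col]] <- NA_real_ else
      f[[col]] <- as.numeric(f[[col]])
  if (is.null(f$standard_concentrations)) {
    f$standard_concentrations <- vector("list", nrow(f))
  } else if (is.character(f$standard_concentrations)) {
    f$standard_concentrations <-
      lapply(strsplit(f$standard_concentrations, ";", fixed = TRUE),
             function(s) as.numeric(s[nzchar(s)]))
  }
  f$therapy_name[is.na(f$therapy_name)] <- ""
  f$tallman_form[is.na(f$tallman_form)] <- ""

  reason <- rep(NA_character_, nrow(f))
  reason[nchar(f$core_name) > 20] <- "core_name exceeds 20 characters"
  reason[is.na(reason) & nchar(f$therapy_name) > 20] <-
    "therapy_name exceeds 20 characters"
  tall_bad <- nzchar(f$tallman_form) &
    tolower(f$tallman_form) != tolower(f$core_name)
  reason[is.na(reason) & tall_bad] <-
    "tallman_form does not case-fold to core_name"
  if (any(!is.na(reason)))
    warnf("rejected %d formulary entr%s: %s",
          sum(!is.na(reason)), if (sum(!is.na(reason)) == 1) "y" else "ies",
          paste(unique(reason[!is.na(reason)]), collapse = "; "))
  rejected <- f[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  f <- f[is.na(reason), , drop = FALSE]
  if (!nrow(f)) stopf("no valid formulary entries remain")

  key <- paste(f$profile, f$core_name, f$therapy_name, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate formulary key(s): %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  rownames(f) <- NULL
  structure(f[, formulary_columns()], class = c("pump_formulary", "data.frame"),
            rejected = rejected)
}

#' Read a formulary from CSV
#'
#' Expects the header `profile,core_name,therapy_name,tallman_form,soft_min,
#' soft_max,hard_min,hard_max,conc_min,conc_max,standard_concentrations`, the
#' last column a semicolon-separated number list.
#'
#' @param source path or connection.
#' @return a `pump_formulary` (see [formulary()] for validation behaviour).
#' @export
read_formulary <- function(source) {
  raw <- utils::read.csv(source, colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("profile", "core_name")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stopf("formulary is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (col in c("soft_min", "soft_max", "hard_min", "hard_max",
                "conc_min", "conc_max"))
    if (!is.null(raw[[col]]))
      raw[[col]] <- suppressWarnings(as.numeric(ifelse(raw[[col]] == "",
                                                       NA, raw[[col]])))
  formulary(raw)
}

#' Write a formulary to CSV
#' @param form a `pump_formulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_formulary <- function(form, path) {
  stopifnot(inherits(form, "pump_formulary"))
  out <- as.data.frame(form)
  out$standard_concentrations <-
    vapply(out$standard_concentrations, function(v) {
      if (is.null(v) || !length(v)) return("")
      paste(format(v, trim = TRUE, scientific = FALSE), collapse = ";")
    }, character(1))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pump_formulary <- function(x, ...) {
  cat("<pump_formulary> ", nrow(x), " entries across ",
      length(unique(x$profile)), " profile(s)\n", sep = "")
  NextMethod()
}

#' Built-in demonstration formulary
#'
#' A small, synthetic care-area library assembled from publicly known
#' medication names (antimicrobials, electrolytes, monoclonal antibodies,
#' oncology therapies, common drips). It exercises every feature the analytics
#' need: TALLman forms, therapy lines, near-identical LASA neighbours, names
#' at the 20-character interface cap, and wildcard concentration entries.
#' It is not any facility's real library.
#'
#' @return a `pump_formulary`.
#' @export
default_formulary <- function() {
  e <- function(profile, core, therapy = "", tallman = "",
                soft = c(NA, NA), hard = c(NA, NA)) {
    data.frame(profile = profile, core_name = core, therapy_name = therapy,
               tallman_form = tallman, soft_min = soft[1], soft_max = soft[2],
               hard_min = hard[1], hard_max = hard[2],
               conc_min = NA_real_, conc_max = NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    e("adult_general", "Sodium bicarbonate", soft = c(10, 200), hard = c(5, 400)),
    e("adult_general", "Sodium phosphate", soft = c(10, 100), hard = c(5, 200)),
    e("adult_general", "Acetaminophen", soft = c(100, 1000), hard = c(50, 1500)),
    e("adult_general", "Abatacept <60 kg", soft = c(100, 750), hard = c(50, 1000)),
    e("adult_general", "Acetylcysteine", soft = c(100, 1000), hard = c(50, 2000)),
    e("adult_general", "Acyclovir", soft = c(100, 800), hard = c(50, 1200)),
    e("adult_general", "Ceftazidime", soft = c(250, 2000), hard = c(100, 3000)),
    e("adult_general", "Ceftriaxone", soft = c(250, 2000), hard = c(100, 4000)),
    e("adult_general", "Cefazolin", soft = c(250, 2000), hard = c(100, 3000)),
    e("adult_general", "Ceftazidime-Continuo", soft = c(250, 6000), hard = c(100, 8000)),
    e("adult_general", "Ceftazidime-extended", soft = c(250, 6000), hard = c(100, 8000)),
    e("adult_general", "Flucloxacillin", soft = c(250, 2000), hard = c(100, 2000)),
    e("adult_general", "FLUconazole", tallman = "FLUconazole", soft = c(50, 800), hard = c(25, 1600)),
    e("adult_general", "Calcium chloride", soft = c(100, 1000), hard = c(50, 2000)),
    e("adult_general", "Calcium gluconate", soft = c(100, 3000), hard = c(50, 6000)),
    e("adult_general", "0.45% NS", soft = c(10, 1000), hard = c(5, 2000)),
    e("adult_general", "0.9% Normal saline", soft = c(10, 1000), hard = c(5, 2000)),
    e("adult_critical_care", "Insulin high non-ICU", soft = c(1, 20), hard = c(0.5, 40)),
    e("adult_critical_care", "Insulin hyperkalemia", soft = c(1, 20), hard = c(0.5, 40)),
    e("adult_critical_care", "Insulin continuous", soft = c(0.5, 25), hard = c(0.1, 50)),
    e("adult_critical_care", "Heparin low dose", soft = c(100, 1500), hard = c(50, 2500)),
    e("adult_critical_care", "Heparin high dose", soft = c(100, 2500), hard = c(50, 4000)),
    e("adult_critical_care", "Amiodarone load", soft = c(50, 300), hard = c(25, 450)),
    e("adult_critical_care", "Amiodarone maint", soft = c(10, 100), hard = c(5, 150)),
    e("adult_critical_care", "Midazolam", "Short-term vent", soft = c(1, 20), hard = c(0.5, 40)),
    e("adult_critical_care", "Midazolam", "Conscious sedation", soft = c(0.5, 10), hard = c(0.25, 20)),
    e("adult_critical_care", "Norepinephrine", soft = c(0.5, 30), hard = c(0.1, 60)),
    e("adult_critical_care", "Amphotericin B", soft = c(10, 300), hard = c(5, 500)),
    e("adult_critical_care", "Ampho B (liposomal)", soft = c(50, 500), hard = c(25, 800)),
    e("oncology", "PACLitaxel weekly", tallman = "PACLitaxel weekly", soft = c(50, 200), hard = c(25, 300)),
    e("oncology", "PACLitaxel 3 weekly", tallman = "PACLitaxel 3 weekly", soft = c(100, 400), hard = c(50, 500)),
    e("oncology", "CISplatin", tallman = "CISplatin", soft = c(10, 200), hard = c(5, 300)),
    e("oncology", "CARBOplatin", tallman = "CARBOplatin", soft = c(50, 900), hard = c(25, 1200)),
    e("oncology", "Cantuzumab mertansin", soft = c(10, 500), hard = c(5, 800)),
    e("oncology", "Cantuzumab ravtansin", soft = c(10, 500), hard = c(5, 800)),
    e("oncology", "Altumomab pentetate", soft = c(10, 500), hard = c(5, 800)),
    e("oncology", "Trastuzumab", soft = c(50, 800), hard = c(25, 1000)),
    e("oncology", "Talizumab", soft = c(10, 500), hard = c(5, 800)),
    e("oncology", "Tanezumab", soft = c(10, 500), hard = c(5, 800)),
    e("pain_service", "Morphine PCA", soft = c(1, 10), hard = c(0.5, 20)),
    e("pain_service", "HYDROmorphone PCA", tallman = "HYDROmorphone PCA", soft = c(0.2, 2), hard = c(0.1, 4))
  )
  # wildcard concentration example: limits without standard concentrations
  rows$conc_min[rows$core_name == "Norepinephrine"] <- 0.016
  rows$conc_max[rows$core_name == "Norepinephrine"] <- 0.256
  formulary(rows)
}
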