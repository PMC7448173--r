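# Cause classification for cancelled infusions.
#
# Decision ladder, first match wins. The order matters: a concentration-limit
# breach is flagged by its dedicated alert and must not leak into the dose
# errors; a channel swap keeps the medication name so it must be recognised
# before the name comparison; name mismatch outranks dose mismatch because a
# different drug makes the dose comparison meaningless.

#' Cancellation cause labels
#' @return character vector of the six cause categories.
#' @export
cause_labels <- function() {
  c("INCORRECT_MEDICATION", "WRONG_DOSE", "INDETERMINATE",
    "WRONG_CHANNEL", "DOSE_CANCELLED_CALC", "CONC_LIMIT_BREACH")
}

#' Classify causes of cancelled infusions
#'
#' Applies the cause ladder to every correction pair:
#'
#' 1. cancelled sequence contains a concentration-limit alert ->
#'    `CONC_LIMIT_BREACH`;
#' 2. replacement is a drug-calculator start -> `DOSE_CANCELLED_CALC`
#'    (library exited, calculator used);
#' 3. same normalized medication, replacement on the sibling module in a
#'    PCA/syringe swap -> `WRONG_CHANNEL`;
#' 4. replacement present, normalized medication names differ ->
#'    `INCORRECT_MEDICATION`;
#' 5. replacement present, same name, dose or concentration differs beyond
#'    unit-normalized equality (relative tolerance `tol`) -> `WRONG_DOSE`;
#' 6. otherwise `INDETERMINATE` (no replacement, identical reprogram, or a
#'    basic-mode replacement that records no name -- the latter flagged).
#'
#' Also computes `dose_error_factor` for `WRONG_DOSE` pairs and the LASA
#' divergence position for `INCORRECT_MEDICATION` pairs.
#'
#' @param pairs a `correction_pairs` data frame from [pair_cancellations()].
#' @param formulary optional `pump_formulary` (reserved for therapy-aware
#'   normalization; names are compared in full by default, since a therapy
#'   mix-up is still a wrong-entity selection at the pump).
#' @param tol relative tolerance for dose/concentration equality after unit
#'   normalization (default `1e-6`, guarding against float-format artefacts).
#' @param unit_table see [dose_unit_table()].
#' @return `pairs` with columns `cause`, `flag`, `dose_error_factor`,
#'   `lasa_position`, `lasa_fraction` added.
#' @export
classify_causes <- function(pairs, formulary = NULL, tol = 1e-6,
                            unit_table = dose_unit_table()) {
  stopifnot(inherits(pairs, "correction_pairs"))
  n <- nrow(pairs)
  cause <- rep(NA_character_, n)
  flag <- rep("", n)

  has_repl <- !is.na(pairs$replacement_seq_id)
  norm_c <- normalize_name(pairs$cancelled_name, strip_therapy = FALSE)
  norm_r <- ifelse(is.na(pairs$replacement_name), "",
                   normalize_name(pairs$replacement_name,
                                  strip_therapy = FALSE))
  named_both <- nzchar(norm_c) & nzchar(norm_r)
  same_name <- named_both & norm_c == norm_r
  is_calc <- has_repl & !is.na(pairs$replacement_start_event) &
    pairs$replacement_start_event == "CALC_START"
  pca_swap <- has_repl & pairs$cross_module &
    !is.na(pairs$replacement_module_type) &
    ((pairs$cancelled_module_type == "SYRINGE" &
        pairs$replacement_module_type == "PCA") |
       (pairs$cancelled_module_type == "PCA" &
          pairs$replacement_module_type == "SYRINGE"))
  dose_diff <- doses_differ(pairs$cancelled_dose, pairs$cancelled_unit,
                            pairs$replacement_dose, pairs$replacement_unit,
                            tol, unit_table)
  conc_diff <- !is.na(pairs$cancelled_conc) & !is.na(pairs$replacement_conc) &
    pairs$replacement_conc > 0 &
    abs(pairs$cancelled_conc / pairs$replacement_conc - 1) > tol

  cause[pairs$has_conc_alert] <- "CONC_LIMIT_BREACH"
  set <- function(cond, label) {
    sel <- is.na(cause) & cond
    cause[sel] <<- label
    sel
  }
  set(is_calc, "DOSE_CANCELLED_CALC")
  set(same_name & pca_swap, "WRONG_CHANNEL")
  set(has_repl & named_both & !same_name, "INCORRECT_MEDICATION")
  set(has_repl & same_name & (dose_diff | conc_diff), "WRONG_DOSE")
  basic_repl <- is.na(cause) & has_repl & !nzchar(norm_r)
  flag[basic_repl] <- "replacement without medication name"
  cause[is.na(cause)] <- "INDETERMINATE"

  pairs$cause <- cause
  pairs$flag <- flag
  pairs$dose_error_factor <- rep(NA_real_, n)
  wd <- cause == "WRONG_DOSE"
  if (any(wd))
    pairs$dose_error_factor[wd] <-
      dose_error_factor(pairs$cancelled_dose[wd], pairs$cancelled_unit[wd],
                        pairs$replacement_dose[wd], pairs$replacement_unit[wd],
                        unit_table)
  pairs$lasa_position <- rep(NA_character_, n)
  pairs$lasa_fraction <- rep(NA_real_, n)
  im <- which(cause == "INCORRECT_MEDICATION")
  if (length(im)) {
    dv <- divergence_position(pairs$cancelled_name[im],
                              pairs$replacement_name[im])
    pairs$lasa_position[im] <- dv$class
    pairs$lasa_fraction[im] <- dv$fraction
  }
  pairs
}

#' Classify a single correction pair
#'
#' Convenience wrapper around [classify_causes()] for one pair.
#'
#' @inheritParams classify_causes
#' @param pair a one-row `correction_pairs` data frame.
#' @return the cause label (character scalar).
#' @export
classify_cause <- function(pair, formulary = NULL, tol = 1e-6,
                           unit_table = dose_unit_table()) {
  stopifnot(nrow(pair) == 1L)
  classify_causes(pair, formulary, tol, unit_table)$cause
}
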