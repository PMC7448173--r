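# Structural validation of an event log (reporting only, never mutates).

#' Validate an event log
#'
#' Scans a `pump_log` for structural anomalies and reports counts with
#' exemplar file rows. Anomaly classes:
#'
#' * `orphan_resolutions`: an `OVERRIDE`/`REPROGRAM`/`CANCEL` whose sequence
#'   contains neither an alert nor a `PROGRAM_SELECT` -- a resolution with
#'   nothing to resolve.
#' * `duplicate_sequence_ids`: a non-empty `sequence_id` reused on more than
#'   one device+module (sequences are split per module downstream, but reuse
#'   is flagged here).
#' * `time_regressions`: pairs of events on one module whose timestamps run
#'   backwards relative to file order (total pairwise inversion count).
#' * `misrecorded_names`: `BASIC_INFUSION_START`/`CALC_START` rows carrying a
#'   medication name, which those pump modes never record.
#' * `missing_sequence_ids`: alert rows (other than `OTHER_ALERT`) without the
#'   sequence identifier that ties an alert group together.
#'
#' @param log a `pump_log`.
#' @return a `pump_log_validation` list: per-class `count` and up to five
#'   `exemplar` file rows, plus `clean` (TRUE iff all counts are 0).
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "pump_log"))
  r <- log$records
  item <- function(rows) list(count = length(rows),
                              exemplars = utils::head(sort(rows), 5))

  res_types <- c("OVERRIDE", "REPROGRAM", "CANCEL")
  alert_types <- c("SOFT_LIMIT_ALERT", "HARD_LIMIT_ALERT", "CONC_LIMIT_ALERT",
                   "OTHER_ALERT")
  uid <- paste(r$device_id, r$module_id, r$sequence_id, sep = "\r")
  uid[!nzchar(r$sequence_id)] <- paste0("@", seq_len(nrow(r)))[!nzchar(r$sequence_id)]
  anchored <- r$event_type %in% c(alert_types, "PROGRAM_SELECT")
  anchored_uids <- unique(uid[anchored])
  orphan <- r$event_type %in% res_types & !(uid %in% anchored_uids)

  sid_mod <- unique(data.frame(sid = r$sequence_id,
                               mod = paste(r$device_id, r$module_id),
                               stringsAsFactors = FALSE))
  sid_mod <- sid_mod[nzchar(sid_mod$sid), , drop = FALSE]
  dup_sids <- unique(sid_mod$sid[duplicated(sid_mod$sid)])
  dup_rows <- which(r$sequence_id %in% dup_sids)

  mod <- paste(r$device_id, r$module_id)
  inv <- 0
  for (m in unique(mod)) {
    i <- mod == m
    ts <- as.numeric(r$timestamp[i])[order(r$file_order[i])]
    inv <- inv + count_inversions(ts)
  }

  misnamed <- r$event_type %in% c("BASIC_INFUSION_START", "CALC_START") &
    nzchar(r$medication_name)
  unsequenced <- r$event_type %in% setdiff(alert_types, "OTHER_ALERT") &
    !nzchar(r$sequence_id)

  out <- list(
    orphan_resolutions = item(r$file_order[orphan]),
    duplicate_sequence_ids = list(count = length(dup_sids),
                                  exemplars = utils::head(r$file_order[dup_rows], 5)),
    time_regressions = list(count = inv, exemplars = integer()),
    misrecorded_names = item(r$file_order[misnamed]),
    missing_sequence_ids = item(r$file_order[unsequenced])
  )
  out$clean <- all(vapply(out[names(out) != "clean"],
                          function(x) x$count == 0, logical(1)))
  structure(out, class = "pump_log_validation")
}

#' @export
print.pump_log_validation <- function(x, ...) {
  cat("<pump_log_validation>", if (x$clean) "clean\n" else "\n")
  for (nm in setdiff(names(x), "clean")) {
    cat(sprintf("  %-24s %d", nm, x[[nm]]$count))
    if (x[[nm]]$count && length(x[[nm]]$exemplars))
      cat("  (rows ", paste(x[[nm]]$exemplars, collapse = ", "), ")", sep = "")
    cat("\n")
  }
  invisible(x)
}
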