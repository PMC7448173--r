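# Event-log data model and delimited-text IO.
#
# The pump vendors' native export dialects are proprietary; the package defines
# an open CSV dialect (documented below) plus a column-map so other dialects
# can be adapted. Timestamps are ISO-8601 local time at 1-second resolution --
# pump logs report hh:mm:ss and all latency arithmetic is second-level, so no
# time-zone math is attempted.

#' Canonical event types
#'
#' Event vocabulary of the log model. `PROGRAM_SELECT` is the selection of a
#' medication program from the DERS library; `SOFT_LIMIT_ALERT`,
#' `HARD_LIMIT_ALERT` and `CONC_LIMIT_ALERT` are dose/concentration limit
#' alerts; `OVERRIDE`, `REPROGRAM` and `CANCEL` are user resolutions;
#' `INFUSION_START` is a library start, while `BASIC_INFUSION_START` (plain
#' mL/h mode) and `CALC_START` (drug calculator) are starts outside the
#' library that carry no medication name.
#'
#' @return character vector of valid `event_type` values.
#' @export
event_types <- function() {
  c("PROGRAM_SELECT", "SOFT_LIMIT_ALERT", "HARD_LIMIT_ALERT",
    "CONC_LIMIT_ALERT", "OVERRIDE", "REPROGRAM", "CANCEL",
    "INFUSION_START", "BASIC_INFUSION_START", "CALC_START", "OTHER_ALERT")
}

#' Canonical pump module types
#' @return character vector: large-volume pump, syringe driver, PCA module.
#' @export
module_types <- function() c("LARGE_VOLUME", "SYRINGE", "PCA")

log_columns <- function() {
  c("timestamp", "device_id", "module_id", "module_type", "profile",
    "sequence_id", "event_type", "medication_name", "therapy",
    "dose_value", "dose_unit", "concentration_value")
}

#' Event-log CSV dialect
#'
#' Describes how a delimited file maps onto the canonical event-log columns.
#' The default dialect is the package's own format: comma-separated, UTF-8,
#' header row `timestamp,device_id,module_id,module_type,profile,sequence_id,
#' event_type,medication_name,therapy,dose_value,dose_unit,concentration_value`.
#'
#' @param delim field delimiter (default `","`).
#' @param columns named character vector mapping canonical column names to the
#'   file's header names; defaults to the identity map. Every canonical column
#'   must be mapped.
#' @param timestamp_formats candidate `strptime` formats tried in order.
#' @return an object of class `log_dialect`.
#' @export
log_dialect <- function(delim = ",", columns = NULL,
                        timestamp_formats = c("%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%dT%H:%M:%S")) {
  cols <- log_columns()
  map <- stats::setNames(cols, cols)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), cols)
    if (length(bad)) stopf("unknown canonical columns in dialect: %s",
                           paste(bad, collapse = ", "))
    map[names(columns)] <- columns
  }
  structure(list(delim = delim, columns = map,
                 timestamp_formats = timestamp_formats),
            class = "log_dialect")
}

parse_log_timestamp <- function(x, formats) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  todo <- rep(TRUE, length(x))
  for (f in formats) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    out[todo][!is.na(p)] <- p[!is.na(p)]
    todo[todo] <- is.na(p)
  }
  out
}

new_pump_log <- function(records, quarantined = NULL, source_meta = list()) {
  o <- order(records$device_id, records$module_id, records$timestamp,
             records$file_order)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 quarantined = quarantined %||%
                   data.frame(file_row = integer(), reason = character()),
                 source_meta = source_meta),
            class = "pump_log")
}

empty_records <- function(n = 0) {
  data.frame(timestamp = as.POSIXct(numeric(n), origin = "1970-01-01",
                                    tz = "UTC"),
             device_id = character(n), module_id = character(n),
             module_type = character(n), profile = character(n),
             sequence_id = character(n), event_type = character(n),
             medication_name = character(n), therapy = character(n),
             dose_value = numeric(n), dose_unit = character(n),
             concentration_value = numeric(n), file_order = integer(n),
             stringsAsFactors = FALSE)
}

#' Build an event log from a records data frame
#'
#' Constructor used by the generator and by tests; applies the canonical sort
#' (device, module, timestamp, original order) and attaches provenance
#' metadata.
#'
#' @param records data frame with the canonical event-log columns (a
#'   `file_order` column is added if absent).
#' @param source_meta free-form provenance list.
#' @return a `pump_log` object.
#' @export
as_pump_log <- function(records, source_meta = list()) {
  missing_cols <- setdiff(setdiff(log_columns(), "file_order"),
                          names(records))
  if (length(missing_cols))
    stopf("records lack columns: %s", paste(missing_cols, collapse = ", "))
  if (is.null(records$file_order))
    records$file_order <- seq_len(nrow(records))
  new_pump_log(records[, c(log_columns(), "file_order")])
}

#' Read a pump event log
#'
#' Parses a delimited event-log export into a `pump_log`. Rows that cannot be
#' parsed (malformed timestamp, unknown event type) are quarantined with a
#' reason rather than silently dropped, so that
#' `nrow(records) + nrow(quarantined)` always equals the number of data rows
#' in the file. A missing mandatory column is a fatal configuration error.
#'
#' @param source path to a delimited text file (or a connection).
#' @param dialect a [log_dialect()] describing delimiter and column map.
#' @return a `pump_log`: list with `records` (parsed, canonically sorted data
#'   frame), `quarantined` (file row + reason), and `source_meta`.
#' @seealso [write_event_log()], [validate_log()]
#' @export
read_event_log <- function(source, dialect = log_dialect()) {
  stopifnot(inherits(dialect, "log_dialect"))
  raw <- utils::read.table(source, header = TRUE, sep = dialect$delim,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols))
    stopf("event log is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  rec <- empty_records(n)
  for (canon in names(dialect$columns)) {
    v <- raw[[dialect$columns[[canon]]]]
    if (canon %in% c("dose_value", "concentration_value")) {
      rec[[canon]] <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
    } else if (canon == "timestamp") {
      rec$timestamp <- parse_log_timestamp(v, dialect$timestamp_formats)
    } else {
      rec[[canon]] <- v
    }
  }
  rec$file_order <- seq_len(n)

  reason <- rep(NA_character_, n)
  reason[is.na(rec$timestamp)] <- "malformed timestamp"
  bad_type <- !(rec$event_type %in% event_types())
  reason[is.na(reason) & bad_type] <- "unknown event type"
  neg <- (!is.na(rec$dose_value) & rec$dose_value < 0) |
    (!is.na(rec$concentration_value) & rec$concentration_value < 0)
  reason[is.na(reason) & neg] <- "negative dose or concentration"

  keep <- is.na(reason)
  quarantined <- data.frame(file_row = which(!keep),
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  new_pump_log(rec[keep, , drop = FALSE], quarantined,
               source_meta = list(source = if (is.character(source)) source
                                  else "<connection>",
                                  n_input_rows = n))
}

#' Write a pump event log
#'
#' Emits the canonical CSV dialect. A write/read round trip through
#' [read_event_log()] preserves record count and all field values.
#'
#' @param log a `pump_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "pump_log"))
  out <- log$records[, setdiff(log_columns(), "file_order"), drop = FALSE]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pump_log <- function(x, ...) {
  r <- x$records
  cat("<pump_log> ", nrow(r), " events",
      if (nrow(x$quarantined)) paste0(" (+", nrow(x$quarantined),
                                      " quarantined rows)"), "\n", sep = "")
  if (nrow(r)) {
    cat("  devices: ", length(unique(r$device_id)),
        ", modules: ", length(unique(paste(r$device_id, r$module_id))),
        "\n  span: ", format(min(r$timestamp)), " .. ",
        format(max(r$timestamp)), "\n", sep = "")
    tt <- sort(table(r$event_type), decreasing = TRUE)
    cat("  top event types: ",
        paste(names(tt)[seq_len(min(4, length(tt)))],
              tt[seq_len(min(4, length(tt)))], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
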