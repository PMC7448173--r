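# Grouping events into alert sequences.
#
# Records sharing a sequence_id on one device+module form one sequence (the
# pump ties an alert group, from first alert to resolution, to a unique
# sequence identifier). Rows with an empty sequence_id (basic/calculator
# starts, some library starts) become singleton sequences so that every event
# is assigned to exactly one sequence.

outcome_from_terminal <- function(ev) {
  out <- rep("UNRESOLVED", length(ev))
  out[ev == "OVERRIDE"] <- "OVERRIDDEN"
  out[ev == "REPROGRAM"] <- "REPROGRAMMED"
  out[ev == "CANCEL"] <- "CANCELLED"
  out[ev %in% c("INFUSION_START", "BASIC_INFUSION_START", "CALC_START")] <-
    "STARTED"
  out
}

#' Group an event log into alert sequences
#'
#' Collapses a `pump_log` to one row per event sequence. The sequence outcome
#' is determined solely by the terminal (latest) event: `OVERRIDDEN`,
#' `REPROGRAMMED`, `CANCELLED`, `STARTED` (any infusion/calculator start) or
#' `UNRESOLVED`. Medication fields are taken from the first event in the
#' sequence that carries them. A `sequence_id` reused on different modules is
#' split per module (and flagged by [validate_log()]).
#'
#' @param log a `pump_log`.
#' @return a `pump_sequences` data frame, one row per sequence, with first and
#'   last timestamps, per-alert-type flags, start and cancel times, outcome
#'   and medication fields.
#' @seealso [pair_cancellations()]
#' @export
group_sequences <- function(log) {
  stopifnot(inherits(log, "pump_log"))
  r <- log$records
  if (!nrow(r)) return(empty_sequences())

  uid <- paste(r$device_id, r$module_id, r$sequence_id, sep = "\r")
  uid[!nzchar(r$sequence_id)] <-
    paste0("@singleton\r", r$file_order[!nzchar(r$sequence_id)])
  o <- order(uid, r$timestamp, r$file_order)
  r <- r[o, , drop = FALSE]
  uid <- uid[o]
  grp <- cumsum(!duplicated(uid))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  n_seq <- sum(first)

  has_type <- function(type) as.vector(rowsum(as.integer(r$event_type %in% type),
                                              grp) > 0)
  # first row per group satisfying a condition, NA-padded
  first_where <- function(cond, value) {
    idx <- which(cond)
    if (!length(idx)) return(rep(if (is.numeric(value)) NA_real_ else
      NA_character_, n_seq))
    g <- grp[idx]
    keep <- idx[!duplicated(g)]
    out <- rep(if (inherits(value, "POSIXct")) as.POSIXct(NA, tz = "UTC")
               else if (is.numeric(value)) NA_real_ else NA_character_, n_seq)
    out[unique(g)] <- value[keep]
    out
  }

  named <- nzchar(r$medication_name)
  dosed <- !is.na(r$dose_value)
  start_ev <- r$event_type %in% c("INFUSION_START", "BASIC_INFUSION_START",
                                  "CALC_START")
  cancel_ev <- r$event_type == "CANCEL"
  select_ev <- r$event_type == "PROGRAM_SELECT"

  seqs <- data.frame(
    sequence_id = r$sequence_id[first],
    device_id = r$device_id[first],
    module_id = r$module_id[first],
    module_type = r$module_type[first],
    profile = r$profile[first],
    n_events = as.vector(rowsum(rep(1L, nrow(r)), grp)),
    first_time = r$timestamp[first],
    last_time = r$timestamp[last],
    first_event = r$event_type[first],
    last_event = r$event_type[last],
    outcome = outcome_from_terminal(r$event_type[last]),
    has_conc_alert = has_type("CONC_LIMIT_ALERT"),
    has_hard_alert = has_type("HARD_LIMIT_ALERT"),
    has_soft_alert = has_type("SOFT_LIMIT_ALERT"),
    has_other_alert = has_type("OTHER_ALERT"),
    has_cancel = has_type("CANCEL"),
    has_program = has_type("PROGRAM_SELECT"),
    stringsAsFactors = FALSE
  )
  seqs$select_time <- as.POSIXct(first_where(select_ev, as.numeric(r$timestamp)),
                                 origin = "1970-01-01", tz = "UTC")
  seqs$start_time <- as.POSIXct(first_where(start_ev, as.numeric(r$timestamp)),
                                origin = "1970-01-01", tz = "UTC")
  seqs$cancel_time <- as.POSIXct(first_where(cancel_ev, as.numeric(r$timestamp)),
                                 origin = "1970-01-01", tz = "UTC")
  seqs$start_event <- first_where(start_ev, r$event_type)
  seqs$medication_name <- first_where(named, r$medication_name)
  seqs$medication_name[is.na(seqs$medication_name)] <- ""
  seqs$therapy <- first_where(named, r$therapy)
  seqs$therapy[is.na(seqs$therapy)] <- ""
  seqs$dose_value <- first_where(dosed, r$dose_value)
  seqs$dose_unit <- first_where(dosed, r$dose_unit)
  seqs$concentration_value <- first_where(!is.na(r$concentration_value),
                                          r$concentration_value)

  o2 <- order(seqs$device_id, seqs$module_id, seqs$first_time)
  seqs <- seqs[o2, , drop = FALSE]
  rownames(seqs) <- NULL
  class(seqs) <- c("pump_sequences", "data.frame")
  seqs
}

empty_sequences <- function() {
  s <- data.frame(sequence_id = character(), device_id = character(),
                  module_id = character(), module_type = character(),
                  profile = character(), n_events = integer(),
                  first_time = as.POSIXct(character(), tz = "UTC"),
                  last_time = as.POSIXct(character(), tz = "UTC"),
                  first_event = character(), last_event = character(),
                  outcome = character(), has_conc_alert = logical(),
                  has_hard_alert = logical(), has_soft_alert = logical(),
                  has_other_alert = logical(), has_cancel = logical(),
                  has_program = logical(),
                  select_time = as.POSIXct(character(), tz = "UTC"),
                  start_time = as.POSIXct(character(), tz = "UTC"),
                  cancel_time = as.POSIXct(character(), tz = "UTC"),
                  start_event = character(), medication_name = character(),
                  therapy = character(), dose_value = numeric(),
                  dose_unit = character(), concentration_value = numeric(),
                  stringsAsFactors = FALSE)
  class(s) <- c("pump_sequences", "data.frame")
  s
}
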