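# Pairing cancelled programs with their replacement programs.
#
# A near-miss "good save" shows up in the log as the cancellation of one
# program rapidly followed by the programming of a second. Each CANCELLED
# sequence is matched to the next confirmed program on the same device whose
# first event falls inside the pairing window. The same module is preferred;
# a different module on the same device is allowed (and flagged) because a
# wrong-channel correction -- e.g. a PCA medication first loaded on a syringe
# driver -- is by nature completed on a sibling module. The default window of
# 120 s covers the longest correction latencies seen in practice (~116 s).

#' Pair cancellations with replacement programs
#'
#' Greedy earliest-first matching: cancellations are processed in time order
#' per device and each takes the earliest not-yet-used confirmed program
#' (outcome `STARTED`) whose first event lies within `window_s` seconds of the
#' cancellation. This matching is maximal, deterministic for a given input,
#' and the number of paired cancellations is non-decreasing in `window_s`.
#' Latency is replacement program-confirmation time (its start event) minus
#' cancellation time; a negative latency (clock regression) rejects the pair
#' and is flagged.
#'
#' @param sequences a `pump_sequences` from [group_sequences()].
#' @param window_s pairing window in seconds (positive; default 120).
#' @return a `correction_pairs` data frame, one row per cancelled sequence:
#'   cancelled-side fields, replacement-side fields (`NA`/empty when
#'   unpaired), `latency_s` (integer seconds, `NA` iff unpaired) and a
#'   `cross_module` flag.
#' @export
pair_cancellations <- function(sequences, window_s = 120) {
  stopifnot(inherits(sequences, "pump_sequences"),
            is_scalar_number(window_s), window_s > 0)
  s <- sequences
  canc_idx <- which(s$outcome == "CANCELLED" & !is.na(s$cancel_time))
  cand_idx <- which(s$outcome == "STARTED" &
                      (s$has_program | s$first_event %in%
                         c("CALC_START", "BASIC_INFUSION_START")))

  n_canc <- length(canc_idx)
  na_chr <- rep(NA_character_, n_canc)
  pairs <- data.frame(
    cancelled_seq_id = s$sequence_id[canc_idx],
    device_id = s$device_id[canc_idx],
    cancelled_module_id = s$module_id[canc_idx],
    cancelled_module_type = s$module_type[canc_idx],
    profile = s$profile[canc_idx],
    cancel_time = s$cancel_time[canc_idx],
    select_time = s$select_time[canc_idx],
    has_conc_alert = s$has_conc_alert[canc_idx],
    cancelled_name = s$medication_name[canc_idx],
    cancelled_therapy = s$therapy[canc_idx],
    cancelled_dose = s$dose_value[canc_idx],
    cancelled_unit = s$dose_unit[canc_idx],
    cancelled_conc = s$concentration_value[canc_idx],
    replacement_seq_id = na_chr,
    replacement_module_id = na_chr,
    replacement_module_type = na_chr,
    replacement_start_event = na_chr,
    replacement_confirm_time = as.POSIXct(rep(NA_real_, n_canc),
                                          origin = "1970-01-01", tz = "UTC"),
    replacement_name = na_chr,
    replacement_therapy = na_chr,
    replacement_dose = rep(NA_real_, n_canc),
    replacement_unit = na_chr,
    replacement_conc = rep(NA_real_, n_canc),
    latency_s = rep(NA_integer_, n_canc),
    cross_module = rep(FALSE, n_canc),
    rejected_negative_latency = rep(FALSE, n_canc),
    stringsAsFactors = FALSE
  )
  if (!nrow(pairs)) {
    class(pairs) <- c("correction_pairs", "data.frame")
    return(pairs)
  }

  o <- order(pairs$device_id, pairs$cancel_time, pairs$cancelled_seq_id)
  pairs <- pairs[o, , drop = FALSE]
  canc_idx <- canc_idx[o]

  cand <- data.frame(idx = cand_idx,
                     device = s$device_id[cand_idx],
                     module = s$module_id[cand_idx],
                     t_first = as.numeric(s$first_time[cand_idx]),
                     used = rep(FALSE, length(cand_idx)),
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$device, cand$t_first, s$sequence_id[cand$idx]), ,
               drop = FALSE]
  # per-device candidate row ranges, times pre-sorted for findInterval()
  by_dev <- split(seq_len(nrow(cand)), cand$device)

  for (k in seq_len(nrow(pairs))) {
    rows <- by_dev[[pairs$device_id[k]]]
    if (is.null(rows)) next
    tc <- as.numeric(pairs$cancel_time[k])
    tv <- cand$t_first[rows]
    # timestamps have 1-second resolution; 0.5 s is a safe open-boundary
    # epsilon at epoch magnitudes (1e-9 would vanish in double precision)
    lo <- findInterval(tc - 0.5, tv) + 1L
    if (lo > length(rows)) next
    hi <- findInterval(tc + window_s + 0.5, tv)
    if (hi < lo) next
    ok <- rows[lo:hi]
    ok <- ok[!cand$used[ok]]
    if (!length(ok)) next
    same <- ok[cand$module[ok] == pairs$cancelled_module_id[k]]
    pick <- if (length(same)) same[1] else ok[1]
    j <- cand$idx[pick]
    confirm <- if (!is.na(s$start_time[j])) s$start_time[j] else s$last_time[j]
    lat <- as.numeric(confirm) - tc
    if (lat < 0) {
      pairs$rejected_negative_latency[k] <- TRUE
      next
    }
    cand$used[pick] <- TRUE
    pairs$replacement_seq_id[k] <- s$sequence_id[j]
    pairs$replacement_module_id[k] <- s$module_id[j]
    pairs$replacement_module_type[k] <- s$module_type[j]
    pairs$replacement_start_event[k] <- s$start_event[j]
    pairs$replacement_confirm_time[k] <- confirm
    pairs$replacement_name[k] <- s$medication_name[j]
    pairs$replacement_therapy[k] <- s$therapy[j]
    pairs$replacement_dose[k] <- s$dose_value[j]
    pairs$replacement_unit[k] <- s$dose_unit[j]
    pairs$replacement_conc[k] <- s$concentration_value[j]
    pairs$latency_s[k] <- as.integer(round(lat))
    pairs$cross_module[k] <- s$module_id[j] != pairs$cancelled_module_id[k]
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("correction_pairs", "data.frame")
  pairs
}

#' Clinician decision time for correction pairs
#'
#' Two conventions are supported, anchored on the unambiguous log events:
#' `cancel_to_correct` (default) is replacement confirmation minus
#' cancellation -- the time from abandoning the erroneous program to
#' confirming its correction; `select_to_cancel` is cancellation minus the
#' erroneous program selection -- the time to recognise the error. Pairs
#' missing the needed endpoint yield `NA` and are excluded from summaries.
#'
#' @param pairs a `correction_pairs` data frame.
#' @param convention `"cancel_to_correct"` or `"select_to_cancel"`.
#' @return integer seconds, one per pair (`NA` where an endpoint is missing).
#' @export
decision_time <- function(pairs,
                          convention = c("cancel_to_correct",
                                         "select_to_cancel")) {
  convention <- match.arg(convention)
  stopifnot(inherits(pairs, "correction_pairs"))
  if (convention == "cancel_to_correct") {
    out <- pairs$latency_s
  } else {
    out <- as.integer(round(as.numeric(pairs$cancel_time) -
                              as.numeric(pairs$select_time)))
  }
  out[!is.na(out) & out < 0] <- NA_integer_
  out
}
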