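# Alert-mix, cancellation-cause, decision-time, dose-error-factor and
# compliance summaries.
#
# Reporting conventions used throughout: percentages are exact quotients
# rounded half-up to 2 decimals, always emitted next to their numerator and
# denominator. Concentration-limit cancellations are logged by the pump under
# the hard-limit ("reprogram limit") alert group, so they count toward the
# hard-limit alert category and are excluded from the "cancelled infusion"
# alert count and from the cancellation-percentage denominator (reported
# against all alerts instead).

alert_categories <- function() {
  c("hard_limit", "soft_limit", "cancelled", "other")
}

#' Summarize the alert mix of a log
#'
#' Counts alert sequences by category: hard-limit (including
#' concentration-limit alerts, which the pump files under "reprogram limit
#' alert"), soft-limit, cancelled infusions (user cancellations without a
#' hard/concentration alert) and all other alerts. Sequences with no alert
#' and no cancellation (plain programs, starts) are not alerts and are not
#' counted.
#'
#' @param log a `pump_log`, or a `pump_sequences` already grouped.
#' @return an `alert_mix` data frame: `category`, `n`, `pct`, with the total
#'   in `attr(, "total")`.
#' @export
summarize_alerts <- function(log) {
  s <- if (inherits(log, "pump_sequences")) log else group_sequences(log)
  hard <- s$has_hard_alert | s$has_conc_alert
  cancelled <- !hard & s$has_cancel
  soft <- !hard & !cancelled & s$has_soft_alert
  other <- !hard & !cancelled & !soft & s$has_other_alert
  alert_mix_from_counts(sum(hard), sum(soft), sum(cancelled), sum(other))
}

#' Alert mix from raw counts
#'
#' The same table [summarize_alerts()] builds, constructed directly from the
#' four category counts.
#'
#' @param hard_limit,soft_limit,cancelled,other category counts.
#' @return an `alert_mix` data frame: `category`, `n`, `pct`.
#' @export
#' @examples
#' alert_mix_from_counts(40184, 141474, 44721, 64428)
alert_mix_from_counts <- function(hard_limit, soft_limit, cancelled, other) {
  n <- c(hard_limit, soft_limit, cancelled, other)
  total <- sum(n)
  out <- data.frame(category = alert_categories(), n = n,
                    pct = share_pct(n, total), stringsAsFactors = FALSE)
  attr(out, "total") <- total
  class(out) <- c("alert_mix", "data.frame")
  out
}

#' @export
print.alert_mix <- function(x, ...) {
  cat("<alert_mix> ", attr(x, "total"), " alerts\n", sep = "")
  NextMethod()
}

num_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      median = NA_real_, min = NA_real_, max = NA_real_))
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             median = stats::median(x), min = min(x), max = max(x))
}

#' Summarize cancellation causes
#'
#' Builds the cancellation-cause table from classified correction pairs:
#' per-cause counts; percentage of cancellations (denominator excludes
#' concentration-limit breaches, which the pump reports under the hard-limit
#' alert group -- their share is reported against all alerts only);
#' percentage of all alerts when `total_alerts` is given; decision-time
#' statistics per cause and overall; and dose-error-factor statistics with a
#' count of extreme factors above `extreme_threshold`.
#'
#' @param pairs a classified `correction_pairs` data frame (see
#'   [classify_causes()]).
#' @param total_alerts optional total alert count (e.g.
#'   `attr(summarize_alerts(log), "total")`) for the percentage-of-alerts
#'   column.
#' @param extreme_threshold dose-error factor above which a correction counts
#'   as an extreme near-miss (default 100).
#' @param convention decision-time convention, see [decision_time()].
#' @return a `cancellation_summary` list: `causes` (data frame),
#'   `decision_times` (per-cause stats data frame), `dose_factors` (stats +
#'   `n_extreme`), `total_cancellations`.
#' @export
summarize_cancellations <- function(pairs, total_alerts = NULL,
                                    extreme_threshold = 100,
                                    convention = "cancel_to_correct") {
  if (is.null(pairs$cause))
    stopf("pairs must be classified first (see classify_causes())")
  counts <- table(factor(pairs$cause, levels = cause_labels()))
  out <- cause_summary_from_counts(as.vector(counts), total_alerts)

  dt <- decision_time(pairs, convention)
  by_cause <- lapply(cause_labels(), function(cl) num_stats(dt[pairs$cause == cl]))
  dts <- cbind(data.frame(cause = c(cause_labels(), "ALL"),
                          stringsAsFactors = FALSE),
               rbind(do.call(rbind, by_cause), num_stats(dt)))
  rownames(dts) <- NULL
  out$decision_times <- dts

  f <- pairs$dose_error_factor
  df_stats <- num_stats(f)
  df_stats$n_extreme <- sum(!is.na(f) & f > extreme_threshold)
  df_stats$extreme_threshold <- extreme_threshold
  out$dose_factors <- df_stats
  out
}

#' Cancellation-cause table from raw counts
#'
#' The count-to-percentage computation of [summarize_cancellations()] applied
#' to externally supplied per-cause counts (ordered as [cause_labels()], or a
#' named vector).
#'
#' @param counts per-cause counts, named by cause label or ordered as
#'   [cause_labels()].
#' @param total_alerts optional total alert count for the
#'   percentage-of-alerts column.
#' @return a `cancellation_summary` list with the `causes` table:
#'   `cause`, `n`, `pct_of_cancellations` (NA for `CONC_LIMIT_BREACH`),
#'   `pct_of_alerts`.
#' @export
#' @examples
#' cause_summary_from_counts(
#'   c(INCORRECT_MEDICATION = 10017, WRONG_DOSE = 8533,
#'     INDETERMINATE = 26144, WRONG_CHANNEL = 17,
#'     DOSE_CANCELLED_CALC = 10, CONC_LIMIT_BREACH = 603),
#'   total_alerts = 290807)
cause_summary_from_counts <- function(counts, total_alerts = NULL) {
  if (!is.null(names(counts))) {
    bad <- setdiff(names(counts), cause_labels())
    if (length(bad)) stopf("unknown cause label(s): %s",
                           paste(bad, collapse = ", "))
    v <- stats::setNames(rep(0, length(cause_labels())), cause_labels())
    v[names(counts)] <- counts
    counts <- v
  }
  stopifnot(length(counts) == length(cause_labels()))
  counts <- as.vector(counts)
  conc <- cause_labels() == "CONC_LIMIT_BREACH"
  denom <- sum(counts[!conc])
  causes <- data.frame(
    cause = cause_labels(), n = counts,
    pct_of_cancellations = ifelse(conc, NA_real_, share_pct(counts, denom)),
    pct_of_alerts = if (is.null(total_alerts)) NA_real_
                    else share_pct(counts, total_alerts),
    stringsAsFactors = FALSE
  )
  structure(list(causes = causes, decision_times = NULL, dose_factors = NULL,
                 total_cancellations = sum(counts),
                 cancellation_denominator = denom,
                 total_alerts = total_alerts),
            class = "cancellation_summary")
}

#' @export
print.cancellation_summary <- function(x, ...) {
  cat("<cancellation_summary> ", x$total_cancellations, " cancellations (",
      x$cancellation_denominator, " outside concentration-limit group)\n",
      sep = "")
  print(x$causes)
  if (!is.null(x$dose_factors) && x$dose_factors$n > 0)
    cat("dose-error factors: n=", x$dose_factors$n,
        " median=", round_half_up(x$dose_factors$median, 2),
        " max=", round_half_up(x$dose_factors$max, 2),
        " >", x$dose_factors$extreme_threshold, "x: ",
        x$dose_factors$n_extreme, "\n", sep = "")
  invisible(x)
}

#' Medication-library compliance
#'
#' Fraction of infusions started through the DERS library rather than the
#' basic mL/h or drug-calculator modes: `100 * library_starts / total_starts`
#' where total counts library, basic and calculator starts.
#'
#' @param log a `pump_log`.
#' @return a `compliance_stats` data frame: `library_starts`, `total_starts`,
#'   `compliance_pct`.
#' @export
compute_compliance <- function(log) {
  stopifnot(inherits(log, "pump_log"))
  ev <- log$records$event_type
  library_starts <- sum(ev == "INFUSION_START")
  total <- library_starts + sum(ev == "BASIC_INFUSION_START") +
    sum(ev == "CALC_START")
  if (total == 0)
    stopf("no infusion starts in log: compliance undefined")
  out <- data.frame(library_starts = library_starts, total_starts = total,
                    compliance_pct = share_pct(library_starts, total))
  class(out) <- c("compliance_stats", "data.frame")
  out
}
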