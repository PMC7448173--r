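# Rendering a report bundle as markdown, CSV files, or JSON.
#
# Every emitted percentage sits next to its numerator and denominator; the
# tables always show the exact round-half-up quotient, never a hand-adjusted
# value, so independently printed variants of the same ratio can be checked
# against the counts.

report_sections <- function() {
  c("alert_mix", "causes", "positions", "compliance")
}

check_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "pump_report") || is.list(bundle))
  missing_sections <- report_sections()[vapply(report_sections(), function(s)
    is.null(bundle[[s]]), logical(1))]
  if (length(missing_sections))
    stopf("incomplete report bundle; missing section(s): %s",
          paste(missing_sections, collapse = ", "))
  invisible(bundle)
}

alert_row_labels <- c(
  hard_limit = "Reprogram limit alert (hard limit)",
  soft_limit = "Override limit alert (soft limit)",
  cancelled = "Cancelled infusion",
  other = "All other alerts")

cause_row_labels <- c(
  INCORRECT_MEDICATION = "Incorrect medication selected",
  WRONG_DOSE = "Wrong dose selected",
  INDETERMINATE = "Indeterminate cause",
  WRONG_CHANNEL = "Wrong channel selected",
  DOSE_CANCELLED_CALC = "Dose cancelled (calculator used)",
  CONC_LIMIT_BREACH = "Concentration limit breached")

position_row_labels <- c(
  BEGINNING = "Name beginning (1)",
  MIDDLE = "Name middle (2)",
  END = "Name end (3)")

md_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "—",
                              format(v, big.mark = ",", trim = TRUE))
    else ifelse(is.na(v), "—", as.character(v))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a report bundle
#'
#' Deterministic rendering of a [run_pipeline()] bundle. `markdown` returns a
#' single document whose tables mirror the standard report row labels;
#' `csv` writes `alert_mix.csv`, `cancellation_causes.csv`,
#' `correction_pairs.csv`, `positions.csv`, `compliance.csv` (and
#' `char_counts.csv` when present) into `path`; `json` returns (or writes) a
#' schema-stable document. An incomplete bundle raises an error listing the
#' missing sections.
#'
#' @param bundle a `pump_report` from [run_pipeline()].
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param path output file (`markdown`/`json`) or directory (`csv`);
#'   optional for `markdown`/`json`.
#' @return markdown or json: the document (invisibly if written); csv: the
#'   directory path.
#' @export
build_report <- function(bundle, format = c("markdown", "csv", "json"),
                         path = NULL) {
  format <- match.arg(format)
  check_bundle(bundle)
  am <- as.data.frame(bundle$alert_mix)
  am$category <- unname(alert_row_labels[am$category])
  cs <- bundle$causes$causes
  cs$cause <- unname(cause_row_labels[cs$cause])
  ps <- as.data.frame(bundle$positions)
  ps$position <- unname(position_row_labels[ps$position])

  if (format == "markdown") {
    names(am) <- c("Alert type", "n", "% of alerts")
    names(cs) <- c("Cause", "n", "% of cancellations", "% of alerts")
    names(ps) <- c("Word/phrase error position", "n", "% of corrections")
    doc <- paste0(
      "# Infusion near-miss report\n\n",
      "## All medication library alerts by type (N=",
      format(attr(bundle$alert_mix, "total"), big.mark = ","), ")\n\n",
      md_table(am), "\n\n",
      "## Causes of infusion cancellation\n\n", md_table(cs), "\n\n",
      "Percentages are exact quotients rounded half-up to 2 decimals;\n",
      "concentration-limit breaches are reported against all alerts\n",
      "(the pump files them under the hard-limit group).\n\n",
      "## Incidence by word/phrase error position\n\n", md_table(ps), "\n\n",
      "## Compliance\n\n",
      md_table(as.data.frame(bundle$compliance)), "\n",
      if (!is.null(bundle$causes$dose_factors) &&
          bundle$causes$dose_factors$n > 0)
        paste0("\n## Dose-error factors\n\n",
               md_table(bundle$causes$dose_factors), "\n"),
      if (!is.null(bundle$char_counts))
        paste0("\n## Library character counts\n\n",
               md_table(bundle$char_counts$histogram), "\n")
    )
    if (!is.null(path)) {
      writeLines(doc, path)
      return(invisible(doc))
    }
    return(doc)
  }

  if (format == "csv") {
    stopifnot(!is.null(path))
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    w <- function(df, name) utils::write.csv(
      df, file.path(path, name), row.names = FALSE, na = "")
    w(as.data.frame(bundle$alert_mix), "alert_mix.csv")
    causes <- bundle$causes$causes
    w(causes, "cancellation_causes.csv")
    if (!is.null(bundle$causes$decision_times))
      w(bundle$causes$decision_times, "decision_times.csv")
    if (!is.null(bundle$causes$dose_factors))
      w(bundle$causes$dose_factors, "dose_factors.csv")
    w(as.data.frame(bundle$positions), "positions.csv")
    w(as.data.frame(bundle$compliance), "compliance.csv")
    if (!is.null(bundle$pairs)) {
      pr <- bundle$pairs
      for (col in c("cancel_time", "select_time", "replacement_confirm_time"))
        if (!is.null(pr[[col]]))
          pr[[col]] <- format(pr[[col]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
      w(pr, "correction_pairs.csv")
    }
    if (!is.null(bundle$char_counts))
      w(bundle$char_counts$histogram, "char_counts.csv")
    return(invisible(path))
  }

  # json
  doc <- list(
    schema = "pumpguard-report/1",
    alert_mix = list(total = attr(bundle$alert_mix, "total"),
                     rows = as.data.frame(bundle$alert_mix)),
    causes = list(total_cancellations = bundle$causes$total_cancellations,
                  cancellation_denominator = bundle$causes$cancellation_denominator,
                  total_alerts = bundle$causes$total_alerts,
                  rows = bundle$causes$causes,
                  decision_times = bundle$causes$decision_times,
                  dose_factors = bundle$causes$dose_factors),
    positions = list(total = attr(bundle$positions, "total"),
                     rows = as.data.frame(bundle$positions)),
    compliance = as.data.frame(bundle$compliance)
  )
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read summary tables back from a rendered report
#'
#' Reconstructs the summary tables (not the full bundle) from a `csv`
#' directory or `json` file written by [build_report()], so counts survive a
#' json -> csv -> json round trip.
#'
#' @param path csv directory or json file.
#' @param format `"csv"` or `"json"`.
#' @return list with `alert_mix`, `causes`, `positions`, `compliance` data
#'   frames.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    rd <- function(name) utils::read.csv(file.path(path, name))
    return(list(alert_mix = rd("alert_mix.csv"),
                causes = rd("cancellation_causes.csv"),
                positions = rd("positions.csv"),
                compliance = rd("compliance.csv")))
  }
  doc <- jsonlite::fromJSON(path)
  list(alert_mix = doc$alert_mix$rows, causes = doc$causes$rows,
       positions = doc$positions$rows, compliance = doc$compliance)
}
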