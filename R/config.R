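# Generator configuration: every distribution and proportion driving the
# synthetic event-log simulator, with defaults set to the facility-scale
# magnitudes the analytics are designed around.

# Moments of a log-normal truncated to [a, b] (closed form).
tln_moment <- function(k, meanlog, sdlog, a, b) {
  za <- (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  p <- stats::pnorm(zb) - stats::pnorm(za)
  exp(k * meanlog + k^2 * sdlog^2 / 2) *
    (stats::pnorm(zb - k * sdlog) - stats::pnorm(za - k * sdlog)) / p
}

# Solve (meanlog, sdlog) so the *truncated* log-normal on [a, b] has the
# requested mean and SD. Plain moment matching then truncating would bias the
# mean; the acceptance of the simulator is on the realized moments.
solve_truncated_lognormal <- function(target_mean, target_sd, a, b) {
  stopifnot(a > 0, b > a, target_mean > a, target_mean < b)
  obj <- function(th) {
    m <- tln_moment(1, th[1], exp(th[2]), a, b)
    v <- tln_moment(2, th[1], exp(th[2]), a, b) - m^2
    (m - target_mean)^2 + (sqrt(max(v, 0)) - target_sd)^2
  }
  cv <- target_sd / target_mean
  s0 <- sqrt(log(1 + cv^2))
  fit <- stats::optim(c(log(target_mean) - s0^2 / 2, log(s0)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

#' Built-in LASA confusion catalog
#'
#' Wrong-name/intended-name pairs the simulator draws from when planting
#' wrong-medication cancellations, each tagged with its divergence class
#' under the default character rule so draws can follow a target position
#' mix. Pairs are publicly known confusable medication names plus
#' therapy-line variants.
#'
#' @return data frame: `wrong`, `intended`, `weight`, `class`.
#' @export
default_lasa_catalog <- function() {
  p <- function(wrong, intended, weight = 1)
    data.frame(wrong = wrong, intended = intended, weight = weight,
               stringsAsFactors = FALSE)
  cat <- rbind(
    p("Abatacept <60 kg", "Acetaminophen"),
    p("0.45% NS", "0.9% Normal saline"),
    p("Acetylcysteine", "Acyclovir"),
    p("Vadastuximab talirin", "Vandortuzumab vedoti"),
    p("Sodium bicarbonate", "Sodium phosphate"),
    p("Ceftazidime", "Ceftriaxone"),
    p("Flucloxacillin", "FLUconazole"),
    p("Calcium chloride", "Calcium gluconate"),
    p("Cefazolin", "Ceftazidime"),
    p("Insulin high non-ICU", "Insulin hyperkalemia"),
    p("Cantuzumab mertansin", "Cantuzumab ravtansin"),
    p("Heparin low dose", "Heparin high dose"),
    p("Ceftazidime-Continuo", "Ceftazidime-extended"),
    p("Amiodarone load", "Amiodarone maint"),
    p("PACLitaxel weekly", "PACLitaxel 3 weekly")
  )
  cat$class <- divergence_position(cat$wrong, cat$intended)$class
  cat
}

#' Default generator configuration
#'
#' The simulator's defaults reproduce the observed structure of a large
#' facility's 12-month DERS log: alert mix over
#' hard-limit/soft-limit/cancelled/other of (13.81, 48.65, 15.37, 22.17)%,
#' cancellation causes in proportion 10017 : 8533 : 26144 : 17 : 10 (wrong
#' medication, wrong dose, indeterminate, wrong channel, calculator exit)
#' with concentration-limit cancellations at 603 per 40,184 hard-limit
#' alerts; LASA divergence positions (69.79, 21.40, 8.81)%; clinician
#' correction latencies log-normal with mean 27.00 s, SD 22.25 s truncated
#' to 4--116 s; dose-error factors log-normal with median 1.5 plus exactly
#' 11 planted extreme outliers in (100, 500]; and library compliance 74.29%.
#'
#' @param n_infusion_starts number of completed library infusion starts to
#'   simulate (default 50,000; the facility logged ~1.05M per year).
#' @param seed integer seed; every draw in [generate_log()] flows from it.
#' @param ... replacements for any top-level config field (see Details in the
#'   vignette).
#' @return a `generator_config` list, validated.
#' @export
default_generator_config <- function(n_infusion_starts = 50000, seed = 1L,
                                     ...) {
  cause_counts <- c(INCORRECT_MEDICATION = 10017, WRONG_DOSE = 8533,
                    INDETERMINATE = 26144, WRONG_CHANNEL = 17,
                    DOSE_CANCELLED_CALC = 10, CONC_LIMIT_BREACH = 603)
  cfg <- list(
    schema = "pumpguard-generator/1",
    n_infusion_starts = n_infusion_starts,
    seed = as.integer(seed),
    compliance_rate = 0.7429,
    calc_share_of_noncompliant = 0.1,
    alerts_per_library_start = 290807 / 1050531,
    alert_mix = c(hard_limit = 0.1381, soft_limit = 0.4865,
                  cancelled = 0.1537, other = 0.2217),
    cause_mix = cause_counts / sum(cause_counts),
    conc_share_of_hard = 603 / 40184,
    position_targets = c(BEGINNING = 0.6979, MIDDLE = 0.2140, END = 0.0881),
    indeterminate_identical_share = 0.5,
    decision_time_dist = list(mean_s = 27.00, sd_s = 22.25,
                              min_s = 4, max_s = 116),
    dose_factor_dist = list(median = 1.5, sdlog = 0.8,
                            extreme_outlier_count = 11,
                            extreme_factor_range = c(100, 500)),
    n_modules = NULL,       # NULL: scaled as ceiling(n_infusion_starts / 400)
    module_mix = c(LARGE_VOLUME = 3662, SYRINGE = 846, PCA = 62) / 4570,
    study_start = "2019-01-01 00:00:00",
    study_days = 365,
    guard_gap_s = 150       # min spacing between programs on one device
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  chk_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9)
      stopf("%s must sum to 1 (got %.12f)", what, sum(p))
    if (any(p < 0)) stopf("%s must be nonnegative", what)
  }
  stopifnot(is_scalar_number(cfg$n_infusion_starts),
            cfg$n_infusion_starts >= 0,
            is_scalar_number(cfg$compliance_rate),
            cfg$compliance_rate > 0, cfg$compliance_rate <= 1,
            is_scalar_number(cfg$alerts_per_library_start),
            cfg$alerts_per_library_start >= 0)
  chk_probs(cfg$alert_mix, "alert_mix")
  chk_probs(cfg$cause_mix, "cause_mix")
  chk_probs(cfg$position_targets, "position_targets")
  chk_probs(cfg$module_mix, "module_mix")
  d <- cfg$decision_time_dist
  if (!(d$min_s > 0 && d$max_s > d$min_s))
    stopf("decision_time_dist truncation bounds must be positive and ordered")
  if (!(d$mean_s > d$min_s && d$mean_s < d$max_s))
    stopf("decision_time_dist mean must lie inside the truncation bounds")
  f <- cfg$dose_factor_dist
  stopifnot(f$median > 0, f$sdlog > 0, f$extreme_outlier_count >= 0,
            length(f$extreme_factor_range) == 2,
            f$extreme_factor_range[1] < f$extreme_factor_range[2])
  if (is.null(cfg$lasa_catalog)) cfg$lasa_catalog <- default_lasa_catalog()
  if (cfg$cause_mix[["INCORRECT_MEDICATION"]] > 0 &&
      !nrow(cfg$lasa_catalog))
    stopf("empty lasa_catalog with nonzero INCORRECT_MEDICATION probability")
  missing_cls <- setdiff(names(cfg$position_targets)[cfg$position_targets > 0],
                         unique(cfg$lasa_catalog$class))
  if (cfg$cause_mix[["INCORRECT_MEDICATION"]] > 0 && length(missing_cls))
    stopf("lasa_catalog has no pair of class %s but position_targets demands it",
          paste(missing_cls, collapse = ", "))
  # solve the truncated-latency parameters once, at validation time
  cfg$decision_time_dist[c("meanlog", "sdlog")] <-
    solve_truncated_lognormal(d$mean_s, d$sd_s, d$min_s, d$max_s)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", format(x$n_infusion_starts, big.mark = ","),
      " library starts, seed ", x$seed, "\n", sep = "")
  cat("  alert mix: ", paste(sprintf("%s %.4f", names(x$alert_mix),
                                     x$alert_mix), collapse = ", "), "\n",
      sep = "")
  cat("  compliance ", x$compliance_rate, ", alerts/start ",
      round(x$alerts_per_library_start, 4), "\n", sep = "")
  invisible(x)
}

#' Read / write a generator configuration (YAML)
#'
#' Configs are YAML documents with a versioned `schema` key so simulation
#' set-ups are reviewable and diffable. The LASA catalog travels inside the
#' file as a list of records.
#'
#' @param path YAML file path.
#' @return `read_generator_config()` returns a validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$schema, "pumpguard-generator/1"))
    stopf("unsupported or missing config schema: %s", y$schema %||% "<none>")
  for (nm in c("alert_mix", "cause_mix", "position_targets", "module_mix"))
    y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$lasa_catalog))
    y$lasa_catalog <- do.call(rbind, lapply(y$lasa_catalog, function(r)
      data.frame(wrong = r$wrong, intended = r$intended,
                 weight = r$weight %||% 1, class = r$class,
                 stringsAsFactors = FALSE)))
  y$dose_factor_dist$extreme_factor_range <-
    unlist(y$dose_factor_dist$extreme_factor_range)
  validate_generator_config(y)
}

#' @rdname read_generator_config
#' @param config a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- unclass(config)
  out$decision_time_dist$meanlog <- NULL  # derived, re-solved on read
  out$decision_time_dist$sdlog <- NULL
  out$lasa_catalog <- lapply(seq_len(nrow(config$lasa_catalog)), function(i)
    as.list(config$lasa_catalog[i, ]))
  for (nm in c("alert_mix", "cause_mix", "position_targets", "module_mix"))
    out[[nm]] <- as.list(out[[nm]])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
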