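# Synthetic pump event-log generator with ground truth.
#
# The simulator emulates the statistical structure the analytics assume --
# alert mix, cancellation-cause mix, LASA divergence positions, truncated
# log-normal correction latencies, heavy-tailed dose-error factors with
# planted extremes, and library compliance -- while remaining collision-free
# by construction: programs on one device are spaced by a guard gap larger
# than the pairing window, so on default settings every cancellation's true
# replacement is also the pairing's unique candidate and cause recovery can
# be checked exactly against the truth file.

#' Sample clinician correction latencies
#'
#' Draws from a log-normal truncated to `[min_s, max_s]` by inverse-CDF
#' sampling, with `(meanlog, sdlog)` chosen so the truncated distribution
#' itself has the configured mean and SD.
#'
#' @param n number of draws.
#' @param params list with `mean_s`, `sd_s`, `min_s`, `max_s` (see
#'   [default_generator_config()]`$decision_time_dist`); `meanlog`/`sdlog`
#'   are solved on the fly if absent.
#' @return numeric vector of latencies in seconds, all inside the bounds.
#' @export
sample_decision_time <- function(n, params) {
  if (!(params$min_s > 0 && params$max_s > params$min_s))
    stopf("infeasible truncation bounds [%s, %s]", params$min_s, params$max_s)
  if (is.null(params$meanlog))
    params[c("meanlog", "sdlog")] <-
      solve_truncated_lognormal(params$mean_s, params$sd_s,
                                params$min_s, params$max_s)
  pa <- stats::plnorm(params$min_s, params$meanlog, params$sdlog)
  pb <- stats::plnorm(params$max_s, params$meanlog, params$sdlog)
  stats::qlnorm(stats::runif(n, pa, pb), params$meanlog, params$sdlog)
}

#' Sample dose-error factors
#'
#' Log-normal bulk centred on the configured median (factors below 1 --
#' potential underdoses -- occur naturally and are kept). Draws within 1% of
#' exactly 1 are rejected and redrawn, since a factor of 1 is not a dose
#' error. Extreme outliers are *planted* by [generate_log()], not drawn here:
#' a parametric tail would only reproduce their count in expectation.
#'
#' @param n number of draws.
#' @param params list with `median` and `sdlog` (see
#'   [default_generator_config()]`$dose_factor_dist`).
#' @return positive numeric vector of factors.
#' @export
sample_dose_error_factor <- function(n, params) {
  stopifnot(params$median > 0, params$sdlog > 0)
  f <- stats::rlnorm(n, log(params$median), params$sdlog)
  bad <- abs(f - 1) < 0.01
  while (any(bad)) {
    f[bad] <- stats::rlnorm(sum(bad), log(params$median), params$sdlog)
    bad <- abs(f - 1) < 0.01
  }
  f
}

round_sig <- function(x, digits = 3) signif(x, digits)

#' Generate a synthetic pump event log with ground truth
#'
#' Simulates a facility's DERS log at the configured scale and returns both
#' the log and a ground-truth record of every planted cancellation (sequence
#' ids of the erroneous and replacement programs, true cause, latency,
#' dose-error factor, divergence position), so recovery by the analysis
#' pipeline can be verified exactly.
#'
#' Deterministic given `seed`: identical config + seed reproduce the output
#' byte for byte (within one R/RNG version; cross-implementation
#' reproducibility is by statistics, not bytes).
#'
#' @param config a `generator_config`, see [default_generator_config()].
#' @param seed overrides `config$seed`.
#' @param formulary `pump_formulary` supplying names, profiles and dose
#'   limits (default [default_formulary()]).
#' @return list with `log` (a `pump_log`), `truth` (a `ground_truth` data
#'   frame, one row per cancellation) and `config`.
#' @export
generate_log <- function(config = default_generator_config(),
                         seed = config$seed,
                         formulary = default_formulary()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, generate_log_impl(config, formulary, seed))
}

generate_log_impl <- function(cfg, form, seed) {
  n <- as.integer(cfg$n_infusion_starts)
  empty_truth <- data.frame(
    seq_id_cancelled = character(), seq_id_replacement = character(),
    cause = character(), latency_s = integer(), dose_factor = numeric(),
    position = character(), stringsAsFactors = FALSE)
  class(empty_truth) <- c("ground_truth", "data.frame")
  meta <- list(generator = "pumpguard", seed = seed,
               n_infusion_starts = n)
  if (n == 0)
    return(list(log = new_pump_log(empty_records(0), source_meta = meta),
                truth = empty_truth, config = cfg))

  # ---- episode plan ---------------------------------------------------
  n_alert <- round(n * cfg$alerts_per_library_start)
  categories <- sample(names(cfg$alert_mix), n_alert, replace = TRUE,
                       prob = cfg$alert_mix)
  n_hard_draw <- sum(categories == "hard_limit")
  is_conc <- stats::runif(n_hard_draw) < cfg$conc_share_of_hard
  n_conc <- sum(is_conc)
  n_hard <- n_hard_draw - n_conc
  n_soft <- sum(categories == "soft_limit")
  n_other <- sum(categories == "other")
  n_cancel_cat <- sum(categories == "cancelled")

  five <- setdiff(cause_labels(), "CONC_LIMIT_BREACH")
  cause5 <- cfg$cause_mix[five] / sum(cfg$cause_mix[five])
  cancel_cause <- c(sample(five, n_cancel_cat, replace = TRUE, prob = cause5),
                    rep("CONC_LIMIT_BREACH", n_conc))
  n_cancel <- length(cancel_cause)

  ind <- cancel_cause == "INDETERMINATE"
  repl_kind <- rep("start", n_cancel)
  repl_kind[cancel_cause == "DOSE_CANCELLED_CALC"] <- "calc"
  repl_kind[ind] <- ifelse(stats::runif(sum(ind)) <
                             cfg$indeterminate_identical_share,
                           "start", "none")

  n_repl_start <- sum(repl_kind == "start")
  n_plain <- max(0L, n - (n_hard + n_soft + n_other + n_repl_start))
  n_noncomp <- round(n * (1 - cfg$compliance_rate) / cfg$compliance_rate)
  n_calc <- round(n_noncomp * cfg$calc_share_of_noncompliant)
  n_basic <- n_noncomp - n_calc

  ep_type <- c(rep("plain", n_plain), rep("hard", n_hard),
               rep("soft", n_soft), rep("other", n_other),
               rep("cancel", n_cancel), rep("basic", n_basic),
               rep("calc", n_calc))
  n_ep <- length(ep_type)
  ep <- data.frame(type = ep_type, stringsAsFactors = FALSE)
  ep$cause <- NA_character_
  ep$cause[ep$type == "cancel"] <- cancel_cause
  ep$repl_kind <- NA_character_
  ep$repl_kind[ep$type == "cancel"] <- repl_kind

  # ---- names and doses ------------------------------------------------
  fidx <- sample(nrow(form), n_ep, replace = TRUE)
  ep$name <- form$core_name[fidx]
  ep$therapy <- form$therapy_name[fidx]
  ep$profile <- form$profile[fidx]
  lo <- ifelse(is.na(form$soft_min[fidx]), 1, form$soft_min[fidx])
  hi <- ifelse(is.na(form$soft_max[fidx]), 100, form$soft_max[fidx])
  ep$dose <- round_sig(stats::runif(n_ep, lo, hi))
  ep$unit <- "mg"
  ep$conc <- NA_real_
  ep$repl_name <- NA_character_
  ep$repl_therapy <- NA_character_
  ep$repl_dose <- NA_real_
  ep$repl_unit <- NA_character_
  ep$repl_conc <- NA_real_
  ep$true_factor <- NA_real_
  ep$true_position <- NA_character_
  nameless <- ep$type %in% c("basic", "calc")
  ep$name[nameless] <- ""
  ep$therapy[nameless] <- ""
  ep$dose[nameless] <- NA_real_
  ep$unit[nameless] <- ""

  cz <- which(ep$type == "cancel")
  with_repl <- cz[ep$repl_kind[cz] != "none"]
  # default replacement mirrors the cancelled program (identical reprogram)
  ep$repl_name[with_repl] <- ep$name[with_repl]
  ep$repl_therapy[with_repl] <- ep$therapy[with_repl]
  ep$repl_dose[with_repl] <- ep$dose[with_repl]
  ep$repl_unit[with_repl] <- ep$unit[with_repl]
  calc_repl <- cz[ep$repl_kind[cz] == "calc"]
  ep$repl_name[calc_repl] <- ""
  ep$repl_therapy[calc_repl] <- ""
  ep$repl_dose[calc_repl] <- NA_real_
  ep$repl_unit[calc_repl] <- ""

  # wrong medication: draw a divergence class, then a catalog pair of it
  im <- cz[ep$cause[cz] == "INCORRECT_MEDICATION"]
  if (length(im)) {
    cls <- sample(names(cfg$position_targets), length(im), replace = TRUE,
                  prob = cfg$position_targets)
    cat_split <- split(seq_len(nrow(cfg$lasa_catalog)), cfg$lasa_catalog$class)
    pick <- integer(length(im))
    for (cl in unique(cls)) {
      rows <- cat_split[[cl]]
      sel <- cls == cl
      pick[sel] <- rows[sample.int(length(rows), sum(sel), replace = TRUE,
                                   prob = cfg$lasa_catalog$weight[rows])]
    }
    ep$name[im] <- cfg$lasa_catalog$wrong[pick]
    ep$therapy[im] <- ""
    ep$repl_name[im] <- cfg$lasa_catalog$intended[pick]
    ep$repl_therapy[im] <- ""
    ep$repl_dose[im] <- ep$dose[im]
    ep$true_position[im] <- cfg$lasa_catalog$class[pick]
  }

  # wrong dose: replacement dose is truth, cancelled dose = truth * factor
  wd <- cz[ep$cause[cz] == "WRONG_DOSE"]
  if (length(wd)) {
    f <- sample_dose_error_factor(length(wd), cfg$dose_factor_dist)
    k <- min(cfg$dose_factor_dist$extreme_outlier_count, length(wd))
    if (k > 0) {
      xi <- sample.int(length(wd), k)
      rg <- cfg$dose_factor_dist$extreme_factor_range
      f[xi] <- rg[1] + stats::runif(k) * (rg[2] - rg[1])
    }
    ep$repl_dose[wd] <- round_sig(ep$dose[wd])
    ep$dose[wd] <- ep$repl_dose[wd] * f
    ep$true_factor[wd] <- f
    # some wrong-dose programs are keyed in microgram units
    mcg <- stats::runif(length(wd)) < 0.1
    ep$dose[wd][mcg] <- ep$dose[wd][mcg] * 1000
    ep$unit[wd][mcg] <- "mcg"
  }

  # wrong channel: a PCA medication first loaded on a syringe module
  wc <- cz[ep$cause[cz] == "WRONG_CHANNEL"]
  if (length(wc)) {
    ep$name[wc] <- "Morphine PCA"
    ep$therapy[wc] <- ""
    ep$repl_name[wc] <- "Morphine PCA"
    ep$repl_therapy[wc] <- ""
    ep$repl_dose[wc] <- ep$dose[wc]
  }

  # concentration-limit breach: custom concentration outside limits,
  # corrected to a standard one
  cc <- cz[ep$cause[cz] == "CONC_LIMIT_BREACH"]
  if (length(cc)) {
    ep$conc[cc] <- round_sig(stats::runif(length(cc), 8, 20))
    ep$repl_conc[cc] <- round_sig(ep$conc[cc] / 10)
  }

  # latencies (integer seconds, the pumps' clock resolution)
  ep$lat <- NA_integer_
  ep$lat[with_repl] <- as.integer(round(sample_decision_time(
    length(with_repl), cfg$decision_time_dist)))
  ep$react <- NA_integer_
  ep$react[cz] <- sample(3:30, n_cancel, replace = TRUE)

  # ---- devices, modules, timeline ------------------------------------
  n_modules <- cfg$n_modules %||% max(4L, ceiling(n / 400))
  n_dev <- max(1L, ceiling(n_modules / 2))
  n_wc_dev <- max(1L, ceiling(0.02 * n_dev))
  dev_ids <- sprintf("D%04d", seq_len(n_dev))
  m1_type <- c(rep("SYRINGE", n_wc_dev),
               sample(names(cfg$module_mix), n_dev - n_wc_dev, replace = TRUE,
                      prob = cfg$module_mix))
  m2_type <- c(rep("PCA", n_wc_dev),
               sample(names(cfg$module_mix), n_dev - n_wc_dev, replace = TRUE,
                      prob = cfg$module_mix))

  ep$dev <- sample.int(n_dev, n_ep, replace = TRUE)
  if (length(wc)) ep$dev[wc] <- sample.int(n_wc_dev, length(wc), replace = TRUE)
  ep$slot <- sample(c(1L, 2L), n_ep, replace = TRUE)
  ep$slot[wc] <- 1L  # cancelled on the syringe module
  ep$module_type <- ifelse(ep$slot == 1L, m1_type[ep$dev], m2_type[ep$dev])
  ep$repl_slot <- ep$slot
  ep$repl_slot[wc] <- 2L  # corrected on the PCA module
  ep$repl_module_type <- ifelse(ep$repl_slot == 1L, m1_type[ep$dev],
                                m2_type[ep$dev])

  # episode duration (first to last event, seconds)
  dur <- rep(2L, n_ep)                       # plain: select -> start
  aler <- ep$type %in% c("hard", "soft", "other")
  dur[aler] <- 2L + 10L + 2L
  dur[cz] <- 2L + ep$react[cz] + ifelse(is.na(ep$lat[cz]), 0L, ep$lat[cz])
  dur[nameless] <- 0L

  study_s <- cfg$study_days * 86400
  ord <- order(ep$dev, stats::runif(n_ep))
  gap_mean <- max(60, n_dev * study_s / n_ep)
  gaps <- cfg$guard_gap_s + stats::rexp(n_ep, rate = 1 / gap_mean)
  prev_dur <- c(0L, dur[ord][-n_ep])
  prev_dur[!duplicated(ep$dev[ord])] <- 0L
  t0 <- stats::ave(gaps + prev_dur, ep$dev[ord], FUN = cumsum)
  ep$t0 <- NA_real_
  ep$t0[ord] <- floor(t0)

  # ---- sequence ids and truth ----------------------------------------
  ep$sid <- sprintf("S%08d", seq_len(n_ep))
  ep$sid2 <- NA_character_
  ep$sid2[with_repl] <- sprintf("R%08d", seq_along(with_repl))
  ep$sid[nameless] <- ""  # basic/calc starts carry no sequence id

  truth <- data.frame(
    seq_id_cancelled = ep$sid[cz],
    seq_id_replacement = ep$sid2[cz],
    cause = ep$cause[cz],
    latency_s = ep$lat[cz],
    dose_factor = ep$true_factor[cz],
    position = ep$true_position[cz],
    stringsAsFactors = FALSE)
  o <- order(truth$seq_id_cancelled)
  truth <- truth[o, , drop = FALSE]
  rownames(truth) <- NULL
  class(truth) <- c("ground_truth", "data.frame")

  # ---- event rows -----------------------------------------------------
  origin <- as.POSIXct(cfg$study_start, tz = "UTC")
  mod_id <- function(dev, slot) paste0(dev_ids[dev], "-M", slot)
  blocks <- list()
  add <- function(idx, offset, type, slot, name, therapy, dose, unit, conc,
                  sid) {
    if (!length(idx)) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      timestamp = origin + ep$t0[idx] + offset,
      device_id = dev_ids[ep$dev[idx]],
      module_id = mod_id(ep$dev[idx], slot),
      module_type = ifelse(slot == ep$slot[idx], ep$module_type[idx],
                           ep$repl_module_type[idx]),
      profile = ep$profile[idx],
      sequence_id = sid,
      event_type = type,
      medication_name = name, therapy = therapy,
      dose_value = dose, dose_unit = unit,
      concentration_value = conc,
      stringsAsFactors = FALSE)
  }
  own <- function(i, off, type) add(i, off, type, ep$slot[i], ep$name[i],
                                    ep$therapy[i], ep$dose[i], ep$unit[i],
                                    ep$conc[i], ep$sid[i])

  pl <- which(ep$type == "plain")
  own(pl, 0, "PROGRAM_SELECT"); own(pl, 2, "INFUSION_START")
  hd <- which(ep$type == "hard")
  own(hd, 0, "PROGRAM_SELECT"); own(hd, 2, "HARD_LIMIT_ALERT")
  own(hd, 12, "REPROGRAM"); own(hd, 14, "INFUSION_START")
  sf <- which(ep$type == "soft")
  own(sf, 0, "PROGRAM_SELECT"); own(sf, 2, "SOFT_LIMIT_ALERT")
  own(sf, 12, "OVERRIDE"); own(sf, 14, "INFUSION_START")
  ot <- which(ep$type == "other")
  own(ot, 0, "PROGRAM_SELECT"); own(ot, 2, "OTHER_ALERT")
  own(ot, 12, "OVERRIDE"); own(ot, 14, "INFUSION_START")
  bs <- which(ep$type == "basic")
  own(bs, 0, "BASIC_INFUSION_START")
  ca <- which(ep$type == "calc")
  own(ca, 0, "CALC_START")

  own(cz, 0, "PROGRAM_SELECT")
  own(cc, 2, "CONC_LIMIT_ALERT")
  own(cz, 2 + ep$react[cz], "CANCEL")
  t_cancel <- 2 + ep$react
  rs <- with_repl[ep$repl_kind[with_repl] == "start"]
  add(rs, t_cancel[rs] + pmax(1, ep$lat[rs] - 5), "PROGRAM_SELECT",
      ep$repl_slot[rs], ep$repl_name[rs], ep$repl_therapy[rs],
      ep$repl_dose[rs], ep$repl_unit[rs], ep$repl_conc[rs], ep$sid2[rs])
  add(rs, t_cancel[rs] + ep$lat[rs], "INFUSION_START",
      ep$repl_slot[rs], ep$repl_name[rs], ep$repl_therapy[rs],
      ep$repl_dose[rs], ep$repl_unit[rs], ep$repl_conc[rs], ep$sid2[rs])
  rc <- with_repl[ep$repl_kind[with_repl] == "calc"]
  add(rc, t_cancel[rc] + ep$lat[rc], "CALC_START",
      ep$repl_slot[rc], "", "", NA_real_, "", NA_real_, ep$sid2[rc])

  records <- do.call(rbind, blocks)
  # emission order = canonical export order, so the file-order diagnostics
  # of validate_log() see a monotone clock per module
  records <- records[order(records$device_id, records$module_id,
                           records$timestamp), , drop = FALSE]
  records$file_order <- seq_len(nrow(records))
  log <- new_pump_log(records, source_meta = meta)
  list(log = log, truth = truth, config = cfg)
}

#' Write / read a ground-truth file (CSV)
#'
#' Header: `seq_id_cancelled,seq_id_replacement,cause,latency_s,dose_factor,
#' position`.
#'
#' @param truth a `ground_truth` data frame.
#' @param path file path.
#' @return the path (write) or the `ground_truth` data frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  t <- utils::read.csv(path, colClasses = c(
    seq_id_cancelled = "character", seq_id_replacement = "character",
    cause = "character", latency_s = "integer", dose_factor = "numeric",
    position = "character"), na.strings = "")
  t$seq_id_replacement[is.na(t$seq_id_replacement)] <- NA_character_
  class(t) <- c("ground_truth", "data.frame")
  t
}
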