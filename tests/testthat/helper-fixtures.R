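# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# Compact event builder: ev("10:00:00", "CANCEL", seq = "S1", ...) on a fixed
# date/device/module unless overridden.
ev <- function(time, type, seq = "S1", name = "", therapy = "",
               dose = NA_real_, unit = "", conc = NA_real_,
               dev = "D1", mod = "M1", mod_type = "LARGE_VOLUME",
               profile = "adult_general", date = "2019-06-01") {
  data.frame(timestamp = as.POSIXct(paste(date, time), tz = "UTC"),
             device_id = dev, module_id = mod, module_type = mod_type,
             profile = profile, sequence_id = seq, event_type = type,
             medication_name = name, therapy = therapy, dose_value = dose,
             dose_unit = unit, concentration_value = conc,
             stringsAsFactors = FALSE)
}

make_log <- function(...) as_pump_log(do.call(rbind, list(...)))

# A cancel-then-correct episode as two sequences on one module.
correction_log <- function(cancel_name, repl_name, cancel_dose = 10,
                           repl_dose = 10, cancel_unit = "mg",
                           repl_unit = "mg", latency = 21,
                           conc_alert = FALSE, repl_event = "INFUSION_START",
                           cancel_conc = NA_real_, repl_conc = NA_real_,
                           mod_type = "LARGE_VOLUME",
                           repl_mod = "M1", repl_mod_type = mod_type) {
  t0 <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC")
  fmt <- function(t) format(t, "%H:%M:%S")
  rows <- list(
    ev(fmt(t0 - 20), "PROGRAM_SELECT", "C1", cancel_name, dose = cancel_dose,
       unit = cancel_unit, conc = cancel_conc, mod_type = mod_type))
  if (conc_alert)
    rows <- c(rows, list(ev(fmt(t0 - 18), "CONC_LIMIT_ALERT", "C1",
                            cancel_name, dose = cancel_dose,
                            unit = cancel_unit, conc = cancel_conc,
                            mod_type = mod_type)))
  rows <- c(rows, list(
    ev(fmt(t0), "CANCEL", "C1", cancel_name, dose = cancel_dose,
       unit = cancel_unit, conc = cancel_conc, mod_type = mod_type)))
  if (!is.null(repl_name)) {
    if (repl_event == "CALC_START") {
      rows <- c(rows, list(
        ev(fmt(t0 + latency), "CALC_START", "R1", "", mod = repl_mod,
           mod_type = repl_mod_type)))
    } else {
      rows <- c(rows, list(
        ev(fmt(t0 + min(latency, max(1, latency - 5))), "PROGRAM_SELECT", "R1", repl_name,
           dose = repl_dose, unit = repl_unit, conc = repl_conc,
           mod = repl_mod, mod_type = repl_mod_type),
        ev(fmt(t0 + latency), repl_event, "R1", repl_name, dose = repl_dose,
           unit = repl_unit, conc = repl_conc, mod = repl_mod,
           mod_type = repl_mod_type)))
    }
  }
  do.call(make_log, rows)
}

classify_one <- function(log, ...) {
  pairs <- pair_cancellations(group_sequences(log), ...)
  classify_causes(pairs)
}

# Table of published example LASA pairs with their printed position labels.
lasa_examples <- function() {
  data.frame(
    cancelled = c("Sodium bicarbonate", "Abatacept <60 kg", "Acetylcysteine",
                  "Ceftazidime", "Flucloxacillin", "Calcium chloride",
                  "Cefazolin", "Ceftazidime-Continuo", "0.45% NS",
                  "Insulin high non-ICU"),
    corrected = c("Sodium phosphate", "Acetaminophen", "Acyclovir",
                  "Ceftriaxone", "FLUconazole", "Calcium gluconate",
                  "Ceftazidime", "Ceftazidime-extended", "0.9% Normal saline",
                  "Insulin hyperkalemia"),
    printed = c("END", "BEGINNING", "MIDDLE", "MIDDLE", "MIDDLE", "MIDDLE",
                "MIDDLE", "END", "BEGINNING", "MIDDLE"),
    stringsAsFactors = FALSE)
}

small_config <- function(n = 2000, seed = 42, ...)
  default_generator_config(n_infusion_starts = n, seed = seed, ...)

# Independent confusability oracle: explicit double loop + order(), no shared
# code with confusability_screen().
brute_force_screen <- function(form) {
  nm_raw <- ifelse(nzchar(form$therapy_name),
                   paste(form$core_name, form$therapy_name), form$core_name)
  nm <- tolower(gsub("[[:space:]]+", " ", trimws(nm_raw)))
  idx <- t(utils::combn(length(nm), 2))
  ed <- numeric(nrow(idx)); cp <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    a <- nm[idx[r, 1]]; b <- nm[idx[r, 2]]
    ed[r] <- utils::adist(a, b)
    k <- 0
    while (k < min(nchar(a), nchar(b)) &&
           substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1
    cp[r] <- k
  }
  nd <- ed / pmax(nchar(nm)[idx[, 1]], nchar(nm)[idx[, 2]])
  o <- order(nd, -cp, nm_raw[idx[, 1]], nm_raw[idx[, 2]])
  data.frame(name_a = nm_raw[idx[o, 1]], name_b = nm_raw[idx[o, 2]],
             edit_distance = ed[o], norm_distance = nd[o],
             common_prefix_len = cp[o], stringsAsFactors = FALSE)
}
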