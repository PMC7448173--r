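# Count-to-percentage summaries: worked examples and conservation.

test_that("cause percentages reproduce the worked examples from the counts", {
  s <- cause_summary_from_counts(
    c(INCORRECT_MEDICATION = 10017, WRONG_DOSE = 8533, INDETERMINATE = 26144,
      WRONG_CHANNEL = 17, DOSE_CANCELLED_CALC = 10, CONC_LIMIT_BREACH = 603),
    total_alerts = 290807)
  cs <- s$causes
  get <- function(cl, col) cs[cs$cause == cl, col]
  expect_equal(get("INCORRECT_MEDICATION", "pct_of_cancellations"), 22.40)
  expect_equal(get("WRONG_DOSE", "pct_of_cancellations"), 19.08)
  expect_equal(get("INDETERMINATE", "pct_of_cancellations"), 58.46)
  expect_equal(get("WRONG_CHANNEL", "pct_of_cancellations"), 0.04)
  expect_equal(get("DOSE_CANCELLED_CALC", "pct_of_cancellations"), 0.02)
  expect_equal(get("WRONG_DOSE", "pct_of_alerts"), 2.93)
  expect_equal(get("CONC_LIMIT_BREACH", "pct_of_alerts"), 0.21)
  # concentration-limit breaches are not a share of the cancellation group
  expect_true(is.na(get("CONC_LIMIT_BREACH", "pct_of_cancellations")))
  expect_equal(s$cancellation_denominator, 44721)
})

test_that("alert-mix percentages are exact round-half-up quotients", {
  am <- alert_mix_from_counts(40184, 141474, 44721, 64428)
  expect_equal(attr(am, "total"), 290807)
  expect_equal(am$pct[am$category == "soft_limit"], 48.65)
  # exact division gives 13.82 / 15.38 (printed variants 13.81 / 15.37 are
  # truncations; the tables always carry the exact quotient)
  expect_equal(am$pct[am$category == "hard_limit"], 13.82)
  expect_equal(am$pct[am$category == "cancelled"], 15.38)
})

test_that("a single classified pair summarizes to 100% of its cause", {
  p <- classify_one(correction_log("Sodium bicarbonate", "Sodium phosphate"))
  s <- summarize_cancellations(p)
  cs <- s$causes
  expect_equal(cs$pct_of_cancellations[cs$cause == "INCORRECT_MEDICATION"], 100)
  expect_equal(s$total_cancellations, 1)
})

test_that("cause counts sum to the cancellation total on generated logs", {
  g <- generate_log(small_config(n = 1500, seed = 12))
  s <- group_sequences(g$log)
  p <- classify_causes(pair_cancellations(s))
  am <- summarize_alerts(s)
  sm <- summarize_cancellations(p, total_alerts = attr(am, "total"))
  expect_equal(sum(sm$causes$n), nrow(p))
  expect_equal(sum(am$n), attr(am, "total"))
  # and every percentage is recomputable from its neighbours
  expect_equal(am$pct, share_pct(am$n, attr(am, "total")))
})

test_that("empty input yields an all-zero summary, not an error", {
  g <- generate_log(small_config(n = 0, seed = 1))
  p <- classify_causes(pair_cancellations(group_sequences(g$log)))
  s <- summarize_cancellations(p)
  expect_equal(sum(s$causes$n), 0)
  expect_equal(s$dose_factors$n, 0)
})

test_that("decision-time statistics match a direct computation per cause", {
  g <- generate_log(small_config(n = 1500, seed = 13))
  p <- classify_causes(pair_cancellations(group_sequences(g$log)))
  s <- summarize_cancellations(p)
  lat <- p$latency_s[p$cause == "INCORRECT_MEDICATION"]
  row <- s$decision_times[s$decision_times$cause == "INCORRECT_MEDICATION", ]
  expect_equal(row$n, sum(!is.na(lat)))
  expect_equal(row$mean, mean(lat, na.rm = TRUE))
  expect_equal(row$median, median(lat, na.rm = TRUE))
})

test_that("compliance follows the start counts", {
  g <- generate_log(small_config(n = 1000, seed = 14))
  comp <- compute_compliance(g$log)
  expect_lte(comp$library_starts, comp$total_starts)
  expect_equal(comp$compliance_pct,
               share_pct(comp$library_starts, comp$total_starts))

  lib3 <- make_log(ev("10:00:00", "INFUSION_START", "S1", "Drug"),
                   ev("10:01:00", "INFUSION_START", "S2", "Drug"),
                   ev("10:02:00", "INFUSION_START", "S3", "Drug"),
                   ev("10:03:00", "BASIC_INFUSION_START", ""))
  expect_equal(compute_compliance(lib3)$compliance_pct, 75.00)

  all_lib <- make_log(ev("10:00:00", "INFUSION_START", "S1", "Drug"))
  expect_equal(compute_compliance(all_lib)$compliance_pct, 100.00)

  none <- make_log(ev("10:00:00", "PROGRAM_SELECT", "S1", "Drug"))
  expect_error(compute_compliance(none), "undefined")
})

test_that("the facility-scale compliance quotient matches its printed value", {
  lib <- 1050531; tot <- 1414191
  expect_lt(abs(share_pct(lib, tot) - 74.29), 0.02)
})
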