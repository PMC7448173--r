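# The cause-classification ladder, exercised through real mini-logs.

test_that("a concentration-limit alert dominates the ladder", {
  log <- correction_log("Norepinephrine", "Norepinephrine",
                        conc_alert = TRUE, cancel_conc = 16, repl_conc = 0.064)
  p <- classify_one(log)
  expect_equal(p$cause, "CONC_LIMIT_BREACH")
})

test_that("a calculator replacement is classified as a calculator exit", {
  log <- correction_log("Heparin low dose", "ignored",
                        repl_event = "CALC_START")
  p <- classify_one(log)
  expect_equal(p$cause, "DOSE_CANCELLED_CALC")
})

test_that("a syringe-to-PCA swap with the same medication is a wrong channel", {
  log <- correction_log("Morphine PCA", "Morphine PCA",
                        mod_type = "SYRINGE", repl_mod = "M2",
                        repl_mod_type = "PCA")
  p <- classify_one(log)
  expect_equal(p$cause, "WRONG_CHANNEL")
  expect_true(p$cross_module)
})

test_that("a changed medication name is an incorrect-medication selection", {
  log <- correction_log("Sodium bicarbonate", "Sodium phosphate")
  p <- classify_one(log)
  expect_equal(p$cause, "INCORRECT_MEDICATION")
  expect_false(is.na(p$lasa_position))
})

test_that("TALLman and case differences alone do not make a name mismatch", {
  log <- correction_log("FLUconazole", "fluconazole", cancel_dose = 100,
                        repl_dose = 100)
  p <- classify_one(log)
  expect_equal(p$cause, "INDETERMINATE")
})

test_that("a same-name dose change is a wrong dose with the forced factor", {
  log <- correction_log("Drug X", "Drug X", cancel_dose = 100,
                        repl_dose = 0.2)
  p <- classify_one(log)
  expect_equal(p$cause, "WRONG_DOSE")
  expect_equal(p$dose_error_factor, 500)
})

test_that("a dose expressed in different units of one dimension is not a dose change", {
  log <- correction_log("Drug X", "Drug X", cancel_dose = 1000,
                        cancel_unit = "mcg", repl_dose = 1, repl_unit = "mg")
  p <- classify_one(log)
  expect_equal(p$cause, "INDETERMINATE")
})

test_that("an identical reprogram and an unpaired cancel are indeterminate", {
  ident <- classify_one(correction_log("Heparin low dose", "Heparin low dose",
                                       cancel_dose = 500, repl_dose = 500,
                                       cancel_unit = "units",
                                       repl_unit = "units"))
  expect_equal(ident$cause, "INDETERMINATE")
  unpaired <- classify_one(correction_log("Heparin low dose", NULL))
  expect_equal(unpaired$cause, "INDETERMINATE")
})

test_that("a nameless basic-mode replacement is indeterminate and flagged", {
  t0 <- as.POSIXct("2019-06-01 10:00:00", tz = "UTC")
  log <- make_log(
    ev("09:59:40", "PROGRAM_SELECT", "C1", "Heparin low dose", dose = 500,
       unit = "units"),
    ev("10:00:00", "CANCEL", "C1", "Heparin low dose", dose = 500,
       unit = "units"),
    ev("10:00:30", "BASIC_INFUSION_START", "R1"))
  p <- classify_one(log)
  expect_equal(p$cause, "INDETERMINATE")
  expect_match(p$flag, "without medication name")
})

test_that("classify_cause() on a single pair agrees with the vectorized path", {
  log <- correction_log("Cefazolin", "Ceftazidime")
  pairs <- pair_cancellations(group_sequences(log))
  expect_equal(classify_cause(pairs[1, ]), "INCORRECT_MEDICATION")
})
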