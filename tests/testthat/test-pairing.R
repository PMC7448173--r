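# Pairing cancellations with replacement programs and decision times.

test_that("a cancel followed 21 s later by a confirmed program pairs with latency 21", {
  log <- correction_log("Sodium bicarbonate", "Sodium phosphate", latency = 21)
  p <- pair_cancellations(group_sequences(log))
  expect_equal(nrow(p), 1)
  expect_equal(p$replacement_seq_id, "R1")
  expect_equal(p$latency_s, 21L)
})

test_that("a cancel with no later program on the module stays unpaired", {
  log <- correction_log("Heparin low dose", NULL)
  p <- pair_cancellations(group_sequences(log))
  expect_equal(nrow(p), 1)
  expect_true(is.na(p$replacement_seq_id))
  expect_true(is.na(p$latency_s))
})

test_that("a program outside the window does not pair", {
  log <- correction_log("Heparin low dose", "Heparin high dose", latency = 300)
  p <- pair_cancellations(group_sequences(log), window_s = 120)
  expect_true(is.na(p$replacement_seq_id))
  # but it does pair once the window covers it
  p2 <- pair_cancellations(group_sequences(log), window_s = 400)
  expect_equal(p2$latency_s, 300L)
})

test_that("pairing is deterministic and insensitive to record order", {
  g <- generate_log(small_config(n = 800, seed = 8))
  s <- group_sequences(g$log)
  p1 <- pair_cancellations(s)
  shuffled <- g$log$records[sample(nrow(g$log$records)), ]
  p2 <- pair_cancellations(group_sequences(as_pump_log(shuffled)))
  o1 <- p1[order(p1$cancelled_seq_id), ]
  o2 <- p2[order(p2$cancelled_seq_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
})

test_that("enlarging the window never decreases the number of paired cancellations", {
  g <- generate_log(small_config(n = 800, seed = 9))
  s <- group_sequences(g$log)
  paired <- vapply(c(15, 30, 60, 120, 300, 1000), function(w)
    sum(!is.na(pair_cancellations(s, window_s = w)$latency_s)), numeric(1))
  expect_true(all(diff(paired) >= 0))
})

test_that("decision-time conventions anchor on the documented endpoints", {
  log <- correction_log("Ceftazidime", "Ceftriaxone", latency = 27)
  p <- pair_cancellations(group_sequences(log))
  expect_equal(decision_time(p, "cancel_to_correct"), 27L)
  # the erroneous program was selected 20 s before its cancellation
  expect_equal(decision_time(p, "select_to_cancel"), 20L)
})

test_that("a zero-latency correction is a valid pair", {
  log <- correction_log("Ceftazidime", "Ceftriaxone", latency = 0)
  p <- pair_cancellations(group_sequences(log))
  expect_equal(p$latency_s, 0L)
})

test_that("planted latencies are recovered to the second", {
  g <- generate_log(small_config(n = 1200, seed = 10))
  p <- pair_cancellations(group_sequences(g$log))
  m <- match(g$truth$seq_id_cancelled, p$cancelled_seq_id)
  expect_equal(p$latency_s[m], g$truth$latency_s)
})
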