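# Synthetic log generator: configuration, determinism, distributions,
# planted-truth consistency.

test_that("the default configuration carries the documented study mix", {
  cfg <- default_generator_config()
  expect_equal(sum(cfg$alert_mix), 1)
  expect_equal(cfg$alert_mix[["cancelled"]], 0.1537)
  expect_equal(cfg$position_targets[["BEGINNING"]], 0.6979)
  expect_equal(sum(cfg$cause_mix), 1)
  expect_equal(cfg$compliance_rate, 0.7429)
  expect_equal(cfg$decision_time_dist$mean_s, 27.00)
  expect_equal(cfg$decision_time_dist$sd_s, 22.25)
  expect_equal(cfg$dose_factor_dist$extreme_outlier_count, 11)
})

test_that("probability vectors that do not sum to one are rejected", {
  expect_error(default_generator_config(
    alert_mix = c(hard_limit = 0.5, soft_limit = 0.5, cancelled = 0.5,
                  other = 0.5)), "sum to 1")
  expect_error(default_generator_config(
    decision_time_dist = list(mean_s = 27, sd_s = 22, min_s = 116, max_s = 4)),
    "bounds")
})

test_that("an empty catalog with wrong-medication probability is a config error", {
  expect_error(default_generator_config(
    lasa_catalog = default_lasa_catalog()[0, ]), "lasa_catalog")
})

test_that("n = 0 produces an empty log and empty truth", {
  g <- generate_log(small_config(n = 0))
  expect_equal(nrow(g$log$records), 0)
  expect_equal(nrow(g$truth), 0)
})

test_that("the same seed reproduces the log and truth exactly", {
  a <- generate_log(small_config(n = 600, seed = 77))
  b <- generate_log(small_config(n = 600, seed = 77))
  expect_identical(a$log$records, b$log$records)
  expect_identical(a$truth, b$truth)
  c <- generate_log(small_config(n = 600, seed = 78))
  expect_false(identical(a$log$records, c$log$records))
})

test_that("latency draws respect truncation and the configured moments", {
  params <- default_generator_config()$decision_time_dist
  set.seed(101)
  x <- sample_decision_time(10000, params)
  expect_true(all(x >= params$min_s & x <= params$max_s))
  se <- params$sd_s / sqrt(length(x))
  expect_lt(abs(mean(x) - params$mean_s), 3 * se)
  # draws follow the truncated log-normal itself (KS below the 1% critical
  # value <=> p-value above 0.01)
  cdf <- function(q) {
    pa <- plnorm(params$min_s, params$meanlog, params$sdlog)
    pb <- plnorm(params$max_s, params$meanlog, params$sdlog)
    (plnorm(q, params$meanlog, params$sdlog) - pa) / (pb - pa)
  }
  expect_gt(stats::ks.test(x, cdf)$p.value, 0.01)
})

test_that("infeasible truncation bounds are a configuration error", {
  expect_error(sample_decision_time(10, list(mean_s = 27, sd_s = 22,
                                             min_s = 116, max_s = 4)),
               "infeasible")
})

test_that("dose-factor draws are positive and never a non-error factor of one", {
  params <- default_generator_config()$dose_factor_dist
  set.seed(102)
  f <- sample_dose_error_factor(10000, params)
  expect_true(all(f > 0))
  expect_true(all(abs(f - 1) >= 0.01))
  expect_lt(abs(median(f) - params$median), 0.05)
})

test_that("exactly the configured number of extreme factors is planted", {
  g <- generate_log(small_config(n = 4000, seed = 15))
  planted <- g$truth$dose_factor[!is.na(g$truth$dose_factor)]
  expect_equal(sum(planted > 100), 11)
  expect_true(all(planted[planted > 100] <= 500))
})

test_that("the truth file is re-derivable from the emitted events", {
  g <- generate_log(small_config(n = 1200, seed = 16))
  r <- g$log$records
  tr <- g$truth
  by_seq <- split(seq_len(nrow(r)), r$sequence_id)
  for (i in which(!is.na(tr$seq_id_replacement))) {
    cz <- r[by_seq[[tr$seq_id_cancelled[i]]], ]
    rp <- r[by_seq[[tr$seq_id_replacement[i]]], ]
    t_cancel <- cz$timestamp[cz$event_type == "CANCEL"]
    t_confirm <- rp$timestamp[rp$event_type %in% c("INFUSION_START",
                                                   "CALC_START")]
    expect_equal(as.numeric(t_confirm) - as.numeric(t_cancel),
                 as.numeric(tr$latency_s[i]))
    if (!is.na(tr$dose_factor[i])) {
      dc <- cz$dose_value[1]; uc <- cz$dose_unit[1]
      dr <- rp$dose_value[1]; ur <- rp$dose_unit[1]
      expect_equal(dose_error_factor(dc, uc, dr, ur), tr$dose_factor[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("a truth file survives a write/read round trip", {
  g <- generate_log(small_config(n = 500, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(g$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$seq_id_cancelled, g$truth$seq_id_cancelled)
  expect_equal(back$cause, g$truth$cause)
  expect_equal(back$latency_s, g$truth$latency_s)
  expect_equal(back$dose_factor, g$truth$dose_factor, tolerance = 1e-12)
})

test_that("a generator config survives a YAML round trip", {
  cfg <- small_config(n = 123, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$n_infusion_starts, 123)
  expect_equal(back$alert_mix, cfg$alert_mix)
  expect_equal(back$cause_mix, cfg$cause_mix)
  expect_equal(back$decision_time_dist$meanlog, cfg$decision_time_dist$meanlog)
  expect_equal(back$lasa_catalog$wrong, cfg$lasa_catalog$wrong)
})
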