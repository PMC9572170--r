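test_that("cohort configuration validates its study conditions", {
  expect_error(cohort_config(-1, 2, 3), "n_controls")
  expect_error(cohort_config(2, 2, 0), "days_per_subject")
  expect_error(cohort_config(2, 2, 3, artifact_rates = c(gap_rate = -0.1)),
               "non-negative")
  expect_error(cohort_config(2, 2, 3, relapse_spec = data.frame(
    patient = 1, start_day = 2, duration = 5, severity = "moderate")),
    "within")
  expect_error(cohort_config(2, 2, 3, relapse_spec = data.frame(
    patient = 1, start_day = 0, duration = 1, severity = "extreme")),
    "severity")
})

test_that("cohort manifest arithmetic and determinism hold", {
  co <- tiny_cohort(2, 2, 3)
  expect_equal(nrow(co$subjects), 4L)
  expect_equal(co$manifest$n_subject_days, 12L)
  expect_false(anyDuplicated(co$subjects$subject_id) > 0)

  co2 <- tiny_cohort(2, 2, 3)
  s1 <- simulate_subject(co$profiles[[1]], co$config)
  s2 <- simulate_subject(co2$profiles[[1]], co2$config)
  expect_identical(s1$streams, s2$streams)

  co3 <- tiny_cohort(2, 2, 3, seed = 99)
  s3 <- simulate_subject(co3$profiles[[1]], co3$config)
  expect_false(identical(s1$streams$rr$rr_ms, s3$streams$rr$rr_ms))
})

test_that("RR stream carries repeats, matches beat count, and injects the
           configured artifact rate", {
  cfg <- cohort_config(1, 0, days_per_subject = 1, seed = 5,
                       artifact_rates = c(rr_outlier_rate = 0, gap_rate = 0,
                                          repeat_rate = 0))
  co <- simulate_cohort(cfg)
  s <- simulate_subject(co$profiles[[1]], cfg)
  rr <- s$streams$rr
  # 5 Hz readout repeats each beat value until the next beat
  expect_gt(nrow(rr), 4e5)
  expect_gt(mean(rr$rr_ms[-1] == rr$rr_ms[-nrow(rr)]), 0.5)
  ev <- dedupe_rr(rr)
  B <- sum(attr(rr, "beat_t") <= max(rr$t_sec))
  expect_equal(nrow(ev), B)

  cfg2 <- cohort_config(1, 0, days_per_subject = 1, seed = 5,
                        artifact_rates = c(rr_outlier_rate = 0.01,
                                           gap_rate = 0, repeat_rate = 0))
  co2 <- simulate_cohort(cfg2)
  s2 <- simulate_subject(co2$profiles[[1]], cfg2)
  frac <- mean(s2$streams$rr$rr_ms < 300 | s2$streams$rr$rr_ms > 2000)
  n <- nrow(s2$streams$rr)
  ci <- 0.01 + c(-4, 4) * sqrt(0.01 * 0.99 / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("zero anomaly magnitude leaves relapse windows indistinguishable", {
  cfg <- cohort_config(0, 1, days_per_subject = 4, seed = 21,
                       prodrome_days = 0,
                       relapse_spec = data.frame(patient = 1, start_day = 2,
                                                 duration = 2,
                                                 severity = "severe",
                                                 magnitude = 0),
                       artifact_rates = c(gap_rate = 0))
  co <- simulate_cohort(cfg)
  iv <- simulate_interval_features(co, "P01")
  a <- iv$sampen[iv$day_state == "normal"][1:200]
  b <- iv$sampen[iv$day_state == "relapse"][1:200]
  expect_gt(wilcox.test(a, b)$p.value, 0.01)
})

test_that("interval generator realizes configured effect sizes within
           tolerance", {
  # Cohen's d of a single 50+50 draw has SE ~ 0.21, so the fidelity bound
  # is checked on the mean realized shift over four seeds.
  for (key in c("sampen_mean", "ste_acc_std")) {
    es <- setNames(1.0, key)
    ds <- vapply(31:34, function(sd_) {
      co <- simulate_cohort(cohort_config(50, 50, days_per_subject = 1,
                                          seed = sd_, effect_sizes = es,
                                          artifact_rates = c(gap_rate = 0)))
      iv <- simulate_interval_features(co)
      iv <- iv[iv$state == "awake", ]
      agg <- if (endsWith(key, "_mean")) {
        tapply(iv$sampen, iv$subject_id, mean)
      } else {
        tapply(iv$ste_acc, iv$subject_id, sd)
      }
      grp <- co$subjects$group[match(names(agg), co$subjects$subject_id)]
      (mean(agg[grp == "patient"]) - mean(agg[grp == "control"])) /
        sqrt((var(agg[grp == "patient"]) + var(agg[grp == "control"])) / 2)
    }, numeric(1))
    expect_gt(mean(ds), 0.75)
    expect_lt(mean(ds), 1.25)
  }
})

test_that("state labels follow the 21-day prodrome and 30-day session
           windows exactly", {
  ann <- data.frame(subject_id = "P01", start_day = 50, end_day = 55,
                    start_s = 50 * 86400, end_s = 55 * 86400,
                    severity = "moderate", psychotic = FALSE,
                    magnitude = 1)
  days <- 0:70
  phys <- day_state_labels(ann, "P01", days, 21)
  expect_true(all(phys[days < 29] == "normal"))
  expect_true(all(phys[days >= 29 & days < 50] == "near_relapse"))
  expect_true(all(phys[days >= 50 & days < 55] == "relapse"))
  expect_true(all(phys[days >= 55] == "normal"))
  sess <- relapsekit:::session_state_labels(ann, "P01", days)
  expect_true(all(sess[days >= 20 & days < 50] == "pre_relapse"))
  expect_true(all(sess[days < 20] == "clean"))
})

test_that("synthetic sessions honour slice geometry, labels and slice-count
           mean", {
  ann <- data.frame(subject_id = "P01", start_day = 60, end_day = 65,
                    start_s = 0, end_s = 1, severity = "severe",
                    psychotic = TRUE, magnitude = 1)
  ss <- simulate_sessions("P01", ann, n_sessions = 40,
                          anomaly_magnitude = 1, seed = 3,
                          span_days = 100, mean_slices = 30)
  expect_true(all(vapply(ss, function(s)
    all(vapply(s$slices, function(m) all(dim(m) == c(128, 64)) &&
          all(m >= 0), logical(1))), logical(1))))
  for (s in ss) {
    expected <- if (s$session_date >= 60 && s$session_date < 65) "relapse"
      else if (s$session_date >= 30 && s$session_date < 60) "pre_relapse"
      else "clean"
    expect_identical(s$state, expected)
  }
  # no annotation -> all clean
  ss0 <- simulate_sessions("P01", ann[0, ], n_sessions = 10, seed = 4)
  expect_true(all(vapply(ss0, `[[`, character(1), "state") == "clean"))
  nsl <- vapply(simulate_sessions("P01", ann[0, ], 100, seed = 5,
                                  mean_slices = 30),
                function(s) length(s$slices), numeric(1))
  expect_lt(abs(mean(nsl) - 30), 3 * sqrt(30 / 100))
})
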