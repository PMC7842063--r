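test_that("cohort generation respects size, side ratio and height range", {
  co <- generate_cohort(10, affected_side_ratio = 0.4, seed = 11)
  expect_equal(nrow(co), 10)
  expect_equal(sum(co$affected_side == "left"), 4)
  expect_equal(sum(co$affected_side == "right"), 6)
  expect_true(all(co$height >= 1.55 & co$height <= 1.85))

  one <- generate_cohort(1, height_range = c(1.7, 1.7), seed = 2)
  expect_equal(one$height, 1.70)

  expect_identical(generate_cohort(8, seed = 5), generate_cohort(8, seed = 5))
  expect_error(generate_cohort(0), class = "gaitdose_invalid_config")
  expect_error(generate_cohort(3, height_range = c(1.8, 1.6)),
               class = "gaitdose_invalid_config")
})

test_that("jitter-free event trains have planted stance intervals and order", {
  tr <- symmetric_trial(cycle = 1.0, stance = 0.6)
  for (lg in c("left", "right")) {
    cy <- segment_gait_cycles(tr$events[tr$events$leg == lg, ])
    expect_true(all(abs(cy$stance_time - 0.6) < 1e-12))
    expect_true(all(abs(cy$cycle_time - 1.0) < 1e-12))
    tl <- tr$events$time_s[tr$events$leg == lg]
    expect_true(all(diff(sort(tl)) > 0))
  }
  # train covers the walk duration and legs are offset by half a cycle
  expect_gte(max(tr$events$time_s), 10)
  first_hs <- vapply(c("left", "right"), function(lg) {
    min(tr$events$time_s[tr$events$leg == lg &
                           tr$events$event_type == "heel_strike"])
  }, numeric(1))
  expect_equal(abs(unname(diff(first_hs))), 0.5)
})

test_that("jittered generation is seed-reproducible and rejects bad configs", {
  cfg <- gait_gen_config(timing_jitter_sd = 0.015, seed = 9L)
  t1 <- generate_gait_events(demo_profile(), cfg)
  t2 <- generate_gait_events(demo_profile(), cfg)
  expect_identical(t1$events, t2$events)
  expect_error(gait_gen_config(stance_fraction_affected = 1.2),
               class = "gaitdose_invalid_config")
  expect_error(gait_gen_config(cycle_time = -1),
               class = "gaitdose_invalid_config")
})

test_that("FSR synthesis produces rectangular pulses matching planted events", {
  tr <- symmetric_trial()
  fs <- 200
  traces <- synthesize_fsr_traces(tr, sampling_rate = fs)
  expect_s3_class(traces, "fsr_traces")
  expect_setequal(unique(traces$channel), c("toe", "lateral_heel", "medial_heel"))
  # noise-free pulse onsets equal planted heel-strikes to within one sample
  left_heel <- traces[traces$leg == "left" & traces$channel == "lateral_heel", ]
  iv <- detect_contact_intervals(left_heel$value, fs)
  hs <- sort(tr$events$time_s[tr$events$leg == "left" &
                                tr$events$event_type == "heel_strike"])
  hs <- hs[seq_len(nrow(iv))]  # last strike has no contact interval
  expect_true(all(abs(iv$onset - hs) <= 1 / fs + 1e-9))

  empty <- tr; empty$events <- tr$events[0, ]
  expect_equal(nrow(synthesize_fsr_traces(empty, 100)), 0)
  expect_warning(synthesize_fsr_traces(tr, 100, pulse_amplitude = 1,
                                       noise_sd = 2),
                 class = "gaitdose_warning")
})

test_that("E-field matrices honour montage profiles and stay non-negative", {
  co <- generate_cohort(4, seed = 3)
  profs <- default_montage_profiles()
  lob <- default_lobule_labels()

  zero_sd <- lapply(profs, function(p) {
    montage_profile(p$montage_id, p$lobule_labels, p$mean_field, 0)
  })
  ef0 <- generate_efield_matrix(zero_sd, co, seed = 1)
  for (m in names(zero_sd)) {
    rows <- as.matrix(ef0[ef0$montage == m, lob])
    expect_true(all(apply(rows, 1, function(r) {
      all(abs(r - zero_sd[[m]]$mean_field) < 1e-12)
    })))
  }

  ef <- generate_efield_matrix(profs, co, seed = 21)
  expect_true(all(as.matrix(ef[, lob]) >= 0))
  dn <- lob[grepl("dentate", lob)]
  expect_true(all(colMeans(ef[ef$montage == "dentate", dn]) > 0.2))
  legs <- lob[grepl("VIIb|VIIIa|VIIIb|IX$", lob) & !grepl("dentate", lob)]
  expect_true(all(colMeans(ef[ef$montage == "leg", legs]) > 0.08))

  bad <- profs
  bad$leg$lobule_labels <- rev(bad$leg$lobule_labels)
  expect_error(generate_efield_matrix(bad, co),
               class = "gaitdose_schema_error")
})

test_that("planted gait change is the exact linear map at zero noise", {
  co <- generate_cohort(5, seed = 8)
  ef <- generate_efield_matrix(default_montage_profiles(), co, seed = 8)
  assoc <- planted_association(noise_sd = 0, seed = 8)
  ch <- plant_gait_change(ef, assoc)
  lob <- rownames(assoc$coefficient_matrix)
  Xc <- scale(as.matrix(ef[, lob]), scale = FALSE)
  expected <- Xc %*% assoc$coefficient_matrix
  expect_equal(as.matrix(ch[, colnames(expected)]), expected,
               ignore_attr = TRUE, tolerance = 1e-12)

  null_assoc <- planted_association(active_lobules = character(0),
                                    noise_sd = 2, seed = 8)
  ch0 <- plant_gait_change(ef, null_assoc)
  vals <- as.matrix(ch0[, gait_parameter_names()])
  expect_lt(abs(mean(vals)), 3 * 2 / sqrt(length(vals)))
})
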