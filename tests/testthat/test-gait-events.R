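test_that("contact detection finds clean pulses and debounces dropouts", {
  fs <- 1000
  v <- numeric(2000)
  v[501:1200] <- 100  # pulse 0.5-1.199 s
  iv <- detect_contact_intervals(v, fs)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$onset, 0.5, tolerance = 1 / fs)
  expect_equal(iv$offset, 1.199, tolerance = 1 / fs)

  # 10 ms dropout inside the pulse is merged at a 50 ms debounce window
  v2 <- v
  v2[801:810] <- 0
  iv2 <- detect_contact_intervals(v2, fs, debounce_window = 0.05)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$onset, 0.5, tolerance = 1 / fs)

  # sub-debounce blip is discarded
  v3 <- numeric(1000)
  v3[101:110] <- 100
  expect_equal(nrow(detect_contact_intervals(v3, fs)), 0)

  expect_equal(nrow(detect_contact_intervals(numeric(500), fs)), 0)
  expect_error(detect_contact_intervals(v, fs, threshold_fraction = 1.5),
               class = "gaitdose_invalid_config")
})

test_that("event derivation takes earliest heel onset and latest offset", {
  contacts <- list(
    lateral_heel = data.frame(onset = 1.00, offset = 1.40),
    medial_heel = data.frame(onset = 1.01, offset = 1.42),
    toe = data.frame(onset = 1.10, offset = 1.62))
  ev <- derive_gait_events(contacts, "left")
  expect_equal(ev$event_type, c("heel_strike", "toe_off"))
  expect_equal(ev$time_s, c(1.00, 1.62))

  # footfall with heel contact but no toe contact is excluded with warning
  contacts$lateral_heel <- rbind(contacts$lateral_heel,
                                 data.frame(onset = 2.0, offset = 2.4))
  contacts$medial_heel <- rbind(contacts$medial_heel,
                                data.frame(onset = 2.0, offset = 2.4))
  expect_warning(ev2 <- derive_gait_events(contacts, "left"),
                 class = "gaitdose_warning")
  expect_equal(nrow(ev2), 2)

  empty <- lapply(contacts, function(x) x[0, ])
  expect_equal(nrow(derive_gait_events(empty, "left")), 0)
})

test_that("cycle segmentation matches hand computation and handles edges", {
  ev <- data.frame(leg = "left",
                   event_type = c("heel_strike", "toe_off", "heel_strike",
                                  "toe_off", "heel_strike"),
                   time_s = c(0, 0.6, 1, 1.6, 2))
  cy <- segment_gait_cycles(ev)
  expect_equal(nrow(cy), 2)
  expect_equal(cy$stance_time, c(0.6, 0.6))
  expect_equal(cy$swing_time, c(0.4, 0.4))
  expect_equal(cy$cycle_time, c(1, 1))
  expect_equal(cy$stance_time + cy$swing_time, cy$cycle_time)

  one <- segment_gait_cycles(ev[1:3, ])
  expect_equal(nrow(one), 1)
  expect_warning(none <- segment_gait_cycles(ev[1, , drop = FALSE]),
                 class = "gaitdose_warning")
  expect_equal(nrow(none), 0)

  # order-insensitive after sorting, idempotent structure
  shuffled <- ev[c(3, 1, 5, 2, 4), ]
  expect_equal(segment_gait_cycles(shuffled), cy)
})

test_that("event stream validation reports issues without mutating input", {
  tr <- symmetric_trial()
  expect_equal(nrow(validate_event_stream(tr$events)), 0)

  bad <- data.frame(leg = "left",
                    event_type = c("heel_strike", "heel_strike", "toe_off"),
                    time_s = c(0, 1, 1.6))
  iss <- validate_event_stream(bad)
  expect_true("missing toe-off" %in% iss$issue)

  unsorted <- tr$events[rev(seq_len(nrow(tr$events))), ]
  expect_true("non-monotone time" %in% validate_event_stream(unsorted)$issue)

  dup <- bad
  dup$time_s <- c(0, 0, 1.6)
  expect_true("duplicate timestamp" %in% validate_event_stream(dup)$issue)
})

test_that("detection of synthesized traces round-trips planted event times", {
  cfg <- gait_gen_config(cycle_time = 1.1, stance_fraction_affected = 0.62,
                         stance_fraction_unaffected = 0.68,
                         walking_speed = 0.8, timing_jitter_sd = 0.01,
                         seed = 4L)
  tr <- generate_gait_events(demo_profile("right"), cfg)
  for (fs in c(100, 250)) {
    traces <- synthesize_fsr_traces(tr, sampling_rate = fs)
    ev <- events_from_traces(traces)
    for (lg in c("left", "right")) {
      for (ty in c("heel_strike", "toe_off")) {
        planted <- sort(tr$events$time_s[tr$events$leg == lg &
                                           tr$events$event_type == ty])
        got <- sort(ev$time_s[ev$leg == lg & ev$event_type == ty])
        n <- length(got)
        expect_gte(n, length(planted) - 1)  # final strike has no contact
        expect_true(all(abs(got - planted[seq_len(n)]) <= 1 / fs + 1e-9))
      }
    }
  }
})
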