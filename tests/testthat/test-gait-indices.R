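test_that("walking speed is distance over duration with guarded inputs", {
  expect_equal(compute_walking_speed(10, 10), 1.0)
  expect_equal(compute_walking_speed(10, 12.5), 0.8)
  expect_error(compute_walking_speed(10, 0), class = "gaitdose_invalid_input")
})

test_that("temporal indices reproduce the healthy 60/40 stance-swing split", {
  tr <- symmetric_trial(cycle = 1.0, stance = 0.6)
  ix <- compute_index_set(tr)
  expect_equal(ix$pct_stance_affected, 60)
  expect_equal(ix$pct_stance_unaffected, 60)
  expect_equal(ix$pct_swing_affected, 40)
  expect_equal(ix$pct_swing_unaffected, 40)
  expect_equal(ix$cadence, 120)
  expect_equal(ix$pct_single_support_affected, 40)
  expect_equal(ix$pct_single_support_unaffected, 40)
  expect_equal(ix$stride_time_affected, 1.0)
  expect_equal(ix$step_time_affected, 0.5)
})

test_that("spatial indices follow the step-length, GSR and walk-ratio formulas", {
  sp <- compute_spatial_indices(c(affected = 0.5, unaffected = 0.5),
                                walking_speed = 1.0, cadence = 120,
                                height = 1.70)
  expect_equal(sp$step_length_affected, 0.5)
  expect_equal(sp$norm_step_length_affected, 0.2941, tolerance = 1e-4)
  expect_equal(sp$gait_stability_ratio, 2.0)
  expect_equal(sp$walk_ratio_affected, 0.004167, tolerance = 1e-4)
  expect_error(compute_spatial_indices(c(affected = .5, unaffected = .5),
                                       0, 120, 1.7),
               class = "gaitdose_invalid_input")
})

test_that("symmetry index is zero at symmetry and antisymmetric", {
  expect_equal(compute_symmetry_index(60, 60), 0)
  expect_equal(compute_symmetry_index(66, 54), 20)
  expect_equal(compute_symmetry_index(54, 66), -20)
  expect_error(compute_symmetry_index(0, 60),
               class = "gaitdose_invalid_input")
})

test_that("planted asymmetric stance fractions are recovered exactly", {
  cfg <- gait_gen_config(cycle_time = 1.0, stance_fraction_affected = 0.65,
                         stance_fraction_unaffected = 0.60,
                         walking_speed = 1.0, timing_jitter_sd = 0)
  tr <- generate_gait_events(demo_profile("left"), cfg)
  ix <- compute_index_set(tr)
  expect_equal(ix$pct_stance_affected, 65)
  expect_equal(ix$pct_stance_unaffected, 60)
  # SI on left/right: affected side is left here
  expect_equal(ix$symmetry_index,
               compute_symmetry_index(65, 60))
})

test_that("a leg without events yields missing fields, not a crash", {
  tr <- symmetric_trial()
  tr$events <- tr$events[tr$events$leg == tr$unaffected_side, ]
  ix <- suppressWarnings(compute_index_set(tr))
  expect_true(is.na(ix$pct_stance_affected))
  expect_true("affected" %in% attr(ix, "missing_side"))
  expect_false(is.na(ix$pct_stance_unaffected))
})

test_that("index identities hold across randomized gait configurations", {
  set.seed(71)
  for (i in 1:12) {
    cfg <- gait_gen_config(
      cycle_time = runif(1, 0.9, 1.6),
      stance_fraction_affected = runif(1, 0.55, 0.72),
      stance_fraction_unaffected = runif(1, 0.55, 0.72),
      walking_speed = runif(1, 0.5, 1.3),
      timing_jitter_sd = sample(c(0, 0.01), 1),
      seed = i)
    tr <- generate_gait_events(demo_profile(sample(c("left", "right"), 1)), cfg)
    ix <- compute_index_set(tr)
    expect_equal(ix$pct_stance_affected + ix$pct_swing_affected, 100,
                 tolerance = 1e-9)
    expect_equal(ix$pct_stance_unaffected + ix$pct_swing_unaffected, 100,
                 tolerance = 1e-9)
    # GSR (steps/m) times speed returns cadence in steps/s
    expect_equal(ix$gait_stability_ratio * ix$walking_speed,
                 ix$cadence / 60, tolerance = 1e-12)
    # walk ratio times cadence (steps/min) returns step length
    expect_equal(ix$walk_ratio_affected * ix$cadence,
                 ix$step_time_affected * ix$walking_speed,
                 tolerance = 1e-12)
    # jitter-free equal cycles: %SST equals the contralateral %swing
    if (cfg$timing_jitter_sd == 0) {
      expect_equal(ix$pct_single_support_affected, ix$pct_swing_unaffected,
                   tolerance = 1e-9)
    }
  }
  # SI antisymmetry on random positive stance pairs
  for (i in 1:10) {
    a <- runif(1, 40, 80); b <- runif(1, 40, 80)
    expect_equal(compute_symmetry_index(a, b),
                 -compute_symmetry_index(b, a), tolerance = 1e-12)
    expect_equal(compute_symmetry_index(a, a), 0)
  }
})
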