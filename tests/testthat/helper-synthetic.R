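# Shared fixtures: all synthetic, built in code at test time.

demo_profile <- function(side = "left", height = 1.70, id = "S01") {
  list(subject_id = id, height = height, affected_side = side)
}

# jitter-free symmetric walk: cycle 1.0 s, stance 0.6 s, 1 m/s over 10 m
symmetric_trial <- function(cycle = 1.0, stance = 0.6, speed = 1.0,
                            distance = 10, side = "left") {
  cfg <- gait_gen_config(cycle_time = cycle,
                         stance_fraction_affected = stance / cycle,
                         stance_fraction_unaffected = stance / cycle,
                         walking_speed = speed, walkway_distance = distance,
                         timing_jitter_sd = 0)
  generate_gait_events(demo_profile(side), cfg)
}

# independent exact two-sided rank-sum oracle from the closed-form
# Mann-Whitney null distribution (stats::pwilcox), valid without ties
pwilcox_two_sided <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  u <- w - n_a * (n_a + 1) / 2
  p_lo <- stats::pwilcox(u, n_a, n_b)
  p_hi <- 1 - stats::pwilcox(u - 1, n_a, n_b)
  min(1, 2 * min(p_lo, p_hi))
}

# normal-equations least-squares oracle for full-rank problems
ols_fitted <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  Xc %*% B + matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
}
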