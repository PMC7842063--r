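#' Canonical gait parameter names
#'
#' The 17 spatiotemporal gait parameters reported per trial: normalized step
#' length, walk ratio, stride time, step time, percent stance, percent swing
#' and percent single-support time for the affected and unaffected sides,
#' plus gait stability ratio, symmetry index and cadence. Overground walking
#' speed is computed alongside but is not part of this canonical list.
#'
#' @return Character vector of length 17.
#' @export
gait_parameter_names <- function() {
  c("norm_step_length_affected", "norm_step_length_unaffected",
    "walk_ratio_affected", "walk_ratio_unaffected",
    "gait_stability_ratio", "symmetry_index",
    "stride_time_affected", "stride_time_unaffected",
    "step_time_affected", "step_time_unaffected",
    "pct_stance_affected", "pct_stance_unaffected",
    "pct_swing_affected", "pct_swing_unaffected",
    "pct_single_support_affected", "pct_single_support_unaffected",
    "cadence")
}

#' Default cerebellar lobule label set
#'
#' SUIT-style lobule labels re-keyed by lesion side (contra-/ipsi-lesional
#' hemispheres plus vermis), together with the two dentate nuclei: 30 labels
#' in total. The set is configurable everywhere it is consumed.
#'
#' @return Character vector of 30 lobule labels.
#' @export
default_lobule_labels <- function() {
  hemi <- c("I_IV", "V", "VI", "CrusI", "CrusII",
            "VIIb", "VIIIa", "VIIIb", "IX", "X")
  vermis <- c("VI", "CrusI", "CrusII", "VIIb", "VIIIa", "VIIIb", "IX", "X")
  c(paste0("contra_", hemi), paste0("ipsi_", hemi),
    paste0("vermis_", vermis),
    "contra_dentate", "ipsi_dentate")
}

#' Gait generator configuration
#'
#' Parameters of the two-leg periodic gait event model. Defaults describe
#' slow hemiplegic overground walking on a 10 m walkway: a 1.25 s gait
#' cycle per leg at 0.8 m/s, with a shortened stance fraction on the
#' affected (paretic) side and a compensatory prolonged stance on the
#' unaffected side.
#'
#' @param cycle_time Seconds per gait cycle (heel-strike to heel-strike of
#'   the same leg).
#' @param stance_fraction_affected,stance_fraction_unaffected Fraction of
#'   the cycle spent in stance on each side, in (0, 1).
#' @param walking_speed Overground speed in m/s.
#' @param walkway_distance Walkway length in metres.
#' @param timing_jitter_sd SD in seconds of independent truncated-Gaussian
#'   jitter (truncated at 3 SD) added to every event time.
#' @param phase_offset Offset between the two legs as a fraction of a cycle.
#' @param seed Integer seed for the jitter stream.
#' @return An object of class `gait_gen_config`.
#' @export
gait_gen_config <- function(cycle_time = 1.25,
                            stance_fraction_affected = 0.62,
                            stance_fraction_unaffected = 0.68,
                            walking_speed = 0.8,
                            walkway_distance = 10,
                            timing_jitter_sd = 0.02,
                            phase_offset = 0.5,
                            seed = 1L) {
  for (nm in c("cycle_time", "walking_speed", "walkway_distance")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      stop_config(nm, " must be a positive number")
    }
  }
  for (nm in c("stance_fraction_affected", "stance_fraction_unaffected")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0 || v >= 1) {
      stop_config(nm, " must lie strictly between 0 and 1")
    }
  }
  if (!is_scalar_number(timing_jitter_sd) || timing_jitter_sd < 0) {
    stop_config("timing_jitter_sd must be non-negative")
  }
  structure(list(cycle_time = cycle_time,
                 stance_fraction_affected = stance_fraction_affected,
                 stance_fraction_unaffected = stance_fraction_unaffected,
                 walking_speed = walking_speed,
                 walkway_distance = walkway_distance,
                 timing_jitter_sd = timing_jitter_sd,
                 phase_offset = phase_offset,
                 seed = as.integer(seed)),
            class = "gait_gen_config")
}

#' Generate a synthetic hemiplegic cohort
#'
#' Heights are drawn uniformly within `height_range`; affected sides are
#' assigned so that `round(n_subjects * affected_side_ratio)` subjects are
#' left-hemiplegic (deterministic rounding), with the side order shuffled.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param height_range Length-2 numeric, metres; may be degenerate.
#' @param affected_side_ratio Fraction of subjects affected on the left.
#' @param seed Integer seed.
#' @return data.frame with columns `subject_id`, `height`, `affected_side`.
#' @examples
#' generate_cohort(10, affected_side_ratio = 0.4, seed = 7)
#' @export
generate_cohort <- function(n_subjects, height_range = c(1.55, 1.85),
                            affected_side_ratio = 0.4, seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 1) {
    stop_config("n_subjects must be >= 1")
  }
  if (length(height_range) != 2L || any(height_range <= 0) ||
      height_range[2] < height_range[1]) {
    stop_config("height_range must be positive and non-decreasing")
  }
  if (affected_side_ratio < 0 || affected_side_ratio > 1) {
    stop_config("affected_side_ratio must lie in [0, 1]")
  }
  n_subjects <- as.integer(n_subjects)
  set.seed(as.integer(seed))
  heights <- stats::runif(n_subjects, height_range[1], height_range[2])
  n_left <- as.integer(round(n_subjects * affected_side_ratio))
  sides <- sample(c(rep("left", n_left), rep("right", n_subjects - n_left)))
  data.frame(subject_id = sprintf("S%02d", seq_len(n_subjects)),
             height = heights,
             affected_side = sides,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic walk trial
#'
#' Emulates one overground pass as two phase-shifted periodic event trains.
#' The affected leg strikes at multiples of the cycle time from trial start;
#' the unaffected leg is offset by `phase_offset` of a cycle. Toe-off
#' follows each heel-strike by the side's stance fraction of the cycle.
#' The train covers at least `walkway_distance / walking_speed` seconds and
#' ends on a heel-strike so the final cycle is complete. Independent
#' truncated-Gaussian jitter is then added to every event time.
#'
#' @param profile One-row data.frame (or list) with `subject_id`, `height`
#'   and `affected_side`.
#' @param config A [gait_gen_config()].
#' @param session,montage Metadata strings carried through the pipeline.
#' @return An object of class `walk_trial`: list with an `events`
#'   data.frame (`leg`, `event_type`, `time_s`) and trial context.
#' @export
generate_gait_events <- function(profile, config,
                                 session = "pre", montage = "none") {
  if (!inherits(config, "gait_gen_config")) {
    stop_config("config must be a gait_gen_config object")
  }
  affected <- match.arg(profile$affected_side, c("left", "right"))
  unaffected <- setdiff(c("left", "right"), affected)
  duration <- config$walkway_distance / config$walking_speed
  ct <- config$cycle_time

  leg_train <- function(t0, stance_fraction) {
    n_strike <- ceiling((duration - t0) / ct)
    hs <- t0 + ct * seq(0, n_strike)
    to <- hs[-length(hs)] + stance_fraction * ct
    data.frame(event_type = c(rep("heel_strike", length(hs)),
                              rep("toe_off", length(to))),
               time_s = c(hs, to), stringsAsFactors = FALSE)
  }

  aff <- leg_train(0, config$stance_fraction_affected)
  aff$leg <- affected
  una <- leg_train(config$phase_offset * ct, config$stance_fraction_unaffected)
  una$leg <- unaffected
  events <- rbind(aff, una)[, c("leg", "event_type", "time_s")]

  if (config$timing_jitter_sd > 0) {
    set.seed(config$seed)
    events$time_s <- events$time_s +
      rtruncnorm0(nrow(events), config$timing_jitter_sd)
    for (lg in c("left", "right")) {
      tl <- sort(events$time_s[events$leg == lg])
      if (any(diff(tl) <= 0)) {
        stop_config("timing_jitter_sd too large: events no longer ordered")
      }
    }
  }
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL

  structure(list(events = events,
                 distance = config$walkway_distance,
                 duration = duration,
                 height = profile$height,
                 affected_side = affected,
                 unaffected_side = unaffected,
                 subject_id = profile$subject_id,
                 session = session,
                 montage = montage,
                 seed = config$seed),
            class = "walk_trial")
}

#' @export
print.walk_trial <- function(x, ...) {
  cat(sprintf("<walk_trial> subject %s  session %s  montage %s\n",
              x$subject_id, x$session, x$montage))
  cat(sprintf("  %d events over %.2f s, affected side: %s\n",
              nrow(x$events), x$duration, x$affected_side))
  invisible(x)
}

#' Synthesize force-sensitive-resistor traces from a walk trial
#'
#' Builds the three per-shoe pressure channels (greater toe, lateral heel,
#' medial heel) implied by the trial's gait events. Heel channels are in
#' contact from heel-strike until 70% of stance; the toe channel from 15%
#' of stance until toe-off. Hence the earliest heel-channel onset equals
#' the heel-strike and the latest offset across channels equals the
#' toe-off, so event detection can round-trip the planted times.
#'
#' @param trial A [generate_gait_events()] trial.
#' @param sampling_rate Samples per second (> 0).
#' @param pulse_amplitude Contact pressure in arbitrary units.
#' @param onset_ramp Seconds of linear rise/fall at each contact edge.
#' @param noise_sd SD of additive Gaussian sensor noise.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `fsr_traces`: long data.frame (`leg`,
#'   `channel`, `time_s`, `value`) with a `sampling_rate` attribute.
#' @export
synthesize_fsr_traces <- function(trial, sampling_rate = 200,
                                  pulse_amplitude = 100, onset_ramp = 0,
                                  noise_sd = 0, seed = 1L) {
  if (!is_scalar_number(sampling_rate) || sampling_rate <= 0) {
    stop_config("sampling_rate must be positive")
  }
  if (pulse_amplitude <= noise_sd) {
    warn_gd("pulse_amplitude <= noise_sd: event recovery not guaranteed")
  }
  ev <- trial$events
  empty <- data.frame(leg = character(), channel = character(),
                      time_s = numeric(), value = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(ev) || nrow(ev) == 0L) {
    return(structure(empty, class = c("fsr_traces", "data.frame"),
                     sampling_rate = sampling_rate))
  }
  t_grid <- seq(0, max(ev$time_s) + 0.25, by = 1 / sampling_rate)

  # trapezoidal contact profile on [on, off] with linear edges of onset_ramp
  contact_profile <- function(t, on, off) {
    v <- numeric(length(t))
    for (i in seq_along(on)) {
      if (onset_ramp > 0) {
        rise <- pmin(1, pmax(0, (t - on[i]) / onset_ramp))
        fall <- pmin(1, pmax(0, (off[i] - t) / onset_ramp))
        v <- pmax(v, pmin(rise, fall))
      } else {
        eps <- 1e-9  # guard against float error on grid-aligned edges
        v <- pmax(v, as.numeric(t >= on[i] - eps & t <= off[i] + eps))
      }
    }
    v * pulse_amplitude
  }

  set.seed(as.integer(seed))
  out <- list()
  for (lg in unique(ev$leg)) {
    le <- ev[ev$leg == lg, ]
    hs <- sort(le$time_s[le$event_type == "heel_strike"])
    to <- sort(le$time_s[le$event_type == "toe_off"])
    # pair each heel-strike with the next toe-off
    on <- off <- numeric(0)
    for (h in hs) {
      nxt <- to[to > h]
      if (length(nxt)) { on <- c(on, h); off <- c(off, nxt[1]) }
    }
    stance <- off - on
    chans <- list(
      lateral_heel = cbind(on, on + 0.70 * stance),
      medial_heel  = cbind(on, on + 0.70 * stance),
      toe          = cbind(on + 0.15 * stance, off))
    for (ch in names(chans)) {
      v <- contact_profile(t_grid, chans[[ch]][, 1], chans[[ch]][, 2])
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      out[[paste(lg, ch)]] <- data.frame(leg = lg, channel = ch,
                                         time_s = t_grid, value = v,
                                         stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("fsr_traces", "data.frame"),
            sampling_rate = sampling_rate)
}

#' Montage electric-field profile
#'
#' Mean lobular electric field strength (V/m) and its between-subject SD
#' for one stimulation montage.
#'
#' @param montage_id Montage label, e.g. `"dentate"` or `"leg"`.
#' @param lobule_labels Character vector of unique lobule labels.
#' @param mean_field Non-negative numeric, V/m, one per label.
#' @param between_subject_sd Non-negative numeric, V/m, one per label
#'   (recycled if scalar).
#' @return Object of class `montage_profile`.
#' @export
montage_profile <- function(montage_id, lobule_labels, mean_field,
                            between_subject_sd = 0) {
  if (anyDuplicated(lobule_labels)) stop_config("lobule labels must be unique")
  if (length(mean_field) != length(lobule_labels)) {
    stop_config("mean_field length must match lobule_labels")
  }
  if (any(mean_field < 0)) stop_config("mean_field must be non-negative")
  sdv <- rep_len(between_subject_sd, length(lobule_labels))
  if (any(sdv < 0)) stop_config("between_subject_sd must be non-negative")
  structure(list(montage_id = montage_id,
                 lobule_labels = as.character(lobule_labels),
                 mean_field = as.numeric(mean_field),
                 between_subject_sd = sdv),
            class = "montage_profile")
}

#' Default dentate and leg montage profiles
#'
#' Qualitative defaults for the two bilateral cerebellar tDCS montages.
#' The dentate montage places > 0.2 V/m on the dentate nuclei (0.25 V/m
#' default) with ~0.12 V/m across the anterior and posterior lobes; the
#' leg-representation montage places ~0.10 V/m on posterior lobules
#' VIIb-IX and on the dentate nuclei with weaker field elsewhere. The
#' between-subject SD, which is a free parameter of the generator, defaults
#' to a 25% coefficient of variation of the montage mean.
#'
#' @param lobule_labels Label set; defaults to [default_lobule_labels()].
#' @param cv Between-subject coefficient of variation of the mean field.
#' @return Named list of two `montage_profile` objects, `dentate` and `leg`.
#' @export
default_montage_profiles <- function(lobule_labels = default_lobule_labels(),
                                     cv = 0.25) {
  dentate_idx <- grepl("dentate", lobule_labels)
  leg_idx <- grepl("VIIb|VIIIa|VIIIb|IX$", lobule_labels) & !dentate_idx

  dentate_mean <- ifelse(dentate_idx, 0.25, 0.12)
  leg_mean <- ifelse(dentate_idx | leg_idx, 0.10, 0.04)

  list(
    dentate = montage_profile("dentate", lobule_labels, dentate_mean,
                              cv * dentate_mean),
    leg = montage_profile("leg", lobule_labels, leg_mean, cv * leg_mean))
}

#' Generate a subject-by-montage lobular E-field matrix
#'
#' One row per subject and montage; each entry is the montage's mean field
#' for that lobule plus a Gaussian subject perturbation, truncated at zero
#' (field strengths are magnitudes).
#'
#' @param profiles List of [montage_profile()] objects sharing one label set.
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param seed Integer seed.
#' @return data.frame with columns `subject`, `montage` and one numeric
#'   column per lobule label.
#' @export
generate_efield_matrix <- function(profiles, cohort, seed = 1L) {
  labels <- profiles[[1]]$lobule_labels
  for (p in profiles) {
    if (!identical(p$lobule_labels, labels)) {
      stop_schema("montage profiles must share one lobule label set")
    }
  }
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    for (p in profiles) {
      field <- pmax(0, p$mean_field +
                      stats::rnorm(length(labels), 0, p$between_subject_sd))
      rows[[length(rows) + 1L]] <-
        c(list(subject = cohort$subject_id[i], montage = p$montage_id),
          as.list(stats::setNames(field, labels)))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Planted linear field-to-gait-change association
#'
#' Ground truth for regression-recovery testing: a sparse coefficient
#' matrix mapping centred lobular field strength (V/m) to percent
#' normalized gait change, non-zero only on `active_lobules`.
#'
#' @param lobule_labels Predictor labels.
#' @param parameters Response names; defaults to the 17 gait parameters.
#' @param active_lobules Labels whose coefficient rows are non-zero.
#' @param effect_size Scale of the non-zero coefficients (change-units per V/m).
#' @param noise_sd SD of additive response noise, change-units.
#' @param seed Integer seed (coefficients and noise).
#' @return Object of class `planted_association` holding
#'   `coefficient_matrix` (lobules x parameters), `noise_sd`, `seed`.
#' @export
planted_association <- function(lobule_labels = default_lobule_labels(),
                                parameters = gait_parameter_names(),
                                active_lobules = c("vermis_VIIIb", "ipsi_IX",
                                                   "vermis_IX", "ipsi_X"),
                                effect_size = 1, noise_sd = 0, seed = 1L) {
  if (!all(active_lobules %in% lobule_labels)) {
    stop_schema("active_lobules must be a subset of lobule_labels")
  }
  set.seed(as.integer(seed))
  B <- matrix(0, length(lobule_labels), length(parameters),
              dimnames = list(lobule_labels, parameters))
  B[active_lobules, ] <- stats::rnorm(length(active_lobules) *
                                        length(parameters)) * effect_size
  structure(list(coefficient_matrix = B,
                 active_lobules = active_lobules,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_association")
}

#' Plant gait-parameter changes from an E-field matrix
#'
#' Applies the planted linear map to the column-centred E-field matrix and
#' adds Gaussian noise: `change = centred_field %*% B + noise`.
#'
#' @param efield data.frame from [generate_efield_matrix()].
#' @param assoc A [planted_association()].
#' @return data.frame with `subject`, `montage` and one column per gait
#'   parameter (percent normalized change).
#' @export
plant_gait_change <- function(efield, assoc) {
  B <- assoc$coefficient_matrix
  labels <- rownames(B)
  if (!all(labels %in% names(efield))) {
    stop_schema("efield matrix lacks lobule columns: ",
                paste(setdiff(labels, names(efield)), collapse = ", "))
  }
  X <- as.matrix(efield[, labels, drop = FALSE])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  set.seed(assoc$seed + 1L)
  Yv <- Xc %*% B
  if (assoc$noise_sd > 0) {
    Yv <- Yv + matrix(stats::rnorm(length(Yv), 0, assoc$noise_sd), nrow(Yv))
  }
  cbind(efield[, c("subject", "montage")],
        as.data.frame(Yv, stringsAsFactors = FALSE))
}
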