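#' Overground walking speed
#'
#' @param distance Walkway distance in metres.
#' @param duration Walk duration in seconds (> 0).
#' @return Speed in m/s.
#' @export
compute_walking_speed <- function(distance, duration) {
  if (!is_scalar_number(duration) || duration <= 0) {
    stop_invalid("duration must be positive")
  }
  if (!is_scalar_number(distance) || distance <= 0) {
    stop_invalid("distance must be positive")
  }
  distance / duration
}

#' Temporal gait indices from segmented cycles
#'
#' Per-side means across retained cycles of stride time, step time, percent
#' stance, percent swing and percent single-support time, plus cadence.
#'
#' Stride time is the interval between successive ipsilateral heel-strikes
#' (the cycle time). Step time of a leg is the interval from the preceding
#' contralateral heel-strike to that leg's heel-strike. Percent stance and
#' swing express each cycle's stance/swing intervals as percentages of its
#' cycle time. Percent single-support time of a leg is the contralateral
#' mean swing time as a percentage of that leg's mean cycle time. Cadence
#' is steps per minute, measured as heel-strikes (both legs) per unit time
#' between the first and last heel-strike.
#'
#' @param cycles_affected,cycles_unaffected Cycle tables from
#'   [segment_gait_cycles()].
#' @param events Both-leg event data.frame (`leg`, `event_type`, `time_s`).
#' @param affected_side `"left"` or `"right"`.
#' @return List of temporal fields (NA for a side with no complete cycle,
#'   with the missing side named in the `missing` element).
#' @export
compute_temporal_indices <- function(cycles_affected, cycles_unaffected,
                                     events, affected_side) {
  missing <- character()
  side_stats <- function(cycles) {
    if (nrow(cycles) == 0L) {
      return(list(stride = NA_real_, pct_stance = NA_real_,
                  pct_swing = NA_real_, swing = NA_real_, cycle = NA_real_))
    }
    list(stride = mean(cycles$cycle_time),
         pct_stance = mean(100 * cycles$stance_time / cycles$cycle_time),
         pct_swing = mean(100 * cycles$swing_time / cycles$cycle_time),
         swing = mean(cycles$swing_time),
         cycle = mean(cycles$cycle_time))
  }
  aff <- side_stats(cycles_affected)
  una <- side_stats(cycles_unaffected)
  if (nrow(cycles_affected) == 0L) missing <- c(missing, "affected")
  if (nrow(cycles_unaffected) == 0L) missing <- c(missing, "unaffected")

  # step time: interval ending at each leg's heel-strike, starting at the
  # preceding contralateral heel-strike
  hs <- events[events$event_type == "heel_strike", ]
  hs <- hs[order(hs$time_s), ]
  step_time <- c(left = NA_real_, right = NA_real_)
  if (nrow(hs) >= 2L) {
    alternation <- hs$leg[-1] != hs$leg[-nrow(hs)]
    steps <- data.frame(leg = hs$leg[-1][alternation],
                        dt = diff(hs$time_s)[alternation])
    for (lg in c("left", "right")) {
      if (any(steps$leg == lg)) step_time[lg] <- mean(steps$dt[steps$leg == lg])
    }
  }
  unaffected_side <- setdiff(c("left", "right"), affected_side)

  cadence <- NA_real_
  if (nrow(hs) >= 2L) {
    span <- max(hs$time_s) - min(hs$time_s)
    if (span > 0) cadence <- 60 * (nrow(hs) - 1L) / span
  }

  pct_sst <- function(own, other) {
    if (is.na(own$cycle) || is.na(other$swing)) return(NA_real_)
    100 * other$swing / own$cycle
  }

  list(stride_time_affected = aff$stride,
       stride_time_unaffected = una$stride,
       step_time_affected = unname(step_time[affected_side]),
       step_time_unaffected = unname(step_time[unaffected_side]),
       pct_stance_affected = aff$pct_stance,
       pct_stance_unaffected = una$pct_stance,
       pct_swing_affected = aff$pct_swing,
       pct_swing_unaffected = una$pct_swing,
       pct_single_support_affected = pct_sst(aff, una),
       pct_single_support_unaffected = pct_sst(una, aff),
       cadence = cadence,
       missing = missing)
}

#' Spatial gait indices
#'
#' Step length is step time times walking speed; normalized step length
#' divides by subject height. The gait stability ratio is cadence in
#' steps/s divided by walking speed (steps per metre); cadence is stored
#' in steps/min and converted inside this formula only. The walk ratio is
#' step length divided by cadence in steps/min.
#'
#' @param step_time Named numeric: `affected`, `unaffected` (seconds).
#' @param walking_speed m/s (> 0).
#' @param cadence steps/min (> 0).
#' @param height Subject height in metres (> 0).
#' @return List with per-side `step_length`, `norm_step_length`,
#'   `walk_ratio`, plus `gait_stability_ratio`.
#' @export
compute_spatial_indices <- function(step_time, walking_speed, cadence, height) {
  if (!is_scalar_number(walking_speed) || walking_speed <= 0) {
    stop_invalid("walking_speed must be positive")
  }
  if (!is_scalar_number(height) || height <= 0) {
    stop_invalid("height must be positive")
  }
  if (!is_scalar_number(cadence) || cadence <= 0) {
    stop_invalid("cadence must be positive")
  }
  step_length <- step_time * walking_speed
  list(step_length_affected = unname(step_length["affected"]),
       step_length_unaffected = unname(step_length["unaffected"]),
       norm_step_length_affected = unname(step_length["affected"]) / height,
       norm_step_length_unaffected = unname(step_length["unaffected"]) / height,
       gait_stability_ratio = (cadence / 60) / walking_speed,
       walk_ratio_affected = unname(step_length["affected"]) / cadence,
       walk_ratio_unaffected = unname(step_length["unaffected"]) / cadence)
}

#' Gait symmetry index
#'
#' Signed percent difference of the left and right percent-stance values,
#' normalized by their mean: `SI = (X_L - X_R) * 100 / (0.5 * (X_L + X_R))`.
#' Zero indicates perfectly symmetric stance; the sign says which leg
#' spends longer in stance.
#'
#' @param stance_pct_left,stance_pct_right Percent stance per leg (> 0).
#' @return Symmetry index in percent.
#' @export
compute_symmetry_index <- function(stance_pct_left, stance_pct_right) {
  if (!is_scalar_number(stance_pct_left) || !is_scalar_number(stance_pct_right) ||
      stance_pct_left <= 0 || stance_pct_right <= 0) {
    stop_invalid("stance percentages must be positive numbers")
  }
  (stance_pct_left - stance_pct_right) * 100 /
    (0.5 * (stance_pct_left + stance_pct_right))
}

#' Compute the full per-trial gait index set
#'
#' Orchestrates event validation, cycle segmentation, and the temporal,
#' spatial and symmetry computations, mapping left/right onto the
#' affected/unaffected sides of the trial. The first and last complete
#' cycle of each leg are trimmed by default to reduce
#' acceleration/deceleration bias over the walkway.
#'
#' @param trial A `walk_trial`.
#' @param trim_cycles Complete cycles dropped from each end of each leg's
#'   cycle table (default 1; set 0 to keep all).
#' @return One-row data.frame of class `gait_indices`: `walking_speed`
#'   plus the 17 parameters of [gait_parameter_names()], with trial
#'   metadata columns. Cycle tables are attached as attribute `cycles`;
#'   sides without complete cycles yield NA fields and a
#'   `missing_side` attribute.
#' @export
compute_index_set <- function(trial, trim_cycles = 1L) {
  ev <- trial$events
  issues <- validate_event_stream(ev)
  fatal <- issues$issue %in% c("non-monotone time", "duplicate timestamp")
  if (any(fatal)) {
    stop_invalid("event stream fails validation: ",
                 paste(unique(issues$issue[fatal]), collapse = "; "))
  }
  trim <- function(cycles) {
    n <- nrow(cycles)
    if (trim_cycles > 0L && n > 2L * trim_cycles) {
      cycles[(trim_cycles + 1L):(n - trim_cycles), , drop = FALSE]
    } else cycles
  }
  side_cycles <- list()
  for (lg in c("left", "right")) {
    le <- ev[ev$leg == lg, , drop = FALSE]
    side_cycles[[lg]] <- suppressWarnings(trim(segment_gait_cycles(le)))
  }
  aff <- trial$affected_side
  una <- trial$unaffected_side %||% setdiff(c("left", "right"), aff)

  tmp <- compute_temporal_indices(side_cycles[[aff]], side_cycles[[una]],
                                  ev, aff)
  speed <- compute_walking_speed(trial$distance, trial$duration)

  spatial <- list(norm_step_length_affected = NA_real_,
                  norm_step_length_unaffected = NA_real_,
                  walk_ratio_affected = NA_real_,
                  walk_ratio_unaffected = NA_real_,
                  gait_stability_ratio = NA_real_)
  if (!is.na(tmp$cadence)) {
    sp <- compute_spatial_indices(
      c(affected = tmp$step_time_affected,
        unaffected = tmp$step_time_unaffected),
      speed, tmp$cadence, trial$height)
    spatial <- sp
  }

  stance_lr <- c(left = NA_real_, right = NA_real_)
  stance_lr[aff] <- tmp$pct_stance_affected
  stance_lr[una] <- tmp$pct_stance_unaffected
  si <- if (anyNA(stance_lr)) NA_real_ else {
    compute_symmetry_index(stance_lr["left"], stance_lr["right"])
  }

  out <- data.frame(
    subject_id = trial$subject_id %||% NA_character_,
    session = trial$session %||% NA_character_,
    montage = trial$montage %||% NA_character_,
    walking_speed = speed,
    norm_step_length_affected = spatial$norm_step_length_affected,
    norm_step_length_unaffected = spatial$norm_step_length_unaffected,
    walk_ratio_affected = spatial$walk_ratio_affected,
    walk_ratio_unaffected = spatial$walk_ratio_unaffected,
    gait_stability_ratio = spatial$gait_stability_ratio,
    symmetry_index = unname(si),
    stride_time_affected = tmp$stride_time_affected,
    stride_time_unaffected = tmp$stride_time_unaffected,
    step_time_affected = tmp$step_time_affected,
    step_time_unaffected = tmp$step_time_unaffected,
    pct_stance_affected = tmp$pct_stance_affected,
    pct_stance_unaffected = tmp$pct_stance_unaffected,
    pct_swing_affected = tmp$pct_swing_affected,
    pct_swing_unaffected = tmp$pct_swing_unaffected,
    pct_single_support_affected = tmp$pct_single_support_affected,
    pct_single_support_unaffected = tmp$pct_single_support_unaffected,
    cadence = tmp$cadence,
    stringsAsFactors = FALSE)
  class(out) <- c("gait_indices", "data.frame")
  attr(out, "cycles") <- side_cycles
  if (length(tmp$missing)) attr(out, "missing_side") <- tmp$missing
  out
}
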