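#' Detect contact intervals in one FSR channel
#'
#' Thresholds a pressure trace at a fraction of its dynamic range and
#' returns the maximal supra-threshold runs. Gaps shorter than the debounce
#' window are merged into the surrounding contact; runs shorter than the
#' window are discarded as bounce.
#'
#' @param values Numeric pressure samples, uniformly sampled.
#' @param sampling_rate Samples per second.
#' @param threshold_fraction Threshold as a fraction of (max - min), in (0, 1).
#' @param debounce_window Seconds; merge/discard scale.
#' @return data.frame with columns `onset`, `offset` (seconds, 0-based from
#'   the first sample); zero rows for a flat trace.
#' @export
detect_contact_intervals <- function(values, sampling_rate,
                                     threshold_fraction = 0.2,
                                     debounce_window = 0.05) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_config("threshold_fraction must lie strictly between 0 and 1")
  }
  if (sampling_rate <= 0) stop_config("sampling_rate must be positive")
  empty <- data.frame(onset = numeric(), offset = numeric())
  if (length(values) == 0L) return(empty)
  rng <- range(values)
  if (diff(rng) == 0) return(empty)  # constant trace: no contacts
  thr <- rng[1] + threshold_fraction * diff(rng)
  above <- values > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty)

  dt <- 1 / sampling_rate
  # merge runs separated by gaps shorter than the debounce window
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt
      if (gap < debounce_window) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  dur <- (merged$end - merged$start) * dt
  merged <- merged[dur >= debounce_window, , drop = FALSE]
  data.frame(onset = (merged$start - 1L) * dt,
             offset = (merged$end - 1L) * dt)
}

#' Detect contact intervals for every channel of an FSR trace set
#'
#' @param traces An `fsr_traces` object (long data.frame with a
#'   `sampling_rate` attribute) as produced by [synthesize_fsr_traces()]
#'   or [read_fsr_csv()].
#' @inheritParams detect_contact_intervals
#' @return Nested list: `contacts[[leg]][[channel]]` interval data.frames.
#' @export
detect_all_contacts <- function(traces, threshold_fraction = 0.2,
                                debounce_window = 0.05) {
  fs <- attr(traces, "sampling_rate")
  if (is.null(fs)) stop_schema("traces lack a sampling_rate attribute")
  out <- list()
  for (lg in unique(traces$leg)) {
    out[[lg]] <- list()
    for (ch in unique(traces$channel[traces$leg == lg])) {
      sub <- traces[traces$leg == lg & traces$channel == ch, ]
      sub <- sub[order(sub$time_s), ]
      iv <- detect_contact_intervals(sub$value, fs, threshold_fraction,
                                     debounce_window)
      # re-anchor to the channel's own time axis
      if (nrow(iv)) {
        iv$onset <- iv$onset + sub$time_s[1]
        iv$offset <- iv$offset + sub$time_s[1]
      }
      out[[lg]][[ch]] <- iv
    }
  }
  out
}

#' Derive heel-strike and toe-off events from per-channel contacts
#'
#' Per footfall, heel-strike is the earliest onset among the two heel
#' channels and toe-off the latest offset among all three channels, i.e.
#' the first and last instants the foot contacts the floor. Footfalls with
#' heel contact but no overlapping toe contact are flagged and dropped
#' with a warning. The returned events strictly alternate heel-strike /
#' toe-off.
#'
#' @param contacts_by_channel Named list of interval data.frames covering
#'   `toe`, `lateral_heel`, `medial_heel`.
#' @param leg Leg identifier carried into the events.
#' @return data.frame with columns `leg`, `event_type`, `time_s`, sorted.
#' @export
derive_gait_events <- function(contacts_by_channel, leg) {
  need <- c("toe", "lateral_heel", "medial_heel")
  if (!all(need %in% names(contacts_by_channel))) {
    stop_schema("contacts must cover channels: ", paste(need, collapse = ", "))
  }
  heel <- rbind(contacts_by_channel$lateral_heel,
                contacts_by_channel$medial_heel)
  toe <- contacts_by_channel$toe
  empty <- data.frame(leg = character(), event_type = character(),
                      time_s = numeric(), stringsAsFactors = FALSE)
  if (nrow(heel) == 0L) return(empty)
  heel <- heel[order(heel$onset), ]

  # group heel intervals into footfalls: overlapping/adjacent heel contacts
  # belong to one footfall (the two heel sensors fire almost together)
  foot_on <- foot_off <- numeric(0)
  cur_on <- heel$onset[1]; cur_off <- heel$offset[1]
  if (nrow(heel) > 1L) {
    for (i in 2:nrow(heel)) {
      if (heel$onset[i] <= cur_off) {
        cur_off <- max(cur_off, heel$offset[i])
      } else {
        foot_on <- c(foot_on, cur_on); foot_off <- c(foot_off, cur_off)
        cur_on <- heel$onset[i]; cur_off <- heel$offset[i]
      }
    }
  }
  foot_on <- c(foot_on, cur_on); foot_off <- c(foot_off, cur_off)

  hs <- to <- numeric(0)
  dropped <- 0L
  next_floor <- -Inf
  for (i in seq_along(foot_on)) {
    # toe contact overlapping or directly following this heel contact
    cand <- toe[toe$offset > foot_on[i] &
                  (i == length(foot_on) | toe$onset < c(foot_on, Inf)[i + 1]), ]
    if (nrow(cand) == 0L) { dropped <- dropped + 1L; next }
    t_off <- max(foot_off[i], max(cand$offset))
    if (foot_on[i] <= next_floor) { dropped <- dropped + 1L; next }
    hs <- c(hs, foot_on[i]); to <- c(to, t_off)
    next_floor <- t_off
  }
  if (dropped > 0L) {
    warn_gd(dropped, " footfall(s) without matching toe contact excluded")
  }
  if (length(hs) == 0L) return(empty)
  ev <- data.frame(leg = leg,
                   event_type = rep(c("heel_strike", "toe_off"), length(hs)),
                   time_s = as.vector(rbind(hs, to)),
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Extract both-leg gait events from FSR traces
#'
#' Convenience composition of [detect_all_contacts()] and
#' [derive_gait_events()].
#'
#' @inheritParams detect_all_contacts
#' @return data.frame of events for both legs, sorted by time.
#' @export
events_from_traces <- function(traces, threshold_fraction = 0.2,
                               debounce_window = 0.05) {
  contacts <- detect_all_contacts(traces, threshold_fraction, debounce_window)
  ev <- do.call(rbind, lapply(names(contacts), function(lg) {
    derive_gait_events(contacts[[lg]], lg)
  }))
  if (is.null(ev)) {
    ev <- data.frame(leg = character(), event_type = character(),
                     time_s = numeric(), stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ev
}

#' Segment one leg's events into gait cycles
#'
#' A cycle runs heel-strike -> toe-off -> next heel-strike of the same leg.
#' Stance time is heel-strike to toe-off, swing time toe-off to the next
#' heel-strike, so stance + swing equals the cycle time exactly. A trailing
#' incomplete cycle is discarded.
#'
#' @param events data.frame of one leg's events (`event_type`, `time_s`).
#' @return data.frame with one row per cycle: `leg`, `heel_strike`,
#'   `toe_off`, `next_heel_strike`, `stance_time`, `swing_time`,
#'   `cycle_time`. Empty (with a warning) when fewer than two heel-strikes
#'   are present.
#' @export
segment_gait_cycles <- function(events) {
  empty <- data.frame(leg = character(), heel_strike = numeric(),
                      toe_off = numeric(), next_heel_strike = numeric(),
                      stance_time = numeric(), swing_time = numeric(),
                      cycle_time = numeric(), stringsAsFactors = FALSE)
  if (nrow(events) == 0L) {
    warn_gd("no events to segment")
    return(empty)
  }
  if (length(unique(events$leg)) > 1L) {
    stop_invalid("segment_gait_cycles expects events of a single leg")
  }
  events <- events[order(events$time_s), ]
  hs <- events$time_s[events$event_type == "heel_strike"]
  to <- events$time_s[events$event_type == "toe_off"]
  if (length(hs) < 2L) {
    warn_gd("fewer than 2 heel-strikes: no complete gait cycle")
    return(empty)
  }
  cyc <- list()
  for (i in seq_len(length(hs) - 1L)) {
    t_off <- to[to > hs[i] & to < hs[i + 1]]
    if (length(t_off) != 1L) next  # malformed alternation within this cycle
    cyc[[length(cyc) + 1L]] <- data.frame(
      leg = events$leg[1], heel_strike = hs[i], toe_off = t_off,
      next_heel_strike = hs[i + 1],
      stance_time = t_off - hs[i],
      swing_time = hs[i + 1] - t_off,
      cycle_time = hs[i + 1] - hs[i],
      stringsAsFactors = FALSE)
  }
  if (length(cyc) == 0L) return(empty)
  out <- do.call(rbind, cyc)
  rownames(out) <- NULL
  out
}

#' Validate a both-leg gait event stream
#'
#' Report-only check for ordering violations, missing heel-strike/toe-off
#' alternation, and duplicate timestamps per leg. The input is never
#' modified.
#'
#' @param events data.frame with `leg`, `event_type`, `time_s`.
#' @return data.frame of issues (`leg`, `issue`, `time_s`); zero rows when
#'   the stream is well formed.
#' @export
validate_event_stream <- function(events) {
  issues <- list()
  add <- function(leg, issue, t) {
    issues[[length(issues) + 1L]] <<- data.frame(
      leg = leg, issue = issue, time_s = t, stringsAsFactors = FALSE)
  }
  if (is.unsorted(events$time_s)) {
    add("both", "non-monotone time", events$time_s[which(diff(events$time_s) < 0)[1] + 1L])
  }
  for (lg in unique(events$leg)) {
    le <- events[events$leg == lg, ]
    le <- le[order(le$time_s), ]
    if (anyDuplicated(le$time_s)) {
      add(lg, "duplicate timestamp", le$time_s[duplicated(le$time_s)][1])
    }
    et <- le$event_type
    if (length(et) > 1L) {
      same <- which(et[-1] == et[-length(et)])
      for (i in same) {
        miss <- if (et[i] == "heel_strike") "missing toe-off" else "missing heel-strike"
        add(lg, miss, le$time_s[i + 1L])
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(leg = character(), issue = character(),
                      time_s = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
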