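# CSV readers/writers for the pipeline's documented schemas. All files are
# plain comma-separated text with headers; times in seconds, fields in V/m.

#' Write walk-trial events to CSV
#'
#' Schema: `subject`, `session`, `montage`, `leg`, `event_type`, `time_s`,
#' plus the trial context columns `distance`, `height`, `affected_side`
#' (repeated per row) so trials round-trip through [load_event_table()].
#'
#' @param trials A `walk_trial` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(trials, path) {
  if (inherits(trials, "walk_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    if (nrow(tr$events) == 0L) return(NULL)
    data.frame(subject = tr$subject_id, session = tr$session,
               montage = tr$montage, leg = tr$events$leg,
               event_type = tr$events$event_type,
               time_s = tr$events$time_s,
               distance = tr$distance, height = tr$height,
               affected_side = tr$affected_side,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(), session = character(),
                      montage = character(), leg = character(),
                      event_type = character(), time_s = numeric(),
                      distance = numeric(), height = numeric(),
                      affected_side = character())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load walk trials from an events CSV
#'
#' Groups rows by subject/session/montage into `walk_trial` objects and
#' validates each event stream. Rows with unparseable or missing fields
#' are dropped with a warning naming their line numbers.
#'
#' @param path Events CSV as written by [write_events_csv()].
#' @return List of `walk_trial` objects (possibly empty, with a warning).
#' @export
load_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "session", "montage", "leg", "event_type", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema("events CSV missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warn_gd("empty events file: ", path)
    return(list())
  }
  ok <- !is.na(suppressWarnings(as.numeric(df$time_s))) &
    df$leg %in% c("left", "right") &
    df$event_type %in% c("heel_strike", "toe_off")
  if (any(!ok)) {
    warn_gd("dropping ", sum(!ok), " malformed row(s) at line(s): ",
            paste(utils::head(which(!ok) + 1L, 10L), collapse = ", "))
    df <- df[ok, , drop = FALSE]
  }
  df$time_s <- as.numeric(df$time_s)
  keys <- unique(df[, c("subject", "session", "montage")])
  trials <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$subject == keys$subject[i] & df$session == keys$session[i] &
                df$montage == keys$montage[i], , drop = FALSE]
    sub <- sub[order(sub$time_s), ]
    events <- data.frame(leg = sub$leg, event_type = sub$event_type,
                         time_s = sub$time_s, stringsAsFactors = FALSE)
    rownames(events) <- NULL
    affected <- if ("affected_side" %in% names(sub)) sub$affected_side[1] else "left"
    tr <- structure(list(
      events = events,
      distance = if ("distance" %in% names(sub)) sub$distance[1] else NA_real_,
      duration = max(sub$time_s) - min(sub$time_s),
      height = if ("height" %in% names(sub)) sub$height[1] else NA_real_,
      affected_side = affected,
      unaffected_side = setdiff(c("left", "right"), affected),
      subject_id = keys$subject[i], session = keys$session[i],
      montage = keys$montage[i]), class = "walk_trial")
    trials[[paste(keys$subject[i], keys$session[i], keys$montage[i],
                  sep = "/")]] <- tr
  }
  trials
}

#' Write FSR traces to CSV
#'
#' Schema: `subject`, `leg`, `channel`, `time_s`, `value`; the sampling
#' rate is stored in a `sampling_rate` column (constant).
#'
#' @param traces An `fsr_traces` object.
#' @param path Output file path.
#' @param subject Subject identifier column value.
#' @return `path`, invisibly.
#' @export
write_fsr_csv <- function(traces, path, subject = "S01") {
  out <- cbind(data.frame(subject = rep(subject, nrow(traces)),
                          stringsAsFactors = FALSE),
               as.data.frame(traces),
               data.frame(sampling_rate = rep(attr(traces, "sampling_rate"),
                                              nrow(traces))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read FSR traces from CSV
#'
#' @param path FSR CSV as written by [write_fsr_csv()].
#' @return An `fsr_traces` object.
#' @export
read_fsr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leg", "channel", "time_s", "value", "sampling_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_schema("FSR CSV missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  fs <- unique(df$sampling_rate)
  if (length(fs) != 1L) stop_schema("FSR CSV mixes sampling rates")
  out <- df[, c("leg", "channel", "time_s", "value")]
  structure(out, class = c("fsr_traces", "data.frame"), sampling_rate = fs)
}

#' Write / read a lobular E-field matrix CSV
#'
#' Schema: `subject`, `montage`, one numeric column per lobule label.
#'
#' @param efield E-field data.frame.
#' @param path File path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_efield_csv <- function(efield, path) {
  utils::write.csv(efield, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_efield_csv
#' @export
read_efield_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject", "montage") %in% names(df))) {
    stop_schema("E-field CSV must have subject and montage columns")
  }
  lob <- setdiff(names(df), c("subject", "montage"))
  if (any(vapply(df[lob], function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    stop_schema("E-field values must be non-negative")
  }
  df
}
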