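#' Unwrap modulo-360 orientation jumps
#'
#' Removes artificial jumps larger than 180 degrees between consecutive
#' frames (wrap-around of a circular readout) by adding the appropriate
#' multiple of 360.
#'
#' @param deg Orientation in degrees.
#' @return Unwrapped orientation.
#' @export
unwrap_orientation <- function(deg) {
  d <- diff(deg)
  corr <- -360 * cumsum(round(d / 360))
  c(deg[1], deg[-1] + corr)
}

#' Centered rolling variance of an orientation trace
#'
#' Population variance (divide by the number of frames in the window) of the
#' orientation within a centered time window, truncated at the trace edges.
#' The population estimator is used because the detection thresholds are
#' empirical and the estimator is stable for the small windows involved; the
#' choice only rescales thresholds slightly.
#'
#' @param trace Data frame with `time_s` and `orientation_deg`, or a numeric
#'   vector of orientations (then `frame_rate` is required).
#' @param window Window length (s, default 0.05); must span at least 2
#'   frames.
#' @param frame_rate Sampling rate; inferred from `time_s` when absent.
#' @return Per-frame variance (deg^2).
#' @export
rolling_variance <- function(trace, window = 0.05, frame_rate = NULL) {
  if (is.data.frame(trace)) {
    x <- trace$orientation_deg
    if (is.null(frame_rate)) {
      if (nrow(trace) < 2) stop("trace must contain at least 2 frames")
      frame_rate <- 1 / stats::median(diff(trace$time_s))
    }
  } else {
    x <- as.numeric(trace)
    if (is.null(frame_rate)) stop("frame_rate required for a bare vector")
  }
  n <- length(x)
  if (n == 0) stop("empty trace")
  k <- max(2L, as.integer(round(window * frame_rate)))
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  m <- hi - lo + 1L
  s1 <- cs1[hi + 1L] - cs1[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  pmax(s2 / m - (s1 / m)^2, 0)
}

# Hysteresis segmentation of a variance trace: an event opens at the first
# frame of a run above start_thresh sustained at least start_min_dur, and
# closes at the first frame of a run below end_thresh sustained at least
# end_min_dur (an open event is closed at the last frame). Run durations are
# counted as frames / fs.
variance_hysteresis <- function(v, fs, start_thresh = 1, end_thresh = 0.5,
                                start_min_dur = 0.02, end_min_dur = 0.05) {
  n_start <- max(1L, ceiling(start_min_dur * fs - 1e-9))
  n_end <- max(1L, ceiling(end_min_dur * fs - 1e-9))
  state <- ifelse(v > start_thresh, 2L, ifelse(v < end_thresh, 0L, 1L))
  runs <- rle(state)
  ends_at <- cumsum(runs$lengths)
  starts_at <- ends_at - runs$lengths + 1L
  in_event <- FALSE
  ev_start <- integer(0); ev_end <- integer(0)
  cur_start <- NA_integer_
  for (s in seq_along(runs$lengths)) {
    if (!in_event) {
      if (runs$values[s] == 2L && runs$lengths[s] >= n_start) {
        in_event <- TRUE
        cur_start <- starts_at[s]
      }
    } else {
      if (runs$values[s] == 0L && runs$lengths[s] >= n_end) {
        ev_start <- c(ev_start, cur_start)
        ev_end <- c(ev_end, starts_at[s])
        in_event <- FALSE
      }
    }
  }
  if (in_event) {
    ev_start <- c(ev_start, cur_start)
    ev_end <- c(ev_end, length(v))
  }
  list(start = ev_start, end = ev_end)
}

#' Detect swim events from an orientation trace
#'
#' Hysteresis detection on the rolling orientation variance: an event starts
#' when the variance exceeds `start_thresh` (1 deg^2) for at least
#' `start_min_dur` (20 ms), and ends when it falls below `end_thresh`
#' (0.5 deg^2) for at least `end_min_dur` (50 ms); the event end is placed
#' at the first frame of that quiet period. The inter-swim interval is the
#' time from the end of the previous event to the start of the current one
#' (the first event has `NA`). An event still open at the end of the trace
#' is closed at the last frame.
#'
#' The orientation change is measured between the event boundaries expanded
#' by one variance window on each side (clipped at the midpoint to
#' neighboring events): for small turns the variance thresholds only
#' trigger on the steep middle of the reorientation, and the expansion
#' recovers the slow head and tail of the turn that the hysteresis clips.
#'
#' @param trace Data frame with `time_s`, `orientation_deg` and optionally
#'   `coherence`, `direction`, `phase`, `trial_id`, `t_stim_s`, `x_cm`,
#'   `y_cm`, `area_px`.
#' @param window,start_thresh,end_thresh,start_min_dur,end_min_dur Detection
#'   settings (defaults as above).
#' @return Data frame of swim events: `start_s`, `end_s`, `duration_s`,
#'   `orientation_change_deg`, `isi_s`, plus stimulus annotation, and
#'   `mean_speed_cmps` / `area_px` when position / area columns are present.
#' @export
detect_swims <- function(trace, window = 0.05, start_thresh = 1,
                         end_thresh = 0.5, start_min_dur = 0.02,
                         end_min_dur = 0.05) {
  stopifnot(is.data.frame(trace), all(c("time_s", "orientation_deg") %in%
                                        names(trace)))
  if (nrow(trace) < 2) stop("trace must contain at least 2 frames")
  fs <- 1 / stats::median(diff(trace$time_s))
  v <- rolling_variance(trace, window = window, frame_rate = fs)
  bounds <- variance_hysteresis(v, fs, start_thresh, end_thresh,
                                start_min_dur, end_min_dur)
  ev_start <- bounds$start
  ev_end <- bounds$end
  if (length(ev_start) == 0) {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0),
                      orientation_change_deg = numeric(0), isi_s = numeric(0))
    return(out)
  }
  k <- max(2L, as.integer(round(window * fs)))
  n <- nrow(trace)
  ne <- length(ev_start)
  meas_a <- pmax(ev_start - k, 1L)
  meas_b <- pmin(ev_end + k, n)
  if (ne > 1) {
    mid <- floor((ev_end[-ne] + ev_start[-1]) / 2)
    meas_a[-1] <- pmax(meas_a[-1], mid)
    meas_b[-ne] <- pmin(meas_b[-ne], mid)
  }
  out <- data.frame(
    start_s = trace$time_s[ev_start],
    end_s = trace$time_s[ev_end],
    duration_s = trace$time_s[ev_end] - trace$time_s[ev_start],
    orientation_change_deg = trace$orientation_deg[meas_b] -
      trace$orientation_deg[meas_a])
  out$isi_s <- c(NA_real_, out$start_s[-1] - out$end_s[-nrow(out)])
  for (col in c("coherence", "direction", "phase", "trial_id", "t_stim_s"))
    if (col %in% names(trace)) out[[col]] <- trace[[col]][ev_start]
  if (all(c("x_cm", "y_cm") %in% names(trace))) {
    step <- sqrt(diff(trace$x_cm)^2 + diff(trace$y_cm)^2)
    cpath <- c(0, cumsum(step))
    out$mean_speed_cmps <- (cpath[ev_end] - cpath[ev_start]) / out$duration_s
  }
  if ("area_px" %in% names(trace)) {
    out$area_px <- vapply(seq_along(ev_start), function(k)
      max(trace$area_px[ev_start[k]:ev_end[k]]), numeric(1))
  }
  out
}

#' Label a turn as correct, incorrect or forward-excluded
#'
#' Turns toward the coherent-motion direction are `"correct"`, turns against
#' it `"incorrect"`, and straight swims within the `+/-band` degrees
#' exclusion band `"forward-excluded"`. The sign convention is that a
#' positive orientation change is a leftward (counterclockwise) turn, so a
#' positive change under a `"left"` stimulus is motion-following. During 0%
#' coherence (or rest), labels are assigned relative to the trial's nominal
#' randomly assigned direction, which is counterbalanced across trials.
#'
#' @param orientation_change Signed turn angle(s) in degrees.
#' @param direction Stimulus direction(s), `"left"` or `"right"`.
#' @param band Half-width of the forward-swim exclusion band (degrees,
#'   default 3; the band is inclusive).
#' @return Character vector of labels.
#' @examples
#' label_event(c(20, 2, -3.01), "left")
#' @export
label_event <- function(orientation_change, direction, band = 3) {
  n <- max(length(orientation_change), length(direction))
  oc <- rep_len(orientation_change, n)
  dir <- rep_len(direction, n)
  if (any(is.na(dir)) || !all(dir %in% c("left", "right")))
    stop("stimulus direction must be 'left' or 'right' for every event")
  signed <- ifelse(dir == "left", oc, -oc)  # positive = motion-following
  ifelse(abs(oc) <= band, "forward-excluded",
         ifelse(signed > 0, "correct", "incorrect"))
}

#' Label a swim-event table
#'
#' Applies [label_event()] to the `orientation_change_deg` and `direction`
#' columns of a swim-event table.
#'
#' @param events Swim-event table from [detect_swims()].
#' @param band Exclusion band (degrees).
#' @return The table with a `label` column added.
#' @export
label_swims <- function(events, band = 3) {
  stopifnot(all(c("orientation_change_deg", "direction") %in% names(events)))
  events$label <- label_event(events$orientation_change_deg,
                              events$direction, band = band)
  events
}

#' Quality-control filtering of swim events
#'
#' Applies the tracking-error filters to a single animal's swim events:
#'
#' * events are flagged when the inter-swim interval reaches 30 s
#'   (`long_isi`), the mean swim speed reaches 6 cm/s (`fast_swim`), the
#'   contour area reaches 2000 px (`big_area`), or the absolute turn angle
#'   exceeds 150 degrees (`big_turn`);
#' * a trial is dropped when more than 5% of its swims are flagged;
#' * the animal is dropped when its average swim rate is below
#'   0.375 swims/s.
#'
#' Criteria whose columns are absent (speed, area) or whose inputs are
#' missing (total observation time for the rate) are skipped and noted in
#' the report rather than failing.
#'
#' @param events Swim-event table (columns `isi_s`,
#'   `orientation_change_deg`, optionally `mean_speed_cmps`, `area_px`,
#'   `trial_id`).
#' @param total_time_s Total observation time of the animal (s), for the
#'   swim-rate criterion.
#' @param isi_max,speed_max,area_max,turn_max,trial_flag_frac,min_rate
#'   Thresholds (defaults as above).
#' @return List with `events` (retained rows), `report` (a `qc_report`:
#'   per-event flag data frame, dropped trials, fish drop flag, skipped
#'   criteria, counts).
#' @export
qc_filter <- function(events, total_time_s = NULL, isi_max = 30,
                      speed_max = 6, area_max = 2000, turn_max = 150,
                      trial_flag_frac = 0.05, min_rate = 0.375) {
  n <- nrow(events)
  skipped <- character(0)
  flags <- data.frame(
    long_isi = !is.na(events$isi_s) & events$isi_s >= isi_max,
    big_turn = abs(events$orientation_change_deg) > turn_max)
  if ("mean_speed_cmps" %in% names(events)) {
    flags$fast_swim <- !is.na(events$mean_speed_cmps) &
      events$mean_speed_cmps >= speed_max
  } else skipped <- c(skipped, "fast_swim")
  if ("area_px" %in% names(events)) {
    flags$big_area <- !is.na(events$area_px) & events$area_px >= area_max
  } else skipped <- c(skipped, "big_area")
  any_flag <- if (n) Reduce(`|`, flags) else logical(0)

  dropped_trials <- integer(0)
  if ("trial_id" %in% names(events) && n) {
    frac <- tapply(any_flag, events$trial_id, mean)
    dropped_trials <- as.integer(names(frac)[frac > trial_flag_frac])
  }
  fish_dropped <- FALSE
  rate <- NA_real_
  if (!is.null(total_time_s) && total_time_s > 0) {
    rate <- n / total_time_s
    fish_dropped <- rate < min_rate
  } else skipped <- c(skipped, "swim_rate")

  keep <- !any_flag
  if (length(dropped_trials) && "trial_id" %in% names(events))
    keep <- keep & !(events$trial_id %in% dropped_trials)
  retained <- if (fish_dropped) events[0, , drop = FALSE]
              else events[keep, , drop = FALSE]
  n_forward <- if ("label" %in% names(events))
    sum(retained$label == "forward-excluded") else NA_integer_
  report <- structure(list(flags = flags, n_events = n,
                           n_flagged = sum(any_flag),
                           dropped_trials = dropped_trials,
                           fish_dropped = fish_dropped, swim_rate = rate,
                           skipped_criteria = skipped,
                           n_forward_excluded = n_forward),
                      class = "qc_report")
  list(events = retained, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_events, "events,", x$n_flagged, "flagged\n")
  if (length(x$dropped_trials))
    cat("  dropped trials:", paste(x$dropped_trials, collapse = ", "), "\n")
  cat("  swim rate:", if (is.na(x$swim_rate)) "(not assessed)" else
    sprintf("%.3f swims/s", x$swim_rate),
    if (isTRUE(x$fish_dropped)) "-> animal dropped" else "", "\n")
  if (length(x$skipped_criteria))
    cat("  skipped criteria:", paste(x$skipped_criteria, collapse = ", "),
        "\n")
  invisible(x)
}

#' Read an orientation trace from CSV
#'
#' Expected columns: `time_s`, `orientation_deg`, and optionally `x_cm`,
#' `y_cm`, `coherence`, `direction`, `phase`, `trial_id`, `area_px`,
#' `t_stim_s`.
#'
#' @param file Path.
#' @return Data frame.
#' @export
read_orientation_trace <- function(file) {
  tr <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("time_s", "orientation_deg") %in% names(tr)))
    stop("trace must contain time_s and orientation_deg columns")
  tr
}
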