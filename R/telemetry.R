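#' Detection thresholds for the six aberrant driving behaviors
#'
#' Thresholds follow the fleet tachograph criteria: speeding is speed above
#' 87 km/h sustained for more than 90 s; abnormal stay is speed below 5 km/h
#' within a 50 m movement range for more than 5 min; hard acceleration is a
#' speed gain above 30 km/h between the 1st and 5th second of a 5-s window;
#' hard deceleration is a drop above 13 km/h per second for 3 consecutive
#' seconds; driving overtime is continuous driving beyond the company limit
#' (default 4 h); excessive rotation is speed below 85 km/h with engine rpm
#' above 1500 for 3 consecutive seconds.
#'
#' @param speed_limit_kmh,speeding_min_s Speeding threshold and the duration
#'   (seconds) a violation must exceed.
#' @param stay_speed_kmh,stay_range_m,stay_min_s Abnormal-stay speed ceiling,
#'   positional-range ceiling, and duration floor.
#' @param accel_diff_kmh Speed gain across a 5-s window that flags hard
#'   acceleration.
#' @param decel_drop_kmh,decel_consec_s Per-second drop and run length for
#'   hard deceleration.
#' @param overtime_max_s Continuous-driving ceiling (seconds; default 4 h).
#' @param rotation_speed_kmh,rotation_rpm,rotation_consec_s Excessive-rotation
#'   speed ceiling, rpm floor, and run length.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(speed_limit_kmh = 87, speeding_min_s = 90,
                        stay_speed_kmh = 5, stay_range_m = 50, stay_min_s = 300,
                        accel_diff_kmh = 30,
                        decel_drop_kmh = 13, decel_consec_s = 3,
                        overtime_max_s = 4 * 3600,
                        rotation_speed_kmh = 85, rotation_rpm = 1500,
                        rotation_consec_s = 3) {
  structure(list(speed_limit_kmh = speed_limit_kmh, speeding_min_s = speeding_min_s,
                 stay_speed_kmh = stay_speed_kmh, stay_range_m = stay_range_m,
                 stay_min_s = stay_min_s, accel_diff_kmh = accel_diff_kmh,
                 decel_drop_kmh = decel_drop_kmh, decel_consec_s = decel_consec_s,
                 overtime_max_s = overtime_max_s,
                 rotation_speed_kmh = rotation_speed_kmh,
                 rotation_rpm = rotation_rpm,
                 rotation_consec_s = rotation_consec_s),
            class = "rule_config")
}

validate_trace <- function(trace) {
  need <- c("timestamp", "speed_kmh", "rpm", "x_m", "y_m")
  if (!all(need %in% names(trace)))
    stop_input("trace must have columns: %s", paste(need, collapse = ", "))
  if (nrow(trace) == 0) stop_input("empty trace")
  if (is.unsorted(trace$timestamp, strictly = TRUE))
    stop_input("trace timestamps must be strictly increasing")
  invisible(trace)
}

# Maximal runs of TRUE in a logical vector -> data.frame(start_idx, end_idx).
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

#' Detect aberrant driving events in a per-second telemetry trace
#'
#' Applies the six tachograph rules (see [rule_config()]) to a 1 Hz trace.
#' Each rule fires once per maximal contiguous violating episode; episode
#' duration is the number of 1-s samples it spans. Hard-acceleration windows
#' that overlap are merged into one episode. The abnormal-stay positional
#' range is the maximal pairwise planar distance within the episode.
#'
#' @param trace Data frame with columns `timestamp` (s, strictly increasing,
#'   1 s apart within a session), `speed_kmh`, `rpm`, `x_m`, `y_m`, and
#'   optionally `driver_id`.
#' @param rules A [rule_config()].
#' @return Data frame with `driver_id`, `behavior`, `start_time`, `end_time`
#'   (one row per episode; zero rows when nothing fires).
#' @export
detect_events <- function(trace, rules = rule_config()) {
  validate_trace(trace)
  # a timestamp jump marks a session boundary: rules never span the gap
  seg <- cumsum(c(1L, diff(trace$timestamp) != 1))
  if (seg[length(seg)] > 1L) {
    parts <- lapply(split(seq_along(seg), seg),
                    function(idx) detect_events_session(trace[idx, , drop = FALSE], rules))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out[order(out$start_time), , drop = FALSE])
  }
  detect_events_session(trace, rules)
}

detect_events_session <- function(trace, rules) {
  id <- if ("driver_id" %in% names(trace)) trace$driver_id[1] else "unknown"
  ts <- trace$timestamp
  sp <- trace$speed_kmh
  rpm <- trace$rpm
  ev <- list()
  add <- function(behavior, runs) {
    if (nrow(runs) == 0) return()
    ev[[length(ev) + 1L]] <<- data.frame(
      driver_id = id, behavior = behavior,
      start_time = ts[runs$start_idx], end_time = ts[runs$end_idx])
  }

  # (1) speeding: runs of speed > limit lasting more than speeding_min_s samples
  r <- runs_of(sp > rules$speed_limit_kmh)
  add("exceeding_speed_limit", r[r$end_idx - r$start_idx + 1L > rules$speeding_min_s, ])

  # (2) abnormal stay: slow runs long enough and spatially confined
  r <- runs_of(sp < rules$stay_speed_kmh)
  r <- r[r$end_idx - r$start_idx + 1L > rules$stay_min_s, ]
  if (nrow(r)) {
    conf <- vapply(seq_len(nrow(r)), function(i) {
      idx <- r$start_idx[i]:r$end_idx[i]
      xr <- range(trace$x_m[idx]); yr <- range(trace$y_m[idx])
      # cheap pre-check via bounding box, exact max pairwise distance if near
      bbox_diag <- sqrt(diff(xr)^2 + diff(yr)^2)
      if (bbox_diag < rules$stay_range_m) return(TRUE)
      if (max(diff(xr), diff(yr)) >= rules$stay_range_m) return(FALSE)
      d <- stats::dist(cbind(trace$x_m[idx], trace$y_m[idx]))
      max(d) < rules$stay_range_m
    }, logical(1))
    add("abnormal_stay", r[conf, ])
  }

  # (3) hard acceleration: speed[t+4] - speed[t] > diff; overlapping windows merged
  n <- length(sp)
  if (n >= 5) {
    win <- sp[5:n] - sp[1:(n - 4)] > rules$accel_diff_kmh
    covered <- rep(FALSE, n)
    for (t in which(win)) covered[t:(t + 4L)] <- TRUE
    add("hard_acceleration", runs_of(covered))
  }

  # (4) hard deceleration: per-second drop > threshold for >= consec steps
  if (n >= 2) {
    drop <- sp[-n] - sp[-1] > rules$decel_drop_kmh   # step t -> t+1
    r <- runs_of(drop)
    r <- r[r$end_idx - r$start_idx + 1L >= rules$decel_consec_s, ]
    if (nrow(r)) r$end_idx <- r$end_idx + 1L  # include the final sample of the run
    add("hard_deceleration", r)
  }

  # (5) driving overtime: continuous driving (speed > 0) beyond the cap
  r <- runs_of(sp > 0)
  add("driving_overtime", r[r$end_idx - r$start_idx + 1L > rules$overtime_max_s, ])

  # (6) excessive rotation: low speed with high rpm for >= consec samples
  r <- runs_of(sp < rules$rotation_speed_kmh & rpm > rules$rotation_rpm)
  add("excessive_rotation_speed",
      r[r$end_idx - r$start_idx + 1L >= rules$rotation_consec_s, ])

  if (length(ev) == 0)
    return(data.frame(driver_id = character(), behavior = character(),
                      start_time = numeric(), end_time = numeric()))
  out <- do.call(rbind, ev)
  out[order(out$behavior, out$start_time), , drop = FALSE]
}

#' Tally detected events into per-driver behavior counts
#'
#' @param events Event data frame as returned by [detect_events()] (possibly
#'   concatenated over drivers).
#' @param exposure_hours Observation-window driving hours (scalar, or named by
#'   driver).
#' @return Data frame with `driver_id`, one count column per behavior in
#'   canonical order, and `exposure_hours`.
#' @export
counts_from_events <- function(events, exposure_hours) {
  bn <- behavior_names()
  ids <- unique(events$driver_id)
  if (length(ids) == 0) ids <- "unknown"
  tab <- table(factor(events$driver_id, levels = ids),
               factor(events$behavior, levels = bn))
  out <- data.frame(driver_id = ids, as.data.frame.matrix(tab),
                    check.names = FALSE, row.names = NULL)
  out$exposure_hours <- if (!is.null(names(exposure_hours)))
    as.numeric(exposure_hours[ids]) else exposure_hours
  out
}

#' Synthesize a compliant baseline trace with optional injected episodes
#'
#' Builds a 1 Hz trace of steady highway driving (default 80 km/h, 1200 rpm,
#' straight-line motion) that violates none of the default rules, for testing
#' event detection. Episodes are injected by overwriting spans of the
#' baseline.
#'
#' @param duration_s Trace length in seconds.
#' @param base_speed_kmh,base_rpm Baseline speed and rpm.
#' @param driver_id Driver label.
#' @return Trace data frame accepted by [detect_events()].
#' @export
baseline_trace <- function(duration_s = 3600, base_speed_kmh = 80,
                           base_rpm = 1200, driver_id = "T1") {
  t <- seq_len(duration_s)
  mps <- base_speed_kmh / 3.6
  data.frame(driver_id = driver_id, timestamp = t,
             speed_kmh = rep(base_speed_kmh, duration_s),
             rpm = rep(base_rpm, duration_s),
             x_m = t * mps, y_m = 0)
}
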