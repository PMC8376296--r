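wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

interp_gaps <- function(v, max_gap) {
  # linear interpolation of interior NA runs of length <= max_gap
  n <- length(v)
  isna <- is.na(v)
  if (!any(isna) || all(isna)) return(v)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next          # edge gaps stay missing
    if (r$lengths[k] > max_gap) next
    v[s:e] <- v[s - 1L] + (v[e + 1L] - v[s - 1L]) *
      (seq_len(r$lengths[k])) / (r$lengths[k] + 1L)
  }
  v
}

#' Head pose from two tracked LEDs
#'
#' Head position is the midpoint of the two LEDs; heading is the direction of
#' the vector from the rear LED to the front LED, wrapped to (-pi, pi].
#' Tracking dropouts of at most `max_gap` frames are filled by linear
#' interpolation per LED coordinate; longer gaps (and edge gaps) remain
#' invalid.
#'
#' @param tracking tracking data frame (columns `red_x_mm`, `red_y_mm`,
#'   `green_x_mm`, `green_y_mm`) or a `vp_session`.
#' @param front_led `"red"` or `"green"`.
#' @param max_gap maximum interpolated gap, frames (default 5).
#' @param frame_rate frames per second (default 30; taken from the manifest
#'   when a session is supplied).
#' @return object of class `vp_pose`: list with `position` (n x 2, mm),
#'   `heading` (radians), `valid`, `frame_rate`.
#' @export
head_pose <- function(tracking, front_led = "red", max_gap = 5L,
                      frame_rate = 30) {
  if (inherits(tracking, "vp_session")) {
    frame_rate <- tracking$manifest$frame_rate_hz
    tracking <- tracking$tracking
  }
  stopifnot(front_led %in% c("red", "green"))
  cols <- c("red_x_mm", "red_y_mm", "green_x_mm", "green_y_mm")
  m <- vapply(cols, function(cl) interp_gaps(tracking[[cl]], max_gap),
              numeric(nrow(tracking)))
  red <- m[, 1:2, drop = FALSE]
  green <- m[, 3:4, drop = FALSE]
  front <- if (front_led == "red") red else green
  rear <- if (front_led == "red") green else red
  valid <- stats::complete.cases(m)
  pos <- (front + rear) / 2
  dvec <- front - rear
  heading <- wrap_angle(atan2(dvec[, 2L], dvec[, 1L]))
  pos[!valid, ] <- NA_real_
  heading[!valid] <- NA_real_
  structure(list(position = pos, heading = heading, valid = valid,
                 frame_rate = frame_rate),
            class = "vp_pose")
}

#' Per-frame kinematic series relative to the operant lever
#'
#' Computes, by first differences at the tracking frame rate: speed (mm/s),
#' radial velocity toward the lever (mm/s, positive while approaching),
#' angular velocity of the head about the lever (rad/s, the rate of change of
#' the lever-centered polar angle of head position), and wrapped heading
#' increments (rad). Values are attributed to the later frame of each pair;
#' the first frame and frames adjacent to invalid pose are `NA`. A frame
#' exactly at the lever has undefined polar angle and yields `NA` angular
#' velocity for the adjacent steps.
#'
#' @param pose `vp_pose`.
#' @param lever_xy numeric length-2, lever position (mm).
#' @param frame_rate frames per second (defaults to `pose$frame_rate`).
#' @return data frame `speed_mm_s`, `radial_velocity_mm_s`,
#'   `angular_velocity_rad_s`, `heading_increment_rad`, `lever_distance_mm`.
#' @export
kinematic_series <- function(pose, lever_xy, frame_rate = pose$frame_rate) {
  p <- pose$position
  n <- nrow(p)
  stopifnot(n >= 2L)
  dx <- diff(p[, 1L]); dy <- diff(p[, 2L])
  speed <- c(NA_real_, sqrt(dx^2 + dy^2) * frame_rate)
  rx <- p[, 1L] - lever_xy[1L]; ry <- p[, 2L] - lever_xy[2L]
  dist <- sqrt(rx^2 + ry^2)
  radial <- c(NA_real_, -diff(dist) * frame_rate)
  theta <- atan2(ry, rx)
  theta[dist < 1e-9] <- NA_real_  # undefined polar angle at the lever
  ang <- c(NA_real_, wrap_angle(diff(theta)) * frame_rate)
  dhead <- c(NA_real_, wrap_angle(diff(pose$heading)))
  data.frame(speed_mm_s = speed, radial_velocity_mm_s = radial,
             angular_velocity_rad_s = ang, heading_increment_rad = dhead,
             lever_distance_mm = dist)
}

#' Movement features for one approach window
#'
#' Computes the trial-level locomotor feature vector over the window
#' `[start_t, end_t]`: summary statistics of speed, of radial velocity toward
#' the lever, and of the magnitude of angular velocity about the lever; move
#' duration; path length; latencies from window start to maximum speed and to
#' maximum (signed) acceleration; maximum perpendicular deviation of the path
#' from the straight start-to-end line; net (unwrapped cumulative) change in
#' heading; turn efficiency (cumulative absolute heading change divided by
#' the absolute net change, undefined when the net change is below 1e-3 rad);
#' and path efficiency (straight start-to-end distance over path length).
#'
#' @param pose `vp_pose`.
#' @param start_t,end_t window bounds, seconds.
#' @param lever_xy lever position (mm).
#' @param onset_latency movement-onset latency (s), copied into the output.
#' @return one-row data frame with the 18 feature columns plus `incomplete`
#'   (TRUE when fewer than 3 valid frames fall in the window).
#' @export
movement_features <- function(pose, start_t, end_t, lever_xy,
                              onset_latency = NA_real_) {
  stopifnot(start_t < end_t)
  fr <- pose$frame_rate
  nfr <- nrow(pose$position)
  t_all <- (seq_len(nfr) - 1L) / fr
  sel <- which(t_all >= start_t - 1e-9 & t_all <= end_t + 1e-9)
  feat_names <- c("radial_velocity_mean", "radial_velocity_max",
                  "radial_velocity_sd", "speed_mean", "speed_sd", "speed_max",
                  "move_duration_s", "path_length_mm", "latency_max_speed_s",
                  "latency_max_accel_s", "max_path_deviation_mm",
                  "turn_efficiency", "angular_velocity_sd",
                  "angular_velocity_max", "angular_velocity_mean",
                  "net_heading_change_rad", "path_efficiency",
                  "movement_onset_latency_s")
  out <- as.data.frame(as.list(setNames(rep(NA_real_, length(feat_names)),
                                        feat_names)))
  out$movement_onset_latency_s <- onset_latency
  out$incomplete <- TRUE
  if (length(sel) < 3L || !all(pose$valid[sel])) return(out)
  p <- pose$position[sel, , drop = FALSE]
  h <- pose$heading[sel]
  tt <- t_all[sel]
  dx <- diff(p[, 1L]); dy <- diff(p[, 2L])
  step <- sqrt(dx^2 + dy^2)
  speed <- step * fr
  rx <- p[, 1L] - lever_xy[1L]; ry <- p[, 2L] - lever_xy[2L]
  dist <- sqrt(rx^2 + ry^2)
  radial <- -diff(dist) * fr
  theta <- atan2(ry, rx)
  ang <- wrap_angle(diff(theta)) * fr
  ang_abs <- abs(ang)
  dh <- wrap_angle(diff(h))
  accel <- diff(speed) * fr

  path_len <- sum(step)
  chord <- sqrt((p[nrow(p), 1L] - p[1L, 1L])^2 + (p[nrow(p), 2L] - p[1L, 2L])^2)
  # perpendicular distance of every path point to the start->end line
  if (chord > 1e-9) {
    ux <- (p[nrow(p), 1L] - p[1L, 1L]) / chord
    uy <- (p[nrow(p), 2L] - p[1L, 2L]) / chord
    devs <- abs(-(uy) * (p[, 1L] - p[1L, 1L]) + ux * (p[, 2L] - p[1L, 2L]))
    max_dev <- max(devs)
  } else {
    max_dev <- max(sqrt((p[, 1L] - p[1L, 1L])^2 + (p[, 2L] - p[1L, 2L])^2))
  }
  net_h <- sum(dh)
  cum_h <- sum(abs(dh))
  out$radial_velocity_mean <- mean(radial)
  out$radial_velocity_max <- max(radial)
  out$radial_velocity_sd <- sd(radial)
  out$speed_mean <- mean(speed)
  out$speed_sd <- sd(speed)
  out$speed_max <- max(speed)
  out$move_duration_s <- end_t - start_t
  out$path_length_mm <- path_len
  out$latency_max_speed_s <- tt[which.max(speed) + 1L] - start_t
  out$latency_max_accel_s <- if (length(accel) >= 1L)
    tt[which.max(accel) + 2L] - start_t else NA_real_
  out$max_path_deviation_mm <- max_dev
  out$turn_efficiency <- if (abs(net_h) >= 1e-3) cum_h / abs(net_h) else NA_real_
  out$angular_velocity_sd <- sd(ang_abs)
  out$angular_velocity_max <- max(ang_abs)
  out$angular_velocity_mean <- mean(ang_abs)
  out$net_heading_change_rad <- net_h
  out$path_efficiency <- if (path_len > 0) chord / path_len else NA_real_
  out$incomplete <- FALSE
  out
}

#' Behavioral-state features at cue onset
#'
#' @param pose `vp_pose`.
#' @param events event-log data frame.
#' @param cue_t cue onset time (s).
#' @param lever_xy lever position (mm).
#' @return one-row data frame: `lever_distance_mm`, `time_since_reward_s`,
#'   `time_since_press_s`, `time_since_cue_s` (NA when no prior event),
#'   `lever_orientation_rad` (absolute egocentric bearing to the lever,
#'   in \[0, pi\]), `incomplete`.
#' @export
state_features <- function(pose, events, cue_t, lever_xy) {
  fr <- pose$frame_rate
  f <- floor(cue_t * fr) + 1L  # 1-based frame index at cue onset
  out <- data.frame(lever_distance_mm = NA_real_, time_since_reward_s = NA_real_,
                    time_since_press_s = NA_real_, time_since_cue_s = NA_real_,
                    lever_orientation_rad = NA_real_, incomplete = TRUE)
  last_before <- function(kinds) {
    tt <- events$time_s[events$kind %in% kinds]
    tt <- tt[tt < cue_t]
    if (length(tt) == 0L) NA_real_ else cue_t - max(tt)
  }
  out$time_since_reward_s <- last_before("reward")
  out$time_since_press_s <- last_before("active_press")
  out$time_since_cue_s <- last_before(c("DS_on", "NS_on"))
  if (f < 1L || f > nrow(pose$position) || !pose$valid[f]) return(out)
  px <- pose$position[f, 1L]; py <- pose$position[f, 2L]
  out$lever_distance_mm <- sqrt((lever_xy[1L] - px)^2 + (lever_xy[2L] - py)^2)
  bearing <- atan2(lever_xy[2L] - py, lever_xy[1L] - px)
  out$lever_orientation_rad <- abs(wrap_angle(bearing - pose$heading[f]))
  out$incomplete <- FALSE
  out
}

#' Trial-level feature table
#'
#' Combines [movement_features()] and [state_features()] for every classified
#' trial into one analysis table (one row per cue presentation; movement
#' columns are `NA` for trials without a usable approach window).
#'
#' @param trials data frame from [classify_trials()].
#' @param pose `vp_pose`.
#' @param events event-log data frame.
#' @param lever_xy lever position (mm).
#' @return data frame: trial bookkeeping columns plus all feature columns.
#' @export
trial_features <- function(trials, pose, events, lever_xy) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    st <- state_features(pose, events, tr$cue_onset_s, lever_xy)
    mv <- if (!is.na(tr$movement_start_s) && !is.na(tr$movement_end_s) &&
              tr$movement_end_s > tr$movement_start_s) {
      movement_features(pose, tr$movement_start_s, tr$movement_end_s,
                        lever_xy, tr$movement_onset_latency_s)
    } else {
      movement_features_na(tr$movement_onset_latency_s)
    }
    names(st)[names(st) == "incomplete"] <- "state_incomplete"
    names(mv)[names(mv) == "incomplete"] <- "movement_incomplete"
    cbind(tr, mv, st, row.names = NULL)
  })
  do.call(rbind, rows)
}

movement_features_na <- function(onset_latency) {
  out <- as.data.frame(as.list(setNames(rep(NA_real_, 18L),
    c("radial_velocity_mean", "radial_velocity_max", "radial_velocity_sd",
      "speed_mean", "speed_sd", "speed_max", "move_duration_s",
      "path_length_mm", "latency_max_speed_s", "latency_max_accel_s",
      "max_path_deviation_mm", "turn_efficiency", "angular_velocity_sd",
      "angular_velocity_max", "angular_velocity_mean",
      "net_heading_change_rad", "path_efficiency",
      "movement_onset_latency_s"))))
  out$movement_onset_latency_s <- onset_latency
  out$incomplete <- TRUE
  out
}
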