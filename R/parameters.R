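#' Detect within-stride gait events
#'
#' Rule-based stand-in event detection on a segmented stride: mid-stance (MS)
#' is the sample of minimal gyroscope magnitude within the mid 60% of the
#' segment; toe-off (TO) the sample of maximal GZ in the first half;
#' heel-strike (HS) the sample with the steepest negative GZ slope in the
#' second half. The ordering TO < HS within the segment is enforced.
#'
#' @param recording an [imu_recording()].
#' @param segment one-row segment `data.frame` (or list with `start`, `end`).
#' @return A one-row `data.frame` with 0-based absolute sample indices
#'   `hs`, `to`, `ms`.
#' @export
detect_events <- function(recording, segment) {
  start <- segment$start; end <- segment$end
  len <- end - start
  if (len < 10L) stop("detect_events: segment too short")
  gz <- seg_slice(recording$gz, start, end)
  if (max(gz) - min(gz) < 1e-12) stop("detect_events: degenerate (constant) signal")
  gm <- sqrt(seg_slice(recording$gx, start, end)^2 +
               seg_slice(recording$gy, start, end)^2 + gz^2)

  lo <- max(1L, floor(0.2 * len) + 1L)
  hi <- min(len, ceiling(0.8 * len))
  ms_rel <- lo - 1L + which.min(gm[lo:hi])

  half <- len %/% 2L
  to_rel <- which.max(gz[1:half])
  d <- diff(gz)
  hs_rel <- half + which.min(d[half:(len - 1L)])
  if (to_rel >= hs_rel) stop("detect_events: event ordering TO < HS violated")
  data.frame(hs = as.integer(start + hs_rel - 1L),
             to = as.integer(start + to_rel - 1L),
             ms = as.integer(start + ms_rel - 1L))
}

#' Detect events for every segment of one recording
#'
#' @param recording an [imu_recording()].
#' @param segments segment `data.frame` for that foot.
#' @return Event `data.frame` (`hs`, `to`, `ms`) aligned with `segments`.
#' @export
detect_all_events <- function(recording, segments) {
  if (nrow(segments) == 0L) return(data.frame(hs = integer(), to = integer(), ms = integer()))
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    detect_events(recording, segments[i, ])
  }))
}

#' Temporal stride parameters from consecutive heel strikes
#'
#' Stride time is the time between the heel strikes opening and closing the
#' stride; swing is the fraction of the stride spent between the terminating
#' toe-off and heel strike, stance its complement.
#'
#' @param events_i,events_next event rows of two consecutive strides of the
#'   same foot.
#' @param sampling_rate sampling rate in Hz.
#' @return A list with `stride_time` (s), `swing_time` and `stance_time`
#'   (fractions of stride time).
#' @export
compute_temporal <- function(events_i, events_next, sampling_rate) {
  dt_hs <- events_next$hs - events_i$hs
  if (dt_hs <= 0) stop("compute_temporal: strides are not consecutive")
  swing <- (events_next$hs - events_next$to) / dt_hs
  list(stride_time = dt_hs / sampling_rate,
       swing_time = swing, stance_time = 1 - swing)
}

#' Foot trajectory between mid-stance anchors by ZUPT double integration
#'
#' Estimates the sensor orientation at the initial mid-stance from the
#' accelerometer under a static assumption (the measured specific force is
#' aligned with gravity), rotates the acceleration into a gravity-aligned
#' frame, removes gravity and double-integrates between the two mid-stance
#' samples with zero-velocity constraints at both anchors; residual velocity
#' drift is removed linearly before the position integration.
#'
#' @param recording an [imu_recording()].
#' @param ms_i,ms_next 0-based mid-stance sample indices, `ms_i < ms_next`.
#' @param height_cm subject body height in cm (normalizes lengths).
#' @return A list with `stride_length` and `path_length` (dimensionless,
#'   m / body height), `max_toe_clearance` (m), and the per-sample `velocity`
#'   and `position` matrices (m/s, m) of the gravity-aligned stride-local
#'   frame.
#' @export
integrate_trajectory <- function(recording, ms_i, ms_next, height_cm) {
  if (ms_next - ms_i < 3L) stop("integrate_trajectory: window shorter than 3 samples")
  if (height_cm <= 0) stop("integrate_trajectory: height must be > 0")
  fs <- recording$sampling_rate
  idx <- (ms_i + 1L):(ms_next + 1L)
  acc <- cbind(recording$ax[idx], recording$ay[idx], recording$az[idx]) * G0

  # static orientation estimate at the initial mid-stance
  w0 <- max(1L, ms_i + 1L - 5L):min(length(recording$t), ms_i + 1L + 5L)
  gvec <- c(mean(recording$ax[w0]), mean(recording$ay[w0]), mean(recording$az[w0]))
  gnorm <- sqrt(sum(gvec^2))
  if (gnorm < 1e-9) stop("integrate_trajectory: cannot estimate gravity direction")
  R <- rotation_to_y(gvec / gnorm)
  lin <- acc %*% t(R)
  lin[, 2] <- lin[, 2] - G0

  tt <- (seq_len(nrow(lin)) - 1L) / fs
  vel <- pracma::cumtrapz(tt, lin)
  # linear velocity-drift correction enforcing v = 0 at both anchors
  nT <- length(tt)
  vel <- vel - outer(tt / tt[nT], vel[nT, ])
  vel[1, ] <- 0; vel[nT, ] <- 0
  pos <- pracma::cumtrapz(tt, vel)

  h_m <- height_cm / 100
  disp <- pos[nT, ]
  stride_len <- sqrt(disp[1]^2 + disp[3]^2)
  steps <- diff(pos)
  path_len <- sum(sqrt(rowSums(steps^2)))
  list(stride_length = stride_len / h_m,
       path_length = path_len / h_m,
       max_toe_clearance = max(pos[, 2]) - pos[1, 2],
       velocity = vel, position = pos)
}

# rotation matrix mapping unit vector u onto the +y axis (Rodrigues)
rotation_to_y <- function(u) {
  ey <- c(0, 1, 0)
  c_ <- sum(u * ey)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  v <- c(u[2] * ey[3] - u[3] * ey[2],
         u[3] * ey[1] - u[1] * ey[3],
         u[1] * ey[2] - u[2] * ey[1])
  s <- sqrt(sum(v^2))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Sagittal foot angles at heel strike and toe off
#'
#' Foot pitch is obtained by integrating GZ from the (flat-foot, 0 deg)
#' mid-stance sample to the heel-strike and toe-off samples respectively
#' (trapezoidal rule; integration runs backwards when the event precedes
#' mid-stance). Dorsiflexion positive.
#'
#' @param recording an [imu_recording()].
#' @param events one-row event `data.frame` (`hs`, `to`, `ms`).
#' @return A list with `hs_angle` and `to_angle` in degrees.
#' @export
compute_angles <- function(recording, events) {
  fs <- recording$sampling_rate
  ang_to <- function(ev) {
    a <- min(events$ms, ev); b <- max(events$ms, ev)
    if (a == b) return(0)
    val <- pracma::trapz(recording$t[(a + 1L):(b + 1L)],
                         recording$gz[(a + 1L):(b + 1L)])
    if (ev >= events$ms) val else -val
  }
  list(hs_angle = ang_to(events$hs), to_angle = ang_to(events$to))
}

#' Signed turning angle of a stride
#'
#' Trapezoidal integral of GZ between two consecutive mid-stance samples, in
#' degrees (yaw projection for a laterally mounted foot sensor).
#'
#' @param recording an [imu_recording()].
#' @param ms_i,ms_next 0-based mid-stance sample indices.
#' @return Signed turning angle in degrees.
#' @export
compute_turning_angle <- function(recording, ms_i, ms_next) {
  if (ms_next <= ms_i) stop("compute_turning_angle: need ms_i < ms_next")
  idx <- (ms_i + 1L):(ms_next + 1L)
  pracma::trapz(recording$t[idx], recording$gz[idx])
}

#' Stride velocity from stride length and stride time
#'
#' @param stride_length height-normalized stride length.
#' @param stride_time stride time in seconds (> 0).
#' @return Height-normalized stride velocity (1/s).
#' @export
compute_stride_velocity <- function(stride_length, stride_time) {
  if (any(stride_time <= 0)) stop("compute_stride_velocity: stride_time must be > 0")
  stride_length / stride_time
}

#' Per-stride spatio-temporal parameter table for one foot
#'
#' Combines event detection, temporal parameters, ZUPT trajectory lengths,
#' sagittal angles and the turning angle into one row per segmented stride.
#' Strides are parameterized over consecutive event pairs; the final stride
#' of the recording, which has no following mid-stance, is closed over a
#' window extended by 75% of its own length (the synthetic recordings hold
#' idle signal there, and real 4x10 m recordings end standing).
#'
#' @param recording an [imu_recording()].
#' @param segments segment `data.frame` for this foot, ordered.
#' @param events event `data.frame` aligned with `segments` (default:
#'   detected with [detect_all_events()]).
#' @param height_cm subject body height in cm.
#' @return A `data.frame` with one row per stride: `foot`, `start`, `end`,
#'   `start_time`, the ten parameters (`stride_time`, `swing_time`,
#'   `stance_time`, `stride_length`, `stride_velocity`, `hs_angle`,
#'   `to_angle`, `max_toe_clearance`, `path_length`, `turning_angle`).
#' @export
stride_records <- function(recording, segments, events = NULL, height_cm = 172) {
  if (is.null(events)) events <- detect_all_events(recording, segments)
  n <- nrow(segments)
  if (n == 0L) {
    return(data.frame(foot = character(), start = integer(), end = integer()))
  }
  fs <- recording$sampling_rate
  n_samp <- length(recording$t)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    if (i < n) {
      ev2 <- events[i + 1L, ]
      tmp <- compute_temporal(ev, ev2, fs)
      ms_next <- ev2$ms
    } else {
      len <- segments$end[i] - segments$start[i]
      ms_next <- min(n_samp - 1L, segments$end[i] + round(0.75 * len))
      tmp <- list(stride_time = len / fs,
                  swing_time = (segments$end[i] - ev$hs) / len,
                  stance_time = 1 - (segments$end[i] - ev$hs) / len)
    }
    traj <- integrate_trajectory(recording, ev$ms, ms_next, height_cm)
    ang <- compute_angles(recording, ev)
    out[[i]] <- data.frame(
      foot = recording$foot, start = segments$start[i], end = segments$end[i],
      start_time = segments$start[i] / fs,
      stride_time = tmp$stride_time,
      swing_time = tmp$swing_time, stance_time = tmp$stance_time,
      stride_length = traj$stride_length,
      stride_velocity = compute_stride_velocity(traj$stride_length, tmp$stride_time),
      hs_angle = ang$hs_angle, to_angle = ang$to_angle,
      max_toe_clearance = traj$max_toe_clearance,
      path_length = traj$path_length,
      turning_angle = compute_turning_angle(recording, ev$ms, ms_next),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
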