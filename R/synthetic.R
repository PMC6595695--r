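#' Generate a ground-truth stride schedule for a 4x10 m walk test
#'
#' Produces the stride-level truth that the IMU synthesizer renders: straight
#' bouts in which subjects accelerate over the first strides, walk at constant
#' velocity, and decelerate over the last strides, separated by runs of
#' turning strides. Acceleration-stride velocities ramp linearly from
#' `v_min_frac * v_const` up to `v_const` following
#' `v_i = v_const * (v_min_frac + (1 - v_min_frac) * i / n_accel)` for
#' `i = 0, ..., n_accel - 1`, mirrored at the bout end. Straight-stride
#' turning angles are drawn from `N(0, ta_straight_sd)`; turning strides carry
#' `|TA|` near `ta_turn_deg` with turn direction alternating between turns.
#' Stride lengths scale with the square root of velocity around
#' `stride_length_const`, so slower strides are both shorter and longer in
#' time (stride time = length / velocity throughout).
#'
#' @param n_bouts number of straight bouts (>= 2).
#' @param strides_per_bout strides per straight bout.
#' @param n_accel,n_decel number of acceleration / deceleration strides per
#'   bout; `n_accel + n_decel < strides_per_bout`.
#' @param turn_strides number of turning strides per turn.
#' @param v_const constant-gait stride velocity in m/s.
#' @param v_min_frac fraction of `v_const` at the first/last stride of a bout.
#' @param ta_turn_deg nominal per-stride turning angle during turns (deg).
#' @param ta_straight_sd standard deviation of straight-stride TA (deg).
#' @param stride_length_const constant-gait stride length in m.
#' @param time_jitter_cv multiplicative stride-to-stride jitter (coefficient
#'   of variation) applied to stride times; 0 for noise-free schedules.
#' @param v_shift additive shift applied to every straight-stride velocity
#'   (m/s), used by the cohort generator to model impaired gait.
#' @param toe_clearance_m nominal maximal toe clearance in m.
#' @param seed integer seed; all schedule randomness flows from it.
#' @return A `data.frame` of class `stride_schedule` with one row per stride:
#'   `phase` (`acceleration`/`constant`/`deceleration`/`turning`),
#'   `stride_time` (s), `stride_length` (m), `stride_velocity` (m/s),
#'   `turning_angle` (deg, signed), `toe_clearance` (m) and `bout_id`
#'   (`NA` for turning strides).
#' @export
generate_schedule <- function(n_bouts = 4, strides_per_bout = 8,
                              n_accel = 3, n_decel = 3, turn_strides = 4,
                              v_const = 1.4, v_min_frac = 0.5,
                              ta_turn_deg = 45, ta_straight_sd = 3,
                              stride_length_const = 1.25,
                              time_jitter_cv = 0, v_shift = 0,
                              toe_clearance_m = 0.04, seed = 1) {
  if (n_bouts < 2L) stop("generate_schedule: n_bouts must be >= 2")
  if (n_accel + n_decel >= strides_per_bout) {
    stop("generate_schedule: n_accel + n_decel must be < strides_per_bout")
  }
  if (turn_strides < 1L) stop("generate_schedule: turn_strides must be >= 1")
  set.seed(as.integer(seed))

  ramp <- v_const * (v_min_frac + (1 - v_min_frac) * (seq_len(n_accel) - 1L) / n_accel)
  dec  <- v_const * (v_min_frac + (1 - v_min_frac) * (seq_len(n_decel) - 1L) / n_decel)
  rows <- list()
  turn_sign <- 1
  for (b in seq_len(n_bouts)) {
    n_const <- strides_per_bout - n_accel - n_decel
    v <- c(ramp, rep(v_const, n_const), rev(dec)) + v_shift
    if (any(v <= 0)) stop("generate_schedule: velocities must stay positive")
    phase <- c(rep("acceleration", n_accel), rep("constant", n_const),
               rep("deceleration", n_decel))
    len <- stride_length_const * sqrt(v / v_const)
    st <- len / v
    if (time_jitter_cv > 0) {
      st <- st * pmax(0.5, 1 + rnorm(length(st), 0, time_jitter_cv))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      phase = phase, stride_time = st, stride_length = len,
      stride_velocity = len / st,
      turning_angle = rnorm(strides_per_bout, 0, ta_straight_sd),
      toe_clearance = toe_clearance_m * pmax(0.25, 1 + rnorm(strides_per_bout, 0, 0.05)),
      bout_id = b, stringsAsFactors = FALSE)
    if (b < n_bouts) {
      v_t <- pmax(0.2, 0.5 * v_const + v_shift)
      len_t <- 0.5 * stride_length_const
      st_t <- rep(len_t / v_t, turn_strides)
      if (time_jitter_cv > 0) {
        st_t <- st_t * pmax(0.5, 1 + rnorm(turn_strides, 0, time_jitter_cv))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phase = "turning", stride_time = st_t, stride_length = len_t,
        stride_velocity = len_t / st_t,
        turning_angle = turn_sign * (ta_turn_deg + rnorm(turn_strides, 0, 1)),
        toe_clearance = toe_clearance_m * pmax(0.25, 1 + rnorm(turn_strides, 0, 0.05)),
        bout_id = NA_integer_, stringsAsFactors = FALSE)
      turn_sign <- -turn_sign
    }
  }
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  class(sched) <- c("stride_schedule", "data.frame")
  sched
}

#' Synthesize per-foot IMU recordings from a stride schedule
#'
#' Renders the scheduled strides as six-axis IMU signals for both feet (the
#' right foot executes the same schedule shifted by half a stride). The GZ
#' channel is the stride-cycle waveform scaled to each stride's duration with
#' a unique minimum at every stride boundary; scheduled turning angles are
#' injected as smooth yaw-rate pulses placed in the early swing of the
#' following cycle, so the integrated GZ between consecutive mid-stance
#' samples equals the scheduled TA. The accelerometer carries gravity
#' (about 1 g on the superior-inferior axis) plus forward- and
#' vertical-acceleration profiles whose double integral reproduces the
#' scheduled stride length and toe clearance between mid-stance anchors
#' (foot velocity is zero at every mid-stance).
#'
#' @param schedule a [generate_schedule()] table.
#' @param sampling_rate sampling rate in Hz.
#' @param noise_sd gyroscope white-noise standard deviation in deg/s
#'   (accelerometer noise is `noise_sd / 500` g); 0 for noise-free signals.
#' @param seed integer seed for the noise draws.
#' @param pad idle padding before the first stride, in seconds.
#' @return A list with elements `left` and `right` ([imu_recording()]s),
#'   `segments` (truth segment table for both feet, 0-based half-open),
#'   `events` (truth `hs`/`to`/`ms` sample indices with `foot` and
#'   `stride` = schedule row) and `schedule` (the input, for convenience).
#' @export
synthesize_imu <- function(schedule, sampling_rate = 102.4, noise_sd = 0,
                           seed = 1, pad = 0.5) {
  if (sampling_rate <= 0) stop("synthesize_imu: sampling_rate must be > 0")
  set.seed(as.integer(seed))
  feet <- list(left = pad, right = pad + 0.5 * schedule$stride_time[1])
  out <- list()
  seg_all <- list(); ev_all <- list()
  for (f in names(feet)) {
    r <- render_foot(schedule, sampling_rate, noise_sd, pad_start = feet[[f]],
                     foot = f)
    out[[f]] <- r$recording
    seg_all[[f]] <- r$segments
    ev_all[[f]] <- r$events
  }
  list(left = out$left, right = out$right,
       segments = do.call(rbind, c(seg_all, list(make.row.names = FALSE))),
       events = do.call(rbind, c(ev_all, list(make.row.names = FALSE))),
       schedule = schedule)
}

# render one foot's signal; pad_start seconds of idle lead-in
render_foot <- function(schedule, fs, noise_sd, pad_start, foot) {
  st <- schedule$stride_time
  n_str <- nrow(schedule)
  starts <- pad_start + cumsum(c(0, st[-n_str]))
  ends <- starts + st
  total <- ends[n_str] + 1.5          # idle tail for final pulse and motion
  n <- ceiling(total * fs)
  t <- (0:(n - 1L)) / fs
  gz <- numeric(n); gx <- numeric(n)
  ax_ms2 <- numeric(n); ay_ms2 <- numeric(n)

  idx0 <- function(time) {
    as.integer(pmin(n - 1L, pmax(0L, ceiling(time * fs - 1e-9))))
  }

  for (i in seq_len(n_str)) {
    k <- which(t >= starts[i] - 1e-12 & t < ends[i] - 1e-12)
    u <- (t[k] - starts[i]) / st[i]
    gz[k] <- gz[k] + gz_stride_waveform(u)
    gx[k] <- gx[k] + gx_stride_waveform(u)
  }

  # turning-angle pulses: stride i's TA lives between its mid-stance and the
  # next one, centred at 25% of the following cycle (idle tail for the last)
  for (i in seq_len(n_str)) {
    host_t <- if (i < n_str) st[i + 1L] else st[i]
    centre <- if (i < n_str) starts[i + 1L] + 0.25 * host_t else ends[i] + 0.25 * host_t
    sdp <- 0.12 * host_t
    amp <- schedule$turning_angle[i] / (sdp * sqrt(2 * pi))
    k <- which(t >= centre - 6 * sdp & t <= centre + 6 * sdp)
    gz[k] <- gz[k] + amp * exp(-0.5 * ((t[k] - centre) / sdp)^2)
  }

  # forward/vertical motion between consecutive mid-stance anchors; sin^4
  # bumps are flat at the anchors, so the foot is genuinely static around
  # mid-stance (the ZUPT assumption) and velocity vanishes at both ends
  ms_t <- starts + .wave$ms_phase * st
  ms_next <- c(ms_t[-1L], ends[n_str] + .wave$ms_phase * st[n_str])
  for (i in seq_len(n_str)) {
    W <- ms_next[i] - ms_t[i]
    k <- which(t >= ms_t[i] - 1e-12 & t < ms_next[i] - 1e-12)
    w <- (t[k] - ms_t[i]) / W
    vmax <- 8 / 3 * schedule$stride_length[i] / W   # integral of sin^4 is 3/8
    ax_ms2[k] <- ax_ms2[k] +
      vmax * 4 * pi / W * sin(pi * w)^3 * cos(pi * w)
    h <- schedule$toe_clearance[i]
    ay_ms2[k] <- ay_ms2[k] +
      h * 4 * pi^2 / W^2 * sin(pi * w)^2 * (3 * cos(pi * w)^2 - sin(pi * w)^2)
  }

  if (noise_sd > 0) {
    gz <- gz + rnorm(n, 0, noise_sd)
    gx <- gx + rnorm(n, 0, noise_sd)
    gy <- rnorm(n, 0, noise_sd)
    acc_sd <- noise_sd / 500
    ax <- ax_ms2 / G0 + rnorm(n, 0, acc_sd)
    ay <- 1 + ay_ms2 / G0 + rnorm(n, 0, acc_sd)
    az <- rnorm(n, 0, acc_sd)
  } else {
    gy <- numeric(n)
    ax <- ax_ms2 / G0
    ay <- 1 + ay_ms2 / G0
    az <- numeric(n)
  }

  seg <- data.frame(start = idx0(starts), end = idx0(ends),
                    foot = foot, stringsAsFactors = FALSE)
  ev <- data.frame(
    hs = idx0(starts + .wave$hs_phase * st),
    to = idx0(starts + .wave$to_phase * st),
    ms = idx0(starts + .wave$ms_phase * st),
    foot = foot, stride = seq_len(n_str), stringsAsFactors = FALSE)
  list(recording = imu_recording(t, ax, ay, az, gx, gy, gz,
                                 foot = foot, sampling_rate = fs),
       segments = seg, events = ev)
}

#' Cohort specification for the synthetic two-class study
#'
#' @param n_subjects number of subjects (>= 4).
#' @param p_impaired proportion of impaired subjects, in (0, 1).
#' @param effect_velocity additive shift (m/s) on impaired straight-stride
#'   velocity (negative = slower).
#' @param effect_time_cv multiplier on impaired stride-time variability.
#' @param effect_turn_strides additional turning strides per turn for
#'   impaired subjects.
#' @param time_jitter_cv baseline stride-time coefficient of variation.
#' @param subject_sd_velocity between-subject standard deviation of the
#'   habitual constant-gait velocity (m/s); without it every unimpaired
#'   subject would walk at an identical speed and any group shift would be
#'   trivially separable.
#' @param subject_sd_log_time_cv between-subject log-scale dispersion of the
#'   stride-time variability, so the impaired/unimpaired CV distributions
#'   overlap as they do in real cohorts.
#' @param subject_turn_strides_range uniform between-subject jitter (+-
#'   strides) on the habitual number of strides per turn.
#' @param noise_sd gyroscope noise (deg/s) passed to the signal synthesizer.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param ... further defaults forwarded to [generate_schedule()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, p_impaired = 0.5,
                        effect_velocity = -0.2, effect_time_cv = 2,
                        effect_turn_strides = 1, time_jitter_cv = 0.04,
                        subject_sd_velocity = 0.15,
                        subject_sd_log_time_cv = 0.4,
                        subject_turn_strides_range = 1L,
                        noise_sd = 0, seed = 1, ...) {
  if (n_subjects < 4L) stop("cohort_spec: n_subjects must be >= 4")
  if (p_impaired <= 0 || p_impaired >= 1) {
    stop("cohort_spec: p_impaired must be in (0, 1)")
  }
  structure(list(n_subjects = n_subjects, p_impaired = p_impaired,
                 effect_velocity = effect_velocity,
                 effect_time_cv = effect_time_cv,
                 effect_turn_strides = effect_turn_strides,
                 time_jitter_cv = time_jitter_cv,
                 subject_sd_velocity = subject_sd_velocity,
                 subject_sd_log_time_cv = subject_sd_log_time_cv,
                 subject_turn_strides_range = as.integer(subject_turn_strides_range),
                 noise_sd = noise_sd,
                 seed = seed, schedule_args = list(...)),
            class = "cohort_spec")
}

#' Generate a two-class synthetic cohort
#'
#' Draws per-subject stride schedules emulating a cohort with and without
#' gait impairment: impaired subjects walk slower by `effect_velocity`, show
#' stride-time variability inflated by `effect_time_cv` and take
#' `effect_turn_strides` extra strides per turn. Impairment is stored as
#' `gait_score`/`postural_stability_score` 1 (0 for unimpaired).
#'
#' @param spec a [cohort_spec()].
#' @return A list with `subjects` (data.frame: `subject_id`, `height`,
#'   `gait_score`, `postural_stability_score`, `impaired`, `seed`) and
#'   `schedules` (list of [generate_schedule()] tables, one per subject).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(spec$seed))
  n <- spec$n_subjects
  n_imp <- round(n * spec$p_impaired)
  impaired <- sample(c(rep(TRUE, n_imp), rep(FALSE, n - n_imp)))
  heights <- rnorm(n, 172.5, 9)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  v_habit <- rnorm(n, 0, spec$subject_sd_velocity)
  cv_habit <- exp(rnorm(n, 0, spec$subject_sd_log_time_cv))
  r <- spec$subject_turn_strides_range
  turn_habit <- if (r > 0) sample(seq(-r, r), n, replace = TRUE) else rep(0L, n)
  base_args <- spec$schedule_args
  turn_base <- if (!is.null(base_args$turn_strides)) base_args$turn_strides else 4
  v_const_base <- if (!is.null(base_args$v_const)) base_args$v_const else 1.4

  schedules <- vector("list", n)
  for (i in seq_len(n)) {
    args <- base_args
    args$seed <- sub_seeds[i]
    args$v_const <- v_const_base + v_habit[i]
    args$time_jitter_cv <- spec$time_jitter_cv * cv_habit[i] *
      (if (impaired[i]) spec$effect_time_cv else 1)
    args$v_shift <- if (impaired[i]) spec$effect_velocity else 0
    args$turn_strides <- max(2L, turn_base + turn_habit[i] +
                               (if (impaired[i]) spec$effect_turn_strides else 0L))
    schedules[[i]] <- do.call(generate_schedule, args)
  }
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    height = heights,
    gait_score = as.integer(impaired),
    postural_stability_score = as.integer(impaired),
    impaired = impaired, seed = sub_seeds, stringsAsFactors = FALSE)
  list(subjects = subjects, schedules = schedules)
}
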