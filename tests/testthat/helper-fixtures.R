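# shared fixtures: tiny hand-built recordings and schedules

fs_default <- 102.4

# minimal constant-gravity recording with custom channels
make_recording <- function(n, fs = fs_default, ax = 0, ay = 1, az = 0,
                           gx = 0, gy = 0, gz = 0, foot = "left") {
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  imu_recording((0:(n - 1)) / fs, rep_n(ax), rep_n(ay), rep_n(az),
                rep_n(gx), rep_n(gy), rep_n(gz),
                foot = foot, sampling_rate = fs)
}

# noise-free synthetic walk shared by several tests
noise_free_walk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- generate_schedule(seed = 101)
      cache <<- synthesize_imu(sched, noise_sd = 0, seed = 101)
    }
    cache
  }
})

# indices of strides inside constant runs whose successor has identical
# scheduled duration (heel-strike based stride time equals the scheduled
# stride time only in steady state)
steady_stride_idx <- function(schedule) {
  n <- nrow(schedule)
  which(schedule$phase == "constant" &
          c(schedule$phase[-1], "") == "constant" &
          c(abs(diff(schedule$stride_time)) < 1e-12, FALSE))
}
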