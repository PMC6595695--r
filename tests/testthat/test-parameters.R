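test_that("temporal parameters follow the heel-strike definitions", {
  e1 <- data.frame(hs = 0L, to = 0L, ms = 0L)
  e2 <- data.frame(hs = 1024L, to = 700L, ms = 900L)
  tmp <- compute_temporal(e1, e2, 102.4)
  expect_equal(tmp$stride_time, 10)
  e2$hs <- 512L
  expect_equal(compute_temporal(e1, e2, 102.4)$stride_time, 5)
  expect_error(compute_temporal(e2, e1, 102.4), "consecutive")
  for (seed in 1:25) {
    set.seed(seed)
    hs0 <- sample(0:50, 1)
    hs1 <- hs0 + sample(50:150, 1)
    to1 <- hs1 - sample(10:40, 1)
    tmp <- compute_temporal(data.frame(hs = hs0), data.frame(hs = hs1, to = to1),
                            102.4)
    expect_equal(tmp$swing_time + tmp$stance_time, 1, tolerance = 1e-12)
  }
})

test_that("event detection follows its rules and rejects degenerate strides", {
  n <- 120
  u <- (0:(n - 1)) / n
  gz <- gz_stride_waveform(u)
  rec <- make_recording(n, gz = gz, gx = gaitphase:::gx_stride_waveform(u))
  ev <- detect_events(rec, list(start = 0L, end = n))
  anchors <- gaitphase:::.wave
  expect_lt(abs(ev$ms - round(anchors$ms_phase * n)), 3)
  expect_lt(abs(ev$to - round(anchors$to_phase * n)), 3)
  expect_lt(abs(ev$hs - round(anchors$hs_phase * n)), 4)
  expect_true(ev$to < ev$hs)
  flat <- make_recording(50)
  expect_error(detect_events(flat, list(start = 0L, end = 50L)), "degenerate")
})

test_that("mid-stance lands on the gyroscope-magnitude minimum", {
  n <- 100
  gm <- abs((0:(n - 1)) - 57) + 1   # unique magnitude minimum at sample 57
  rec <- make_recording(n, gx = gm, gz = sin((0:(n - 1)) / 5))
  ev <- detect_events(rec, list(start = 0L, end = n))
  expect_identical(ev$ms, 57L)
})

test_that("ZUPT double integration reproduces 1-D kinematics", {
  fs <- 100
  # rest 0.5 s, +1 m/s^2 for 0.5 s, -1 m/s^2 for 0.5 s, rest 0.5 s
  ax <- c(rep(0, 50), rep(1, 50), rep(-1, 50), rep(0, 50)) / gaitphase:::G0
  rec <- make_recording(200, fs = fs, ax = ax)
  tr <- integrate_trajectory(rec, 10L, 190L, height_cm = 100)
  expect_equal(tr$stride_length, 0.25, tolerance = 1e-6)
  expect_equal(tr$path_length, tr$stride_length, tolerance = 1e-9)
  expect_equal(tr$max_toe_clearance, 0, tolerance = 1e-9)
  # velocity is exactly zero at both mid-stance anchors
  expect_identical(tr$velocity[1, ], c(0, 0, 0))
  expect_identical(unname(tr$velocity[nrow(tr$velocity), ]), c(0, 0, 0))

  # zero acceleration -> zero displacement
  tr0 <- integrate_trajectory(make_recording(100, fs = fs), 5L, 95L, 100)
  expect_equal(tr0$stride_length, 0, tolerance = 1e-12)
  expect_equal(tr0$path_length, 0, tolerance = 1e-12)
  expect_error(integrate_trajectory(rec, 10L, 12L, 100), "shorter")
  expect_error(integrate_trajectory(rec, 10L, 190L, 0), "height")
})

test_that("sagittal angles are the GZ integral from mid-stance", {
  fs <- 100
  # constant 30 deg/s, mid-stance at 0, toe-off 0.5 s later
  rec <- make_recording(200, fs = fs, gz = 30)
  ev <- data.frame(hs = 150L, to = 50L, ms = 0L)
  ang <- compute_angles(rec, ev)
  expect_equal(ang$to_angle, 15, tolerance = 1e-9)
  expect_equal(ang$hs_angle, 45, tolerance = 1e-9)
  # zero signal -> zero angles
  ang0 <- compute_angles(make_recording(100, fs = fs),
                         data.frame(hs = 80L, to = 30L, ms = 50L))
  expect_identical(ang0$hs_angle, 0)
  # event before mid-stance integrates backwards with flipped sign
  ang_rev <- compute_angles(rec, data.frame(hs = 150L, to = 20L, ms = 50L))
  expect_equal(ang_rev$to_angle, -9, tolerance = 1e-9)

  # trapezoid matches a fine cumulative-sum quadrature oracle
  set.seed(3)
  gz <- cumsum(rnorm(300)) / 5
  rec <- make_recording(300, fs = fs, gz = gz)
  ev <- data.frame(hs = 250L, to = 120L, ms = 60L)
  ang <- compute_angles(rec, ev)
  oracle <- function(a, b) {
    idx <- (a + 1):(b + 1)
    sum((gz[idx][-1] + gz[idx][-length(idx)]) / 2) / fs
  }
  expect_equal(ang$hs_angle, oracle(60, 250), tolerance = 1e-6)
  expect_equal(ang$to_angle, oracle(60, 120), tolerance = 1e-6)
})

test_that("turning angle integrates GZ between mid-stance samples", {
  fs <- 100
  rec <- make_recording(201, fs = fs, gz = 90)
  expect_equal(compute_turning_angle(rec, 0L, 200L), 180, tolerance = 1e-9)
  rec0 <- make_recording(201, fs = fs)
  expect_equal(compute_turning_angle(rec0, 0L, 200L), 0)
  # one full sinusoid period integrates to zero
  gz <- sin(2 * pi * (0:200) / 200) * 50
  recs <- make_recording(201, fs = fs, gz = gz)
  expect_lt(abs(compute_turning_angle(recs, 0L, 200L)), 1e-6)
  expect_error(compute_turning_angle(rec, 10L, 10L), "ms_i < ms_next")
})

test_that("stride velocity is length over time with scaling law", {
  expect_equal(compute_stride_velocity(0.25, 1), 0.25)
  expect_equal(compute_stride_velocity(0, 2), 0)
  expect_equal(compute_stride_velocity(1.2, 2), compute_stride_velocity(1.2, 1) / 2)
  expect_error(compute_stride_velocity(1, 0), "stride_time")
})

test_that("noise-free synthetic strides recover the scheduled parameters", {
  sim <- noise_free_walk()
  sched <- sim$schedule
  height <- 170
  tpl <- gz_stride_template(fs_default)
  for (f in c("left", "right")) {
    rec <- sim[[f]]
    seg <- refine_by_minima(rec$gz, dtw_segment(rec$gz, tpl, foot = f), 10)
    st <- stride_records(rec, seg, height_cm = height)
    expect_identical(nrow(st), nrow(sched))
    i <- seq_len(nrow(st) - 1L)
    # turning angle within 1 degree for every stride
    expect_lt(max(abs(st$turning_angle[i] - sched$turning_angle[i])), 1)
    # stride length within 5% (height-normalized truth)
    truth_len <- sched$stride_length / (height / 100)
    expect_lt(max(abs(st$stride_length[i] - truth_len[i]) / truth_len[i]), 0.05)
    # heel-strike stride time matches scheduled time in steady state
    ss <- steady_stride_idx(sched)
    expect_lt(max(abs(st$stride_time[ss] - sched$stride_time[ss]) /
                    sched$stride_time[ss]), 0.02)
    expect_lt(max(abs(st$max_toe_clearance[i] - sched$toe_clearance[i])), 0.005)
  }
})
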