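#' Construct a validated IMU recording
#'
#' An `imu_recording` holds one foot's six-axis inertial signal: a three-axis
#' accelerometer in units of g and a three-axis gyroscope in deg/s, sampled
#' uniformly. Axis convention: x posterior-anterior, y superior-inferior,
#' z medio-lateral (so `gz` carries the sagittal stride cycle of a laterally
#' mounted foot sensor).
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing and
#'   uniform to within 1e-9 s.
#' @param ax,ay,az accelerometer channels in g.
#' @param gx,gy,gz gyroscope channels in deg/s.
#' @param foot `"left"` or `"right"`.
#' @param sampling_rate sampling rate in Hz (default 102.4).
#' @return An object of class `imu_recording`: a list with the seven channels,
#'   `foot` and `sampling_rate`.
#' @export
imu_recording <- function(t, ax, ay, az, gx, gy, gz,
                          foot = c("left", "right"),
                          sampling_rate = 102.4) {
  foot <- match.arg(foot)
  chans <- list(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  n <- length(t)
  if (n < 2L) stop("imu_recording: all channels must have length >= 2")
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n)) stop("imu_recording: all channels must have equal length")
  if (!all(vapply(chans, is.numeric, logical(1)))) {
    stop("imu_recording: all channels must be numeric")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("imu_recording: sampling_rate must be > 0")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("imu_recording: timestamps must be strictly increasing")
  if (max(abs(dt - 1 / sampling_rate)) > 1e-6) {
    stop("imu_recording: timestamps must be uniform at the stated sampling rate")
  }
  structure(c(chans, list(foot = foot, sampling_rate = sampling_rate)),
            class = "imu_recording")
}

#' @export
length.imu_recording <- function(x) length(x$t)

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> foot=%s, n=%d samples @ %.1f Hz (%.1f s)\n",
              x$foot, length(x$t), x$sampling_rate,
              length(x$t) / x$sampling_rate))
  invisible(x)
}

#' Read a per-foot IMU CSV file
#'
#' Expects a UTF-8 CSV with header columns `time,ax,ay,az,gx,gy,gz`
#' ('.' decimal separator), one file per foot.
#'
#' @param path path to the CSV file.
#' @param foot `"left"` or `"right"`.
#' @param sampling_rate expected sampling rate in Hz; defaults to the value
#'   implied by the median timestamp step.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, foot = c("left", "right"), sampling_rate = NULL) {
  foot <- match.arg(foot)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("read_imu_csv: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(sampling_rate)) {
    dt <- diff(df$time)
    if (any(dt <= 0)) stop("read_imu_csv: non-monotone time column")
    sampling_rate <- 1 / median(dt)
  }
  imu_recording(df$time, df$ax, df$ay, df$az, df$gx, df$gy, df$gz,
                foot = foot, sampling_rate = sampling_rate)
}

#' Write a per-foot IMU CSV file
#'
#' Inverse of [read_imu_csv()]; values are written with full double precision
#' so a read/write round trip is lossless up to float formatting.
#'
#' @param recording an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- data.frame(time = recording$t,
                   ax = recording$ax, ay = recording$ay, az = recording$az,
                   gx = recording$gx, gy = recording$gy, gz = recording$gz)
  df[] <- lapply(df, function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a stride-segment table
#'
#' Stride segments are half-open sample windows `[start, end)` in 0-based
#' sample indices, non-overlapping and ordered for a given foot.
#'
#' @param start,end integer vectors, 0-based inclusive start / exclusive end.
#' @param foot side label(s), recycled.
#' @param n_samples optional signal length for bounds checking.
#' @return A `data.frame` with columns `start`, `end`, `foot`.
#' @export
stride_segments <- function(start, end, foot = "left", n_samples = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("stride_segments: length mismatch")
  seg <- data.frame(start = start, end = end,
                    foot = rep_len(as.character(foot), length(start)),
                    stringsAsFactors = FALSE)
  validate_segments(seg, n_samples = n_samples)
  seg
}

#' Validate a stride-segment table
#'
#' Checks the segment invariants: `0 <= start < end`, within bounds when
#' `n_samples` is given, and per-foot segments ordered and non-overlapping.
#'
#' @param segments a segment `data.frame` (columns `start`, `end`, `foot`).
#' @param n_samples optional signal length.
#' @return `segments`, invisibly; throws on violation.
#' @export
validate_segments <- function(segments, n_samples = NULL) {
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(segments$start < 0L) || any(segments$start >= segments$end)) {
    stop("segments: need 0 <= start < end")
  }
  if (!is.null(n_samples) && any(segments$end > n_samples)) {
    stop("segments: end index beyond signal length")
  }
  for (f in unique(segments$foot)) {
    s <- segments[segments$foot == f, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("segments: overlapping segments for foot ", f)
    }
  }
  invisible(segments)
}

# slice a channel vector by a 0-based half-open window
seg_slice <- function(x, start, end) x[(start + 1L):end]
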