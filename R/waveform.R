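# Canonical smooth stride-cycle waveforms used by the synthetic generator and
# as the packaged segmentation template. The GZ cycle is a sum of Gaussians:
# a deep trough at each stride boundary (the segmentation anchor), a swing
# peak in the first half (toe-off anchor), a sharp dip whose falling edge is
# the steepest negative slope of the cycle (heel-strike anchor) and a stance
# bump. Amplitudes are solved so that the integral of the cycle vanishes
# separately over [0, 0.75] and [0.75, 1] of the normalized stride phase:
# mid-stance sits at phase 0.75, so any mid-stance-to-mid-stance integral of
# the cycle is zero and the integrated yaw of a stride equals exactly the
# turning-angle pulse injected on top of the cycle.

.wave <- local({
  tr_a <- 400; tr_w <- 0.05          # boundary trough
  hs_a <- 220; hs_w <- 0.013         # heel-strike dip at phase 0.55; its
  hs_c <- 0.55                       # falling edge must stay the steepest
  sw_c <- 0.25; sw_w <- 0.06         # swing peak (toe-off anchor)
  bu_c <- 0.89; bu_w <- 0.04         # stance bump, clear of the mid-stance
  # zero-area constraints (half-trough mass at each boundary)
  bu_a <- tr_a * tr_w / (2 * bu_w)
  sw_a <- (tr_a * tr_w / 2 + hs_a * hs_w) / sw_w
  list(tr_a = tr_a, tr_w = tr_w, hs_a = hs_a, hs_w = hs_w, hs_c = hs_c,
       sw_a = sw_a, sw_c = sw_c, sw_w = sw_w, bu_a = bu_a, bu_c = bu_c,
       bu_w = bu_w,
       # phase anchors of the within-stride events
       ms_phase = 0.75, to_phase = sw_c, hs_phase = hs_c - hs_w)
})

#' Canonical GZ stride-cycle waveform
#'
#' Evaluates the smooth medio-lateral gyroscope cycle (deg/s) at normalized
#' stride phase `u` in `[0, 1)`. The unique minimum of the cycle lies at the
#' stride boundary (`u = 0` / `u = 1`), the swing peak at `u = 0.25`, the
#' steepest negative slope at `u` slightly before `0.55` and mid-stance at
#' `u = 0.75`; the integral over any mid-stance-to-mid-stance span of
#' concatenated cycles is zero.
#'
#' @param u numeric vector of normalized stride phase values.
#' @return deg/s values of the cycle.
#' @export
gz_stride_waveform <- function(u) {
  w <- .wave
  -w$tr_a * (exp(-0.5 * (u / w$tr_w)^2) + exp(-0.5 * ((u - 1) / w$tr_w)^2)) +
    w$sw_a * exp(-0.5 * ((u - w$sw_c) / w$sw_w)^2) -
    w$hs_a * exp(-0.5 * ((u - w$hs_c) / w$hs_w)^2) +
    w$bu_a * exp(-0.5 * ((u - w$bu_c) / w$bu_w)^2)
}

# GX companion channel: a 60 deg/s plateau with a deep narrow notch at
# mid-stance so the gyroscope magnitude has a unique minimum at the
# mid-stance sample regardless of the GZ stance shape.
gx_stride_waveform <- function(u) {
  60 * (1 - 0.99 * exp(-0.5 * ((u - .wave$ms_phase) / 0.02)^2))
}

#' Packaged canonical stride template for DTW segmentation
#'
#' Renders one cycle of [gz_stride_waveform()] at the given stride time, for
#' use as the default template of [dtw_segment()].
#'
#' @param sampling_rate sampling rate in Hz.
#' @param stride_time nominal stride time in seconds.
#' @return numeric vector of one stride cycle (deg/s).
#' @export
gz_stride_template <- function(sampling_rate = 102.4, stride_time = 1.0) {
  m <- round(sampling_rate * stride_time)
  if (m < 10L) stop("gz_stride_template: template must be >= 10 samples")
  gz_stride_waveform((0:(m - 1L)) / m)
}
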