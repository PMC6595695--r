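#' Gamma-tail threshold of positive values
#'
#' Fits a gamma distribution (location fixed at zero) to strictly positive
#' values by maximum likelihood and returns the `q`-quantile of the fitted
#' distribution. Degenerate samples (zero variance), for which the MLE is
#' undefined, fall back to the empirical `q`-quantile.
#'
#' @param values strictly positive numeric vector, length >= 3.
#' @param q quantile level in (0, 1), default 0.9.
#' @return The fitted-gamma `q`-quantile.
#' @export
gamma_tail_threshold <- function(values, q = 0.9) {
  if (length(values) < 3L) stop("gamma_tail_threshold: need >= 3 values")
  if (any(values <= 0)) stop("gamma_tail_threshold: values must be > 0")
  if (sd(values) < 1e-12 * max(values)) {
    return(unname(quantile(values, q, type = 7)))
  }
  fit <- suppressWarnings(
    fitdistrplus::fitdist(values, "gamma", method = "mle", keepdata = FALSE))
  unname(qgamma(q, shape = fit$estimate[["shape"]], rate = fit$estimate[["rate"]]))
}

#' Isolate turning strides from a per-foot turning-angle sequence
#'
#' Implements the two-stage unsupervised turning detector, applied to each
#' foot separately: (1) every stride with `|TA|` above `hard_threshold_deg`
#' (default 20 deg) is a turning stride; (2) a gamma distribution is fitted
#' to the `|TA|` of the remaining strides and any unmarked stride whose
#' `|TA|` reaches the upper-`(1-q)` tail of the fitted distribution is added
#' if it is index-adjacent to an already marked stride. The adjacency
#' expansion is iterated to a fixed point by default (`iterate = FALSE`
#' applies a single pass). Strides marked by the hard rule are never removed.
#' Maximal runs of consecutive turning strides are grouped into turns.
#'
#' @param ta_deg signed turning angles (deg) of one foot's strides in time
#'   order.
#' @param q gamma tail level (default 0.9, i.e. the upper 10%).
#' @param hard_threshold_deg hard turning threshold in degrees.
#' @param stride_times optional stride times (s) used for per-turn durations.
#' @param iterate iterate the adjacency expansion to a fixed point.
#' @return A list of class `turning_result`: `is_turning` (logical),
#'   `tail_threshold` (fitted gamma quantile or `NA` when skipped), and
#'   `turns` (data.frame `first`, `last`, `n_strides`, `turning_time`).
#' @export
isolate_turning <- function(ta_deg, q = 0.9, hard_threshold_deg = 20,
                            stride_times = NULL, iterate = TRUE) {
  n <- length(ta_deg)
  if (n < 1L) stop("isolate_turning: empty TA sequence")
  ata <- abs(ta_deg)
  marked <- ata > hard_threshold_deg

  thr <- NA_real_
  rest <- ata[!marked]
  rest <- rest[rest > 0]
  if (length(rest) < 3L) {
    if (any(!marked)) {
      warning("isolate_turning: fewer than 3 straight strides; gamma step skipped")
    }
  } else if (any(marked)) {
    thr <- gamma_tail_threshold(rest, q)
    repeat {
      adj <- (c(FALSE, marked[-n]) | c(marked[-1L], FALSE)) & !marked
      add <- adj & ata >= thr
      if (!any(add)) break
      marked <- marked | add
      if (!iterate) break
    }
  }
  list(is_turning = marked, tail_threshold = thr,
       turns = group_turns(marked, stride_times))
}

#' Group turning flags into turns
#'
#' Maximal runs of consecutive turning strides become turns; the turning time
#' of a turn is the sum of its stride times.
#'
#' @param is_turning logical per-stride flags in time order.
#' @param stride_times stride times in seconds (optional; `NA` durations
#'   otherwise).
#' @return A `data.frame` with one row per turn: `first`, `last` (1-based
#'   stride indices), `n_strides`, `turning_time`.
#' @export
group_turns <- function(is_turning, stride_times = NULL) {
  r <- rle(is_turning)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L) {
    return(data.frame(first = integer(), last = integer(),
                      n_strides = integer(), turning_time = numeric()))
  }
  data.frame(
    first = starts[keep], last = ends[keep],
    n_strides = r$lengths[keep],
    turning_time = vapply(keep, function(k) {
      if (is.null(stride_times)) NA_real_ else sum(stride_times[starts[k]:ends[k]])
    }, numeric(1)))
}
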