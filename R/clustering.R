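#' Names of the straight-gait clustering methods
#'
#' The crop family (`"5%crop"` ... `"25%crop"`) plus the four threshold
#' methods applied to stride velocity or stride time (`"median vel"`,
#' `"median t"`, `"distr vel"`, `"distr t"`, `"3means vel"`, `"3means t"`,
#' `"perc vel"`, `"perc t"`).
#'
#' @return Character vector of method names.
#' @export
clustering_methods <- function() {
  c(paste0(c(5, 10, 15, 20, 25), "%crop"),
    paste(rep(c("median", "distr", "3means", "perc"), each = 2),
          c("vel", "t")))
}

#' Split straight strides into walking bouts
#'
#' Maximal runs of non-turning strides (both feet merged in time order)
#' become bouts; empty runs are dropped.
#'
#' @param turning_flags logical per-stride flags in time order.
#' @return Integer vector of bout ids aligned with the strides (`NA` for
#'   turning strides), numbered 1, 2, ... in time order.
#' @export
split_into_bouts <- function(turning_flags) {
  n <- length(turning_flags)
  bout <- rep(NA_integer_, n)
  if (n == 0L) return(bout)
  r <- rle(!turning_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  id <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      id <- id + 1L
      bout[starts[k]:ends[k]] <- id
    }
  }
  bout
}

#' Normalize a bout's parameter values by the bout mean
#'
#' @param values numeric values of one bout (mean must be nonzero).
#' @return `values / mean(values)` (mean of the output is 1).
#' @export
normalize_bout <- function(values) {
  if (length(values) < 1L) stop("normalize_bout: empty bout")
  m <- mean(values)
  if (abs(m) < 1e-12) stop("normalize_bout: zero bout mean")
  values / m
}

#' Crop-based raw labels for one bout
#'
#' Assigns the first and last `n_percent`% of a bout's strides (count rounded
#' half-up) to the non-constant cluster and the rest to the constant cluster.
#'
#' @param n_strides number of strides in the bout.
#' @param n_percent crop percentage; the studied grid is 5, 10, 15, 20, 25
#'   (other values are allowed with a warning).
#' @return Character vector of raw labels (`"constant"` / `"non_constant"`).
#' @export
crop_labels <- function(n_strides, n_percent) {
  if (n_strides < 1L) stop("crop_labels: empty bout")
  if (!n_percent %in% c(5, 10, 15, 20, 25)) {
    warning("crop_labels: n_percent outside the studied grid {5,10,15,20,25}")
  }
  k <- floor(n_percent / 100 * n_strides + 0.5)   # round half-up
  lab <- rep("constant", n_strides)
  if (2 * k >= n_strides) return(rep("non_constant", n_strides))
  if (k > 0) {
    lab[seq_len(k)] <- "non_constant"
    lab[(n_strides - k + 1L):n_strides] <- "non_constant"
  }
  lab
}

#' Threshold-based raw labels for one bout
#'
#' Derives a lower and upper threshold on the bout-normalized clustering
#' parameter and labels a stride constant iff it lies strictly between them:
#' \describe{
#'   \item{median}{values normalized by the bout median; thresholds 0.95 and
#'     1.05.}
#'   \item{distr}{normal fit (sample mean and SD, ddof 1) of the bout-mean
#'     normalized values; thresholds mean -/+ SD.}
#'   \item{kmeans3}{1-D k-means with K = 3 on the bout-mean normalized
#'     values, five seeded random initializations (three distinct values
#'     drawn uniformly from the bout); the run with the largest separation
#'     (minimum pairwise distance between the three centers) wins, and the
#'     smallest and largest center become the thresholds.}
#'   \item{percentile}{empirical 25th and 75th percentiles
#'     (linear-interpolation convention) of the bout-mean normalized values.}
#' }
#'
#' @param values the bout's stride velocities or stride times (raw scale).
#' @param method one of `"median"`, `"distr"`, `"kmeans3"`, `"percentile"`.
#' @param seed integer seed (used by `kmeans3`).
#' @return A list with `lower`, `upper` (thresholds on the normalized scale),
#'   `normalized` values and `labels` (`"constant"` / `"non_constant"`).
#' @export
threshold_labels <- function(values,
                             method = c("median", "distr", "kmeans3", "percentile"),
                             seed = 1) {
  method <- match.arg(method)
  n <- length(values)
  if (method == "kmeans3") {
    if (length(unique(values)) < 3L) {
      stop("threshold_labels: kmeans3 needs >= 3 distinct values")
    }
  } else if (n < 3L) {
    stop("threshold_labels: need >= 3 strides in the bout")
  }
  if (method == "median") {
    md <- median(values)
    if (abs(md) < 1e-12) stop("threshold_labels: zero bout median")
    x <- values / md
    lower <- 0.95; upper <- 1.05
  } else {
    x <- normalize_bout(values)
    if (method == "distr") {
      lower <- mean(x) - sd(x); upper <- mean(x) + sd(x)
    } else if (method == "percentile") {
      qs <- unname(quantile(x, c(0.25, 0.75), type = 7))
      lower <- qs[1]; upper <- qs[2]
    } else {
      centers <- kmeans3_1d(x, seed = seed)
      lower <- min(centers); upper <- max(centers)
    }
  }
  labels <- ifelse(x > lower & x < upper, "constant", "non_constant")
  list(lower = lower, upper = upper, normalized = x, labels = labels)
}

# 1-D Lloyd k-means, K = 3, five seeded initializations (one spread over the
# value quantiles, the rest random draws of three distinct values);
# assignment ties break toward the lower-index center; the run whose final
# centers have the largest minimum pairwise distance is returned.
kmeans3_1d <- function(x, seed = 1, n_init = 5L, max_iter = 100L) {
  set.seed(as.integer(seed))
  ux <- unique(x)
  spread <- unname(quantile(x, c(1, 3, 5) / 6, type = 7))
  best_sep <- -Inf; best_centers <- NULL
  for (r in seq_len(n_init)) {
    centers <- if (r == 1L && !anyDuplicated(spread)) spread else sample(ux, 3L)
    assign_old <- rep(0L, length(x))
    for (it in seq_len(max_iter)) {
      d <- abs(outer(x, centers, "-"))
      assign <- max.col(-d, ties.method = "first")
      if (identical(assign, assign_old)) break
      assign_old <- assign
      for (k in 1:3) {
        if (any(assign == k)) centers[k] <- mean(x[assign == k])
      }
    }
    sep <- min(dist(centers))
    if (sep > best_sep) {
      best_sep <- sep
      best_centers <- centers
    }
  }
  best_centers
}

#' Enforce acceleration-constant-deceleration ordering within a bout
#'
#' Post-processes raw constant/non-constant labels under the assumption that
#' gait acceleration and deceleration can only occur within the first and
#' last 25% of a bout (band size `ceiling(0.25 n)`): within the head band,
#' all strides up to and including the last raw non-constant stride become
#' acceleration; mirrored from the tail for deceleration; every other stride
#' (including raw non-constant strides outside the bands) becomes constant.
#'
#' @param raw_labels character vector of `"constant"` / `"non_constant"` raw
#'   labels of one bout in time order.
#' @return Character vector of final labels (`"acceleration"`, `"constant"`,
#'   `"deceleration"`).
#' @export
postprocess_labels <- function(raw_labels) {
  n <- length(raw_labels)
  if (n == 0L) return(character(0))
  band <- ceiling(0.25 * n)
  out <- rep("constant", n)
  head_nc <- which(raw_labels[seq_len(band)] == "non_constant")
  if (length(head_nc) > 0L) out[seq_len(max(head_nc))] <- "acceleration"
  tail_idx <- (n - band + 1L):n
  tail_nc <- which(raw_labels[tail_idx] == "non_constant")
  if (length(tail_nc) > 0L) {
    first_dec <- tail_idx[min(tail_nc)]
    out[first_dec:n] <- "deceleration"
  }
  out
}

#' Cluster one bout by a named method
#'
#' Dispatches over the clustering methods (see [clustering_methods()]):
#' crop methods position the non-constant strides directly; threshold methods
#' derive thresholds from the chosen parameter. By default the 25%-band
#' ordering post-processor is applied to every method; `raw = TRUE` returns
#' the raw constant/non-constant labels instead.
#'
#' @param velocity,time the bout's stride velocities and stride times in
#'   time order (raw scale; velocity already height-normalized upstream).
#' @param method_name a method name from [clustering_methods()].
#' @param seed integer seed for the k-means methods.
#' @param raw return raw labels without post-processing.
#' @return Character labels: `"acceleration"`/`"constant"`/`"deceleration"`
#'   (or raw `"constant"`/`"non_constant"` when `raw = TRUE`).
#' @export
cluster_bout <- function(velocity, time, method_name, seed = 1, raw = FALSE) {
  n <- length(velocity)
  stopifnot(length(time) == n)
  if (grepl("%crop$", method_name)) {
    pct <- as.numeric(sub("%crop$", "", method_name))
    if (is.na(pct)) stop("cluster_bout: unknown method '", method_name, "'")
    labels <- crop_labels(n, pct)
  } else {
    parts <- strsplit(method_name, " ")[[1L]]
    if (length(parts) != 2L || !parts[2L] %in% c("vel", "t")) {
      stop("cluster_bout: unknown method '", method_name, "'")
    }
    meth <- switch(parts[1L],
                   median = "median", distr = "distr",
                   "3means" = "kmeans3", perc = "percentile",
                   stop("cluster_bout: unknown method '", method_name, "'"))
    vals <- if (parts[2L] == "vel") velocity else time
    labels <- threshold_labels(vals, meth, seed = seed)$labels
  }
  if (raw) labels else postprocess_labels(labels)
}
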