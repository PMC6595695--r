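# canonical parameter and feature ordering for straight-gait clusters
STRAIGHT_PARAMS <- c("stride_time", "swing_time", "stance_time",
                     "stride_length", "stride_velocity", "hs_angle",
                     "to_angle", "max_toe_clearance", "path_length",
                     "turning_angle")
TURNING_STRIDE_PARAMS <- c("stride_length", "stride_time", "stride_velocity",
                           "path_length")

#' Canonical feature names of a gait cluster
#'
#' @param cluster `"baseline"`, `"constant"`, `"non_constant"` or
#'   `"turning"`.
#' @return Character vector of feature column names in canonical order.
#' @export
cluster_feature_names <- function(cluster) {
  if (cluster == "turning") {
    c("n_strides_mean", "turning_time_mean",
      as.vector(t(outer(TURNING_STRIDE_PARAMS, c("mean", "cv"), paste, sep = "_"))))
  } else {
    as.vector(t(outer(STRAIGHT_PARAMS, c("mean", "cv"), paste, sep = "_")))
  }
}

# coefficient of variation, sd (ddof = 1) over |mean|; NA when undefined
cv_of <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (abs(m) < 1e-12) return(NA_real_)
  sd(x) / abs(m)
}

mean_of <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  mean(x)
}

#' Aggregate per-stride parameters of one straight-gait cluster
#'
#' Computes the mean and coefficient of variation (sd with ddof 1 over the
#' absolute mean) of each of the ten spatio-temporal parameters over the
#' strides of the named cluster, pooled over feet and bouts. The turning
#' angle of straight strides straddles zero, so its aggregation uses `|TA|`.
#' Empty clusters yield all-`NA` features; CVs of clusters with fewer than
#' two strides are `NA`.
#'
#' @param strides per-stride parameter `data.frame` (see [stride_records()])
#'   restricted to the cluster's strides.
#' @param cluster cluster name (for the missing-feature template).
#' @return A named numeric vector in [cluster_feature_names()] order.
#' @export
aggregate_cluster <- function(strides, cluster = "baseline") {
  feats <- setNames(rep(NA_real_, length(cluster_feature_names(cluster))),
                    cluster_feature_names(cluster))
  if (cluster == "turning") stop("aggregate_cluster: use aggregate_turning")
  if (nrow(strides) == 0L) return(feats)
  for (p in STRAIGHT_PARAMS) {
    v <- strides[[p]]
    if (p == "turning_angle") v <- abs(v)
    feats[paste0(p, "_mean")] <- mean_of(v)
    feats[paste0(p, "_cv")] <- cv_of(v)
  }
  feats
}

#' Aggregate the turning cluster
#'
#' Per-turn parameters (number of strides, turning time) are averaged over
#' all turns; per-stride parameters (stride length, stride time, stride
#' velocity, path length) are aggregated as mean and CV over all turning
#' strides pooled across turns.
#'
#' @param turns per-turn `data.frame` (`n_strides`, `turning_time`), pooled
#'   over feet.
#' @param turning_strides per-stride parameter `data.frame` of the turning
#'   strides.
#' @return A named numeric vector in [cluster_feature_names()] order
#'   (all `NA` when there are no turns).
#' @export
aggregate_turning <- function(turns, turning_strides) {
  feats <- setNames(rep(NA_real_, length(cluster_feature_names("turning"))),
                    cluster_feature_names("turning"))
  if (nrow(turns) == 0L) return(feats)
  feats["n_strides_mean"] <- mean(turns$n_strides)
  feats["turning_time_mean"] <- mean(turns$turning_time)
  for (p in TURNING_STRIDE_PARAMS) {
    v <- turning_strides[[p]]
    feats[paste0(p, "_mean")] <- mean_of(v)
    feats[paste0(p, "_cv")] <- cv_of(v)
  }
  feats
}

#' Per-subject feature vectors for all gait clusters
#'
#' Splits a labeled stride table into the four gait clusters (baseline = all
#' straight strides, constant, non-constant = acceleration plus deceleration,
#' turning) and aggregates each. The partition invariant (clusters disjoint
#' and exhaustive over segmented strides) is asserted via
#' [cluster_partition()].
#'
#' @param strides per-stride parameter `data.frame` with a `label` column
#'   holding final labels.
#' @param turns pooled per-turn `data.frame` (`n_strides`, `turning_time`).
#' @return A named numeric vector concatenating the four clusters' features,
#'   prefixed `baseline.`, `constant.`, `non_constant.`, `turning.`.
#' @export
subject_features <- function(strides, turns) {
  part <- cluster_partition(strides$label)
  stopifnot(length(part$baseline) + length(part$turning) == nrow(strides))
  c(setNames(aggregate_cluster(strides[part$baseline, , drop = FALSE]),
             paste0("baseline.", cluster_feature_names("baseline"))),
    setNames(aggregate_cluster(strides[part$constant, , drop = FALSE]),
             paste0("constant.", cluster_feature_names("constant"))),
    setNames(aggregate_cluster(strides[part$non_constant, , drop = FALSE]),
             paste0("non_constant.", cluster_feature_names("non_constant"))),
    setNames(aggregate_turning(turns, strides[part$turning, , drop = FALSE]),
             paste0("turning.", cluster_feature_names("turning"))))
}
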