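#' Write a stride-annotation JSON file
#'
#' The annotation file is the interchange format between segmentation and the
#' downstream stages (and the mechanized replacement for manual stride
#' correction): a JSON list with one object per stride carrying the half-open
#' segment window, the within-stride gait events, a phase label and bookkeeping
#' fields: `{start, end, hs, to, ms, label, foot, bout_id}`. All sample indices
#' are 0-based.
#'
#' @param segments segment `data.frame` (columns `start`, `end`, `foot`).
#' @param events optional event `data.frame` aligned with `segments`
#'   (columns `hs`, `to`, `ms`); `NA` allowed.
#' @param labels optional character vector of phase labels aligned with
#'   `segments` (`"turning"`, `"acceleration"`, `"constant"`, `"deceleration"`,
#'   `"unassigned"`).
#' @param path output path.
#' @param bout_id optional integer vector of bout ids (`NA` for turning).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, events = NULL, labels = NULL, path,
                              bout_id = NULL) {
  n <- nrow(segments)
  validate_segments(segments)
  if (is.null(events)) {
    events <- data.frame(hs = rep(NA_integer_, n), to = rep(NA_integer_, n),
                         ms = rep(NA_integer_, n))
  }
  if (is.null(labels)) labels <- rep("unassigned", n)
  if (is.null(bout_id)) bout_id <- rep(NA_integer_, n)
  if (nrow(events) != n || length(labels) != n || length(bout_id) != n) {
    stop("write_annotations: inconsistent lengths")
  }
  df <- data.frame(start = segments$start, end = segments$end,
                   hs = events$hs, to = events$to, ms = events$ms,
                   label = labels, foot = segments$foot, bout_id = bout_id,
                   stringsAsFactors = FALSE)
  jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stride-annotation JSON file
#'
#' @param path path to an annotation JSON written by [write_annotations()].
#' @return A list with `segments` (data.frame `start,end,foot`), `events`
#'   (data.frame `hs,to,ms`), `labels` (character) and `bout_id` (integer).
#' @export
read_annotations <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0L || nrow(as.data.frame(df)) == 0L) {
    return(list(
      segments = data.frame(start = integer(), end = integer(),
                            foot = character(), stringsAsFactors = FALSE),
      events = data.frame(hs = integer(), to = integer(), ms = integer()),
      labels = character(0),
      bout_id = integer(0)))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  segments <- data.frame(start = as.integer(df$start), end = as.integer(df$end),
                         foot = as.character(df$foot), stringsAsFactors = FALSE)
  validate_segments(segments)
  list(segments = segments,
       events = data.frame(hs = as.integer(df$hs), to = as.integer(df$to),
                           ms = as.integer(df$ms)),
       labels = as.character(df$label),
       bout_id = as.integer(df$bout_id))
}

#' Validate a gait-cluster partition
#'
#' Final stride labels must partition every segmented stride into exactly one
#' of the turning, constant or non-constant (acceleration or deceleration)
#' clusters; the baseline cluster is defined as all straight strides
#' (constant plus non-constant). Unassigned strides are forbidden in final
#' outputs and fail loudly here.
#'
#' @param labels character vector of final per-stride labels.
#' @return A list of index vectors `turning`, `constant`, `non_constant`,
#'   `baseline`, invisibly usable as cluster views; throws if any stride is
#'   unlabeled or carries an unknown label.
#' @export
cluster_partition <- function(labels) {
  known <- c("turning", "acceleration", "constant", "deceleration")
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0L) {
    stop("cluster_partition: unassigned or unknown label(s): ",
         paste(bad, collapse = ", "))
  }
  turning <- which(labels == "turning")
  constant <- which(labels == "constant")
  non_constant <- which(labels %in% c("acceleration", "deceleration"))
  list(turning = turning, constant = constant, non_constant = non_constant,
       baseline = sort(c(constant, non_constant)))
}
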