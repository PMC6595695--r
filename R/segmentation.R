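#' Segment strides in a GZ signal by subsequence DTW template matching
#'
#' Matches a single-stride GZ template against the medio-lateral gyroscope
#' channel by subsequence dynamic time warping (both signals are z-normalized
#' internally) and returns the non-overlapping matches with normalized DTW
#' distance at or below `distance_threshold`, selected greedily in ascending
#' distance order. Warping is bounded by restricting accepted match lengths
#' to within `band_frac` of the template length.
#'
#' @param gz numeric GZ signal (deg/s).
#' @param template single-stride template, e.g. [gz_stride_template()].
#' @param distance_threshold maximum normalized DTW distance of a match
#'   (absolute-difference cost divided by template length, on z-normalized
#'   signals).
#' @param len_range accepted match length as a fraction of the template
#'   length, `c(min, max)`; this bounds how far the warping may compress or
#'   stretch a stride.
#' @param overlap_tol maximum number of samples two accepted matches may
#'   share (adjacent strides share the boundary trough); residual overlaps
#'   are clipped at the midpoint.
#' @param foot side label attached to the segments.
#' @return A segment `data.frame` (`start`, `end`, `foot`; 0-based half-open),
#'   ordered by start. Empty for constant or too-short signals.
#' @export
dtw_segment <- function(gz, template, distance_threshold = 0.5,
                        len_range = c(0.6, 1.8), overlap_tol = 3L,
                        foot = "left") {
  empty <- data.frame(start = integer(), end = integer(),
                      foot = character(), stringsAsFactors = FALSE)
  m <- length(template)
  if (m < 10L) stop("dtw_segment: template must have >= 10 samples")
  if (length(gz) <= m) return(empty)
  if (sd(gz) == 0 || sd(template) == 0) return(empty)
  x <- (gz - mean(gz)) / sd(gz)
  y <- (template - mean(template)) / sd(template)

  res <- subsequence_dtw(x, y)
  cost <- res$cost; start <- res$start
  n <- length(x)
  len <- seq_len(n) - 1L - start + 1L      # match length ending at j (1-based j)
  min_len <- max(2L, floor(m * len_range[1]))
  max_len <- ceiling(m * len_range[2])

  # candidate endpoints: local minima of the endpoint-cost curve
  is_loc_min <- c(cost[1] <= cost[2],
                  cost[2:(n - 1)] < cost[1:(n - 2)] & cost[2:(n - 1)] <= cost[3:n],
                  cost[n] < cost[n - 1])
  cand <- which(is_loc_min & cost <= distance_threshold &
                  len >= min_len & len <= max_len)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(cost[cand], cand)]

  taken <- logical(n)
  starts <- integer(0); ends <- integer(0)
  for (j in cand) {
    s <- start[j] + 1L                     # 1-based inclusive start
    if (sum(taken[s:j]) > overlap_tol) next
    taken[s:j] <- TRUE
    starts <- c(starts, s - 1L)            # back to 0-based
    ends <- c(ends, j)                     # exclusive end = j (0-based j is j-1)
  }
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (length(starts) > 1L) {
    for (i in seq_len(length(starts) - 1L)) {
      if (ends[i] > starts[i + 1L]) {
        mid <- (ends[i] + starts[i + 1L]) %/% 2L
        ends[i] <- mid; starts[i + 1L] <- mid
      }
    }
  }
  keep <- starts < ends
  seg <- data.frame(start = starts[keep], end = ends[keep], foot = foot,
                    stringsAsFactors = FALSE)
  validate_segments(seg, n_samples = length(gz))
  seg
}

#' Refine stride boundaries to local GZ minima
#'
#' Moves every segment boundary to the nearest strict local minimum of the GZ
#' signal within `search_radius` samples (boundaries already at a local
#' minimum are fixed points, so refinement is idempotent). If refined
#' boundaries of neighbouring segments would overlap, the conflicting
#' boundaries are clipped to their midpoint.
#'
#' @param gz numeric GZ signal.
#' @param segments segment `data.frame` (non-overlapping, one foot).
#' @param search_radius search radius in samples.
#' @return The refined segment `data.frame`.
#' @export
refine_by_minima <- function(gz, segments, search_radius = 10L) {
  if (nrow(segments) == 0L) return(segments)
  validate_segments(segments, n_samples = length(gz))
  n <- length(gz)
  interior <- which(gz[2:(n - 1)] < gz[1:(n - 2)] & gz[2:(n - 1)] < gz[3:n]) + 1L
  minima0 <- interior - 1L                  # 0-based local-minimum positions

  snap <- function(b) {
    if (length(minima0) == 0L) return(b)
    d <- abs(minima0 - b)
    k <- which(d <= search_radius)
    if (length(k) == 0L) return(b)
    k <- k[order(d[k], minima0[k])][1L]
    minima0[k]
  }
  for (f in unique(segments$foot)) {
    idx <- which(segments$foot == f)
    idx <- idx[order(segments$start[idx])]
    s <- vapply(segments$start[idx], snap, numeric(1))
    e <- vapply(segments$end[idx], snap, numeric(1))
    # restore validity: starts before ends, clip overlaps to midpoints
    bad <- e <= s
    s[bad] <- segments$start[idx][bad]; e[bad] <- segments$end[idx][bad]
    if (length(idx) > 1L) {
      for (i in seq_len(length(idx) - 1L)) {
        if (e[i] > s[i + 1L]) {
          mid <- (e[i] + s[i + 1L]) %/% 2L
          e[i] <- mid; s[i + 1L] <- mid
        }
      }
    }
    segments$start[idx] <- as.integer(s)
    segments$end[idx] <- as.integer(e)
  }
  validate_segments(segments, n_samples = length(gz))
  segments
}

#' Apply file-driven corrections to a segment list
#'
#' Mechanized replacement for manual stride correction: applies an ordered
#' edit list (additions, deletions, replacements) to an automatically
#' segmented stride list. Deletions and replacements reference the existing
#' segment by its `start` index.
#'
#' @param segments segment `data.frame`.
#' @param edits either a path to a JSON edit file or a `data.frame`/list of
#'   edits with fields `action` (`"add"`, `"delete"`, `"replace"`), `start`,
#'   `end`, `foot` and (for `replace`) `target_start`.
#' @return The corrected, validated segment `data.frame` ordered by start.
#' @export
apply_corrections <- function(segments, edits) {
  if (is.character(edits) && length(edits) == 1L) {
    edits <- jsonlite::read_json(edits, simplifyVector = TRUE)
  }
  edits <- as.data.frame(edits, stringsAsFactors = FALSE)
  if (nrow(edits) == 0L) return(segments)
  for (i in seq_len(nrow(edits))) {
    ed <- edits[i, ]
    if (ed$action == "add") {
      segments <- rbind(segments,
                        data.frame(start = as.integer(ed$start),
                                   end = as.integer(ed$end),
                                   foot = as.character(ed$foot),
                                   stringsAsFactors = FALSE))
    } else if (ed$action == "delete") {
      hit <- segments$start == ed$target_start & segments$foot == ed$foot
      if (!any(hit)) stop("apply_corrections: no segment with start ", ed$target_start)
      segments <- segments[!hit, , drop = FALSE]
    } else if (ed$action == "replace") {
      hit <- which(segments$start == ed$target_start & segments$foot == ed$foot)
      if (length(hit) == 0L) {
        stop("apply_corrections: no segment with start ", ed$target_start)
      }
      segments$start[hit] <- as.integer(ed$start)
      segments$end[hit] <- as.integer(ed$end)
    } else {
      stop("apply_corrections: unknown action '", ed$action, "'")
    }
  }
  segments <- segments[order(segments$foot, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  validate_segments(segments)
  segments
}
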