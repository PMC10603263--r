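# Nearest-neighbor machinery: point-to-polyline distances, KMT minus-end
# branching detection, and global microtubule-microtubule interaction
# mapping.

#' Distance from a point to a microtubule polyline
#'
#' Exact minimum Euclidean distance from a 3D point to the union of the
#' polyline's segments (segment-exact, not vertex-sampled, so the result
#' does not depend on the resampling density), together with the
#' arc-length position of the closest (foot) point.
#'
#' @param p length-3 point (nm).
#' @param mt a [microtubule()] or n x 3 coordinate matrix.
#' @return Named numeric vector `c(distance, arc)` in nm.
#' @export
point_to_polyline_distance <- function(p, mt) {
  pts <- .metric_points(mt)
  stopifnot(nrow(pts) >= 2, length(p) == 3)
  r <- .points_polyline_mindist(matrix(p, 1), pts)
  c(distance = r$dist, arc = r$arc)
}

.mt_class_vec <- function(spindle) vapply(spindle$microtubules, `[[`, "", "mt_class")

.empty_interactions <- function() {
  data.frame(kind = character(0), source_mt = integer(0),
             target_mt = integer(0), target_class = character(0),
             distance_nm = numeric(0), source_position_nm = numeric(0),
             target_position_nm = numeric(0),
             interaction_length_nm = numeric(0), stringsAsFactors = FALSE)
}

#' Detect KMT minus-end branching
#'
#' For each KMT minus end, finds the single closest other microtubule
#' (segment-exact distance to its spline) and emits one branch record iff
#' that distance is at most `threshold` (default 25 nm).  Ties on the
#' closest microtubule are broken toward the lower microtubule id; records
#' report whether the branch target is itself a KMT or a non-KMT.
#'
#' @param spindle a `spindle` with plus/minus ends assigned.
#' @param threshold maximal minus-end-to-spline distance in nm.
#' @param exclude_same_fiber also skip candidate microtubules of the same
#'   k-fiber (default `FALSE`: only the KMT itself is excluded).
#' @return Data frame of branch records: `kind = "branch"`, `source_mt`
#'   (the KMT), `target_mt`, `target_class`, `distance_nm`,
#'   `source_position_nm` (arc position of the foot on the target),
#'   `interaction_length_nm` (`NA` for branches).
#' @export
detect_kmt_branching <- function(spindle, threshold = 25,
                                 exclude_same_fiber = FALSE) {
  stopifnot(threshold > 0)
  mts <- spindle$microtubules
  cls <- .mt_class_vec(spindle)
  kmts <- which(cls == "KMT")
  out <- .empty_interactions()
  for (i in kmts) {
    mt <- mts[[i]]
    if (is.na(mt$plus_end)) stop("plus/minus ends not assigned (mt ", i, ")")
    p <- .minus_end_point(mt)
    best_d <- Inf; best_j <- NA_integer_; best_arc <- NA_real_
    for (j in seq_along(mts)) {
      if (j == i) next
      if (exclude_same_fiber && !is.na(mt$fiber_id) &&
          identical(mts[[j]]$fiber_id, mt$fiber_id)) next
      r <- .points_polyline_mindist(matrix(p, 1), mts[[j]]$points)
      if (r$dist < best_d - 1e-12 ||
          (abs(r$dist - best_d) <= 1e-12 && !is.na(best_j) && j < best_j)) {
        best_d <- r$dist; best_j <- j; best_arc <- r$arc
      }
    }
    if (!is.na(best_j) && best_d <= threshold) {
      minus_arc <- if (identical(mt$plus_end, "last")) 0 else
        .polyline_length(mt$points)
      out <- rbind(out, data.frame(
        kind = "branch", source_mt = mt$mt_id, target_mt = mts[[best_j]]$mt_id,
        target_class = cls[best_j], distance_nm = best_d,
        source_position_nm = minus_arc, target_position_nm = best_arc,
        interaction_length_nm = NA_real_, stringsAsFactors = FALSE))
    }
  }
  out
}

## Interaction runs of one ordered (source, target) microtubule pair.
.pair_runs <- function(src_pts, tgt_pts, threshold) {
  r <- .points_polyline_mindist(src_pts, tgt_pts)
  within <- r$dist <= threshold
  if (!any(within)) return(NULL)
  arc <- .arc_lengths(src_pts)
  runs <- rle(within)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(start = arc[starts[keep]],
             len = arc[ends[keep]] - arc[starts[keep]],
             dist = vapply(keep, function(k) {
               min(r$dist[starts[k]:ends[k]])
             }, 1))
}

#' Detect global microtubule-microtubule interactions
#'
#' For every unordered pair of microtubules with any approach within
#' `threshold` (default 100 nm), emits one record per maximal contiguous
#' run of source sample points lying within `threshold` of the target
#' spline; both orientations of each pair are reported, so every
#' interaction is discoverable from either partner.  `source_position_nm`
#' is the arc-length start of the run on the source and
#' `interaction_length_nm` its arc-length extent (source-side accounting;
#' assumes uniform resampling).  Candidate pairs are pruned with
#' axis-aligned bounding boxes expanded by `threshold`; with
#' `brute_force = TRUE` every pair is tested, which is the reference
#' all-pairs path (results are identical).
#'
#' @param spindle a resampled `spindle`.
#' @param threshold interaction distance in nm.
#' @param brute_force disable the bounding-box spatial pruning.
#' @return Data frame of proximity records (see [detect_kmt_branching()]
#'   for the shared schema).
#' @export
detect_mt_interactions <- function(spindle, threshold = 100,
                                   brute_force = FALSE) {
  stopifnot(threshold > 0)
  mts <- spindle$microtubules
  cls <- .mt_class_vec(spindle)
  n <- length(mts)
  out <- .empty_interactions()
  if (n < 2L) return(out)
  boxes <- lapply(mts, function(m) .bbox(m$points, pad = threshold / 2))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!brute_force && !.bbox_overlap(boxes[[i]], boxes[[j]])) next
      for (ord in list(c(i, j), c(j, i))) {
        runs <- .pair_runs(mts[[ord[1]]]$points, mts[[ord[2]]]$points, threshold)
        if (is.null(runs)) next
        out <- rbind(out, data.frame(
          kind = "proximity", source_mt = mts[[ord[1]]]$mt_id,
          target_mt = mts[[ord[2]]]$mt_id, target_class = cls[ord[2]],
          distance_nm = runs$dist, source_position_nm = runs$start,
          target_position_nm = NA_real_,
          interaction_length_nm = runs$len, stringsAsFactors = FALSE))
      }
    }
  }
  out
}
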