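# Spindle data model and preprocessing: classification, resampling,
# reorientation onto the pole-to-pole axis, plus/minus-end assignment,
# k-fiber construction and sister pairing.

#' Construct a microtubule
#'
#' One ordered 3D polyline with identity and class.  Coordinates are in nm;
#' consecutive duplicate points are removed.
#'
#' @param points numeric matrix (n x 3), n >= 2, coordinates in nm.
#' @param mt_id integer id.
#' @param mt_class `"KMT"` or `"nonKMT"`.
#' @param fiber_id optional integer k-fiber membership.
#' @return An object of class `microtubule` with fields `mt_id`, `points`,
#'   `mt_class`, `fiber_id`, `plus_end` (`"first"`/`"last"`/`NA`),
#'   `pole_id`, and flags.
#' @export
microtubule <- function(points, mt_id = 1L, mt_class = c("nonKMT", "KMT"),
                        fiber_id = NA_integer_) {
  mt_class <- match.arg(mt_class)
  points <- .dedupe_points(as.matrix(points))
  stopifnot(nrow(points) >= 2, ncol(points) == 3, all(is.finite(points)))
  structure(list(mt_id = as.integer(mt_id), points = points,
                 mt_class = mt_class, fiber_id = as.integer(fiber_id),
                 plus_end = NA_character_, pole_id = NA_character_,
                 tie = FALSE, degenerate = FALSE),
            class = "microtubule")
}

#' @export
print.microtubule <- function(x, ...) {
  cat("microtubule ", x$mt_id, " (", x$mt_class, "): ", nrow(x$points),
      " points, length ", round(.polyline_length(x$points), 1), " nm\n", sep = "")
  invisible(x)
}

#' Construct a spindle
#'
#' The container for all microtubules of one spatial graph plus the two
#' spindle poles.  Poles can be supplied or estimated later with
#' [estimate_poles()].
#'
#' @param microtubules list of [microtubule()] objects.
#' @param pole1,pole2 optional length-3 pole coordinates (nm).
#' @param graph_id integer id of the source spatial graph.
#' @param axis spindle axis the reorientation maps the pole-to-pole line
#'   onto: `"z"` (default), `"x"` or `"y"`.
#' @param resample_spacing nm spacing used/assumed by resampling.
#' @return An object of class `spindle`.
#' @export
new_spindle <- function(microtubules, pole1 = NULL, pole2 = NULL,
                        graph_id = 1L, axis = c("z", "x", "y"),
                        resample_spacing = 20) {
  axis <- match.arg(axis)
  stopifnot(all(vapply(microtubules, inherits, TRUE, "microtubule")))
  if (!is.null(pole1) && !is.null(pole2) &&
      sqrt(sum((pole1 - pole2)^2)) < 1e-9) {
    stop("pole1 and pole2 coincide")
  }
  structure(list(graph_id = as.integer(graph_id),
                 microtubules = microtubules,
                 fibers = NULL,
                 pole1 = pole1, pole2 = pole2, axis = axis,
                 resample_spacing = resample_spacing),
            class = "spindle")
}

#' @export
print.spindle <- function(x, ...) {
  cls <- vapply(x$microtubules, `[[`, "", "mt_class")
  cat("spindle (graph ", x$graph_id, "): ", length(x$microtubules),
      " microtubules (", sum(cls == "KMT"), " KMT, ", sum(cls == "nonKMT"),
      " non-KMT), ", length(x$fibers), " k-fibers\n", sep = "")
  if (!is.null(x$pole1)) {
    cat("poles: (", paste(round(x$pole1, 1), collapse = ", "), ") and (",
        paste(round(x$pole2, 1), collapse = ", "), ") nm\n", sep = "")
  }
  invisible(x)
}

.axis_unit <- function(spindle) {
  switch(spindle$axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
}

#' Convert a spatial graph to a spindle
#'
#' Builds [microtubule()] objects from the edges of a `spatial_graph`,
#' classifying each edge as KMT when its KMT label field is nonzero and
#' reading optional k-fiber membership from an integer edge field.
#' Coordinates are converted to nm.
#'
#' @param graph a `spatial_graph` from [read_spatial_graph()].
#' @param kmt_field name of the KMT label field (any nonzero value marks a
#'   KMT); aliases are tried in order.
#' @param fiber_field name of the k-fiber membership field; values > 0 are
#'   fiber ids.
#' @inheritParams new_spindle
#' @return A `spindle`.
#' @export
as_spindle <- function(graph, pole1 = NULL, pole2 = NULL,
                       kmt_field = "KMT", fiber_field = "KFiberID",
                       axis = c("z", "x", "y"), resample_spacing = 20) {
  stopifnot(inherits(graph, "spatial_graph"))
  axis <- match.arg(axis)
  scale <- if (identical(graph$units, "um")) 1000 else 1
  kf <- kmt_field[kmt_field %in% names(graph$labels)]
  ff <- fiber_field[fiber_field %in% names(graph$labels)]
  n_e <- length(graph$num_edge_points)
  mts <- vector("list", n_e)
  for (i in seq_len(n_e)) {
    is_kmt <- length(kf) > 0L && graph$labels[[kf[1]]][i] != 0L
    fid <- if (length(ff) > 0L && graph$labels[[ff[1]]][i] > 0L) {
      graph$labels[[ff[1]]][i]
    } else NA_integer_
    mts[[i]] <- microtubule(.sg_edge_points(graph, i) * scale, mt_id = i,
                            mt_class = if (is_kmt) "KMT" else "nonKMT",
                            fiber_id = fid)
  }
  new_spindle(mts, pole1 = pole1, pole2 = pole2, graph_id = graph$graph_id,
              axis = axis, resample_spacing = resample_spacing)
}

#' Convert a spindle back to a spatial graph
#'
#' Inverse of [as_spindle()]: emits a `spatial_graph` with `KMT` and
#' `KFiberID` per-edge label fields, suitable for [write_spatial_graph()].
#'
#' @param spindle a `spindle`.
#' @return A `spatial_graph` (coordinates in nm).
#' @export
as_spatial_graph <- function(spindle) {
  stopifnot(inherits(spindle, "spindle"))
  polys <- lapply(spindle$microtubules, `[[`, "points")
  kmt <- as.integer(vapply(spindle$microtubules, `[[`, "", "mt_class") == "KMT")
  fid <- vapply(spindle$microtubules, `[[`, 1L, "fiber_id")
  fid[is.na(fid)] <- 0L
  spatial_graph_from_polylines(polys, labels = list(KMT = kmt, KFiberID = fid),
                               graph_id = spindle$graph_id, units = "nm")
}

#' Resample to uniform point spacing
#'
#' Resamples a polyline to a uniform arc-length point distance (default
#' 20 nm).  The resampled track lies exactly on the original polyline,
#' endpoints are preserved, interior points are spaced exactly `spacing`
#' apart in arc length with a final interval <= `spacing`.  A microtubule
#' shorter than `spacing` collapses to its two endpoints and is flagged
#' degenerate.
#'
#' @param x a [microtubule()], a `spindle` (all microtubules resampled), or
#'   a coordinate matrix.
#' @param spacing target point distance in nm (> 0).
#' @return Same class as `x`.
#' @export
resample_uniform <- function(x, spacing = 20) UseMethod("resample_uniform")

#' @export
resample_uniform.matrix <- function(x, spacing = 20) .resample_polyline(x, spacing)

#' @export
resample_uniform.microtubule <- function(x, spacing = 20) {
  pts <- .resample_polyline(x$points, spacing)
  x$degenerate <- isTRUE(attr(pts, "degenerate"))
  attr(pts, "degenerate") <- NULL
  x$points <- pts
  x
}

#' @export
resample_uniform.spindle <- function(x, spacing = x$resample_spacing) {
  x$microtubules <- lapply(x$microtubules, resample_uniform, spacing = spacing)
  x$resample_spacing <- spacing
  x
}

#' Estimate the spindle poles from KMT geometry
#'
#' When pole positions are not supplied, they are estimated as the two
#' centroids of the poleward (outer) KMT endpoints, clustered by hemisphere
#' along the first principal axis of all microtubule points.  Pole 1 is the
#' pole at the lower principal-axis coordinate.
#'
#' @param spindle a `spindle` with at least one KMT (falls back to all
#'   microtubules when no KMTs are labeled).
#' @return The `spindle` with `pole1`/`pole2` set.
#' @export
estimate_poles <- function(spindle) {
  mts <- spindle$microtubules
  use <- Filter(function(m) m$mt_class == "KMT", mts)
  if (length(use) < 2L) use <- mts
  allpts <- do.call(rbind, lapply(mts, `[[`, "points"))
  ctr <- colMeans(allpts)
  ax <- stats::prcomp(allpts, center = TRUE, scale. = FALSE)$rotation[, 1]
  ends <- do.call(rbind, lapply(use, function(m) {
    e <- m$points[c(1L, nrow(m$points)), ]
    # the outer end (farther from the spindle center along the axis) points
    # poleward in a bipolar spindle
    proj <- as.numeric((e - rep(ctr, each = 2)) %*% ax)
    e[which.max(abs(proj)), , drop = FALSE]
  }))
  proj <- as.numeric(sweep(ends, 2, ctr) %*% ax)
  if (all(proj >= 0) || all(proj <= 0)) {
    stop("pole estimation failed: all poleward ends lie in one hemisphere")
  }
  p1 <- colMeans(ends[proj < 0, , drop = FALSE])
  p2 <- colMeans(ends[proj >= 0, , drop = FALSE])
  spindle$pole1 <- p1
  spindle$pole2 <- p2
  spindle
}

#' Reorient the spindle onto its pole-to-pole axis
#'
#' Applies one rigid transform (proper rotation + translation, never a
#' reflection, so twist handedness is preserved) to every point and both
#' poles, mapping pole 1 to the origin and the pole-to-pole line onto the
#' configured axis (default +z).  Afterwards the two poles agree in both
#' off-axis coordinates; all pairwise distances are preserved.
#'
#' @param spindle a `spindle` with both poles set.
#' @return The reoriented `spindle`.
#' @export
reorient_to_axis <- function(spindle) {
  if (is.null(spindle$pole1) || is.null(spindle$pole2)) {
    stop("both poles must be set (see estimate_poles)")
  }
  u <- spindle$pole2 - spindle$pole1
  if (sqrt(sum(u^2)) < 1e-9) stop("poles coincide")
  e <- .axis_unit(spindle)
  R <- .rotation_between(u, e)
  p1 <- spindle$pole1
  tf <- function(m) t(R %*% (t(m) - p1))
  spindle$microtubules <- lapply(spindle$microtubules, function(mt) {
    mt$points <- tf(mt$points)
    mt
  })
  spindle$pole2 <- as.numeric(tf(matrix(spindle$pole2, 1)))
  spindle$pole1 <- c(0, 0, 0)
  off <- spindle$pole2 - sum(spindle$pole2 * e) * e
  if (max(abs(off)) > 1e-6) {
    warning("off-axis pole residual ", format(max(abs(off))), " nm")
  }
  if (!is.null(spindle$fibers)) {
    spindle <- build_kfibers(spindle, if (is.null(spindle$twist_step)) 500 else spindle$twist_step)
  }
  spindle
}

## Axial coordinate (nm) of points along the pole1 -> pole2 direction.
.axial_coord <- function(spindle, pts) {
  a <- .normalize(spindle$pole2 - spindle$pole1)
  as.numeric(sweep(matrix(pts, ncol = 3), 2, spindle$pole1) %*% a)
}

#' Assign plus and minus ends to KMTs
#'
#' For every KMT, the polyline end whose axial position is farther from its
#' associated pole is marked as the plus end (KMT plus ends terminate at
#' kinetochores near the spindle equator; minus ends point poleward).  The
#' associated pole is the pole closer to the nearer endpoint.  Axial ties
#' are broken toward the first point and flagged.
#'
#' @param spindle a `spindle` with both poles set.
#' @return The `spindle` with `plus_end` and `pole_id` set on every KMT.
#' @export
infer_plus_minus_ends <- function(spindle) {
  if (is.null(spindle$pole1) || is.null(spindle$pole2)) {
    stop("both poles must be set (see estimate_poles)")
  }
  a <- .normalize(spindle$pole2 - spindle$pole1)
  ax_p <- c(0, sum((spindle$pole2 - spindle$pole1) * a))
  spindle$microtubules <- lapply(spindle$microtubules, function(mt) {
    if (mt$mt_class != "KMT") return(mt)
    ends <- mt$points[c(1L, nrow(mt$points)), ]
    d1 <- sqrt(rowSums(sweep(ends, 2, spindle$pole1)^2))
    d2 <- sqrt(rowSums(sweep(ends, 2, spindle$pole2)^2))
    pole <- if (min(d1) <= min(d2)) 1L else 2L
    mt$pole_id <- paste0("pole", pole)
    ax_e <- .axial_coord(spindle, ends)
    far <- abs(ax_e - ax_p[pole])
    if (abs(far[1] - far[2]) < 1e-9) {
      mt$plus_end <- "first"
      mt$tie <- TRUE
    } else {
      mt$plus_end <- if (far[1] > far[2]) "first" else "last"
      mt$tie <- FALSE
    }
    mt
  })
  spindle
}

## Points of a KMT ordered plus end first.
.oriented_points <- function(mt) {
  if (identical(mt$plus_end, "last")) {
    mt$points[rev(seq_len(nrow(mt$points))), , drop = FALSE]
  } else {
    mt$points
  }
}

.plus_end_point <- function(mt) .oriented_points(mt)[1L, ]
.minus_end_point <- function(mt) {
  p <- .oriented_points(mt)
  p[nrow(p), ]
}

## Sample every member KMT of a fiber at arc-length steps of `step` from
## its plus end.  Returns center curve (mean over members present at each
## step), per-step member coordinates, and presence mask.  Steps are kept
## while at least min(2, n_members) members reach them.
.fiber_step_samples <- function(spindle, kmt_ids, step) {
  mts <- spindle$microtubules[kmt_ids]
  n <- length(mts)
  lens <- vapply(mts, function(m) .polyline_length(m$points), 1)
  need <- min(2L, n)
  nstep <- 0L
  repeat {
    if (sum(lens >= (nstep + 1L) * step) < need) break
    nstep <- nstep + 1L
  }
  k <- nstep + 1L  # includes position 0
  pos <- (seq_len(k) - 1L) * step
  member <- array(NA_real_, c(n, k, 3))
  present <- matrix(FALSE, n, k)
  for (j in seq_len(n)) {
    op <- .oriented_points(mts[[j]])
    for (s in seq_len(k)) {
      if (lens[j] >= pos[s] - 1e-9) {
        member[j, s, ] <- .point_at_arc(op, pos[s])
        present[j, s] <- TRUE
      }
    }
  }
  center <- matrix(NA_real_, k, 3)
  for (s in seq_len(k)) {
    sel <- which(present[, s])
    center[s, ] <- colMeans(matrix(member[sel, s, ], ncol = 3))
  }
  list(positions = pos, center = center, member = member, present = present,
       kmt_ids = kmt_ids)
}

#' Build k-fibers from per-KMT fiber labels
#'
#' Groups KMTs by their `fiber_id`, computes each fiber's plus-end centroid
#' (mean 3D position of member plus ends — the k-fiber plus end used for
#' the outer-kinetochore distance) and its center curve: member KMTs are
#' sampled at arc-length steps of `twist_step` from their plus ends and the
#' center at each step is the mean over members reaching that step (the
#' curve is truncated when fewer than two members remain; a single-KMT
#' fiber uses its own track).
#'
#' @param spindle a `spindle` with plus/minus ends assigned (see
#'   [infer_plus_minus_ends()]).
#' @param twist_step sampling step of the center curve in nm.
#' @return The `spindle` with a list of k-fibers (`fiber_id`, `kmt_ids`,
#'   `center_curve`, `plus_end_centroid`, `pole_id`, `sister_fiber_id`).
#' @export
build_kfibers <- function(spindle, twist_step = 500) {
  mts <- spindle$microtubules
  fids <- vapply(mts, `[[`, 1L, "fiber_id")
  cls <- vapply(mts, `[[`, "", "mt_class")
  sel <- which(cls == "KMT" & !is.na(fids))
  if (length(sel) == 0L) {
    warning("no k-fiber membership labels; fibers not built", call. = FALSE)
    return(spindle)
  }
  if (any(vapply(mts[sel], function(m) is.na(m$plus_end), TRUE))) {
    spindle <- infer_plus_minus_ends(spindle)
    mts <- spindle$microtubules
  }
  fibers <- list()
  for (f in sort(unique(fids[sel]))) {
    ids <- sel[fids[sel] == f]
    poles <- unique(vapply(mts[ids], `[[`, "", "pole_id"))
    if (length(poles) > 1L) {
      stop("k-fiber ", f, ": member KMTs disagree on pole (",
           paste(poles, collapse = ", "), ")")
    }
    plus <- t(vapply(mts[ids], .plus_end_point, numeric(3)))
    samp <- .fiber_step_samples(spindle, ids, twist_step)
    fibers[[as.character(f)]] <- structure(list(
      fiber_id = as.integer(f), kmt_ids = ids,
      center_curve = samp$center, step = twist_step,
      plus_end_centroid = colMeans(plus),
      pole_id = poles, sister_fiber_id = NA_integer_),
      class = "kfiber")
  }
  spindle$fibers <- fibers
  spindle$twist_step <- twist_step
  spindle
}

#' Pair sister k-fibers
#'
#' Pairs fibers from opposite poles whose plus-end centroids are mutually
#' nearest and whose pole-to-centroid directions are antiparallel within a
#' cone (default 60 degrees), i.e. the two kinetochores face each other.
#' Non-mutual or misaligned candidates are left unpaired with a warning.
#'
#' @param spindle a `spindle` with fibers built.
#' @param cone_deg maximal deviation from antiparallel in degrees.
#' @return The `spindle` with `sister_fiber_id` set on paired fibers.
#' @export
pair_sister_kfibers <- function(spindle, cone_deg = 60) {
  if (is.null(spindle$fibers) || length(spindle$fibers) == 0L) {
    warning("no fibers to pair", call. = FALSE)
    return(spindle)
  }
  fb <- spindle$fibers
  poles <- vapply(fb, `[[`, "", "pole_id")
  i1 <- which(poles == "pole1")
  i2 <- which(poles == "pole2")
  if (length(i1) == 0L || length(i2) == 0L) {
    warning("all fibers on one pole; nothing to pair", call. = FALSE)
    return(spindle)
  }
  cen <- t(vapply(fb, `[[`, numeric(3), "plus_end_centroid"))
  dir <- t(vapply(seq_along(fb), function(i) {
    p <- if (poles[i] == "pole1") spindle$pole1 else spindle$pole2
    .normalize(cen[i, ] - p)
  }, numeric(3)))
  D <- as.matrix(stats::dist(cen))[i1, i2, drop = FALSE]
  best12 <- apply(D, 1, which.min)
  best21 <- apply(D, 2, which.min)
  unpaired <- 0L
  for (a in seq_along(i1)) {
    b <- best12[a]
    if (best21[b] != a) { unpaired <- unpaired + 1L; next }
    ang <- acos(pmin(pmax(-sum(dir[i1[a], ] * dir[i2[b], ]), -1), 1)) * 180 / pi
    if (ang > cone_deg) { unpaired <- unpaired + 1L; next }
    fb[[i1[a]]]$sister_fiber_id <- fb[[i2[b]]]$fiber_id
    fb[[i2[b]]]$sister_fiber_id <- fb[[i1[a]]]$fiber_id
  }
  n_un <- sum(vapply(fb, function(f) is.na(f$sister_fiber_id), TRUE))
  if (n_un > 0L) {
    warning(n_un, " fiber(s) left unpaired", call. = FALSE)
  }
  spindle$fibers <- fb
  spindle
}

#' Run the standard preprocessing chain
#'
#' Resample, estimate poles (if absent), reorient onto the spindle axis,
#' assign plus/minus ends, build k-fibers and pair sisters — the
#' standardization every analysis assumes.
#'
#' @param spindle a `spindle`.
#' @param spacing resample spacing in nm.
#' @param twist_step center-curve sampling step in nm.
#' @param cone_deg sister-pairing antiparallel cone in degrees.
#' @return The preprocessed `spindle`.
#' @export
preprocess_spindle <- function(spindle, spacing = 20, twist_step = 500,
                               cone_deg = 60) {
  spindle <- resample_uniform(spindle, spacing)
  if (is.null(spindle$pole1) || is.null(spindle$pole2)) {
    spindle <- estimate_poles(spindle)
  }
  spindle <- reorient_to_axis(spindle)
  spindle <- infer_plus_minus_ends(spindle)
  has_fib <- any(vapply(spindle$microtubules,
                        function(m) m$mt_class == "KMT" && !is.na(m$fiber_id),
                        TRUE))
  if (has_fib) {
    spindle <- build_kfibers(spindle, twist_step)
    spindle <- pair_sister_kfibers(spindle, cone_deg)
  }
  spindle
}
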