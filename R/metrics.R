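# Scalar and profile statistics: length, tortuosity, twist, helicity,
# cross-section area, KMT packing density, outer-kinetochore distance and
# KMT-number statistics.

#' Microtubule length
#'
#' Total track length: the sum of Euclidean distances between consecutive
#' 3D points of the polyline.  Always at least the endpoint chord length.
#'
#' @param x a [microtubule()], a `kfiber` (length of its center curve), or
#'   an n x 3 coordinate matrix.
#' @return Length in nm.
#' @examples
#' polyline_length(rbind(c(0, 0, 0), c(3000, 4000, 0)))  # 5000
#' @export
polyline_length <- function(x) {
  pts <- .metric_points(x)
  .polyline_length(pts)
}

.metric_points <- function(x) {
  if (inherits(x, "microtubule")) x$points
  else if (inherits(x, "kfiber")) x$center_curve
  else as.matrix(x)
}

#' Tortuosity
#'
#' Ratio of track length to the straight endpoint distance: 1 for a
#' straight line, pi/2 (1.57) for a half-circle, growing without bound for
#' closed shapes.  With a `window` (nm), local tortuosity is computed on
#' sliding arc-length windows anchored at each point and reported at the
#' window centers.  Fiber tortuosity is the tortuosity of the fiber center
#' curve.
#'
#' @param x a [microtubule()], `kfiber`, or coordinate matrix.
#' @param window `NULL` for total tortuosity, or a window extent in nm.
#' @return A single ratio, or a data frame (`position`, `tortuosity`) in
#'   local mode.  Coincident endpoints give `Inf`.
#' @export
tortuosity <- function(x, window = NULL) {
  pts <- .metric_points(x)
  stopifnot(nrow(pts) >= 2)
  if (is.null(window)) {
    l <- .chord_length(pts)
    L <- .polyline_length(pts)
    return(if (l == 0) Inf else L / l)
  }
  stopifnot(window > 0)
  arc <- .arc_lengths(pts)
  L <- arc[length(arc)]
  if (window > L) stop("window (", window, " nm) exceeds polyline length (",
                       round(L, 1), " nm)")
  out <- data.frame(position = numeric(0), tortuosity = numeric(0))
  for (i in seq_len(nrow(pts))) {
    if (arc[i] + window > L + 1e-9) break
    j <- max(which(arc <= arc[i] + window + 1e-9))
    seg <- pts[i:j, , drop = FALSE]
    l <- .chord_length(seg)
    out <- rbind(out, data.frame(position = (arc[i] + arc[j]) / 2,
                                 tortuosity = if (l == 0) Inf else
                                   (arc[j] - arc[i]) / l))
  }
  out
}

#' Per-microtubule length table
#'
#' One row per microtubule of the requested class with its track length,
#' followed by summary rows (mean, median, n).
#'
#' @param spindle a `spindle`.
#' @param mt_class `"KMT"`, `"nonKMT"`, or `"all"`.
#' @return A `metric_table` with columns `graph_id`, `object_id`,
#'   `position`, `value`, `units`.
#' @export
length_distribution <- function(spindle, mt_class = c("KMT", "nonKMT", "all")) {
  mt_class <- match.arg(mt_class)
  mts <- spindle$microtubules
  if (mt_class != "all") {
    mts <- Filter(function(m) m$mt_class == mt_class, mts)
  }
  if (length(mts) == 0L) {
    warning("no microtubules of class ", mt_class, call. = FALSE)
    return(metric_table("length", .mt_rows(spindle$graph_id,
                                           character(0), numeric(0), "nm")))
  }
  lens <- vapply(mts, function(m) .polyline_length(m$points), 1)
  ids <- as.character(vapply(mts, `[[`, 1L, "mt_id"))
  df <- .mt_rows(spindle$graph_id,
                 c(ids, "mean", "median", "n"),
                 c(lens, mean(lens), stats::median(lens), length(lens)),
                 "nm")
  metric_table("length", df)
}

.mt_rows <- function(graph_id, object_id, value, units, position = NA_real_) {
  data.frame(graph_id = rep(graph_id, length(value)),
             object_id = object_id,
             position = rep_len(position, length(value)),
             value = value,
             units = rep_len(units, length(value)),
             stringsAsFactors = FALSE)
}

.get_fiber <- function(spindle, fiber_id) {
  f <- spindle$fibers[[as.character(fiber_id)]]
  if (is.null(f)) stop("no such fiber: ", fiber_id)
  f
}

## Per-step radial vectors of member KMTs about the fiber center, projected
## into the plane normal to the local center-curve tangent.
.twist_frames <- function(spindle, fiber) {
  samp <- .fiber_step_samples(spindle, fiber$kmt_ids, fiber$step)
  tg <- .polyline_tangents(samp$center)
  list(samp = samp, tangents = tg)
}

#' Local k-fiber twist
#'
#' At arc-length steps (default 500 nm) along the microtubule lattice, each
#' KMT's radial vector about the fiber center is projected into the plane
#' normal to the local center-curve tangent, and the signed angle rotating
#' the vector at step i onto that at step i+1 is measured in degrees.  The
#' per-step fiber twist is the mean over contributing KMTs.  The sign is
#' right-handed about the pole-to-pole axis direction (pole 1 to pole 2);
#' mirror reflection of the spindle flips all signs.
#'
#' @param spindle a `spindle` with fibers built.
#' @param fiber_id fiber to analyze.
#' @return Data frame with `step_index`, `position` (nm, window center),
#'   `twist_deg`, `n_kmt`; zero rows when the fiber spans fewer than two
#'   steps.
#' @export
local_twist <- function(spindle, fiber_id) {
  fiber <- .get_fiber(spindle, fiber_id)
  fr <- .twist_frames(spindle, fiber)
  samp <- fr$samp
  k <- length(samp$positions)
  axis_ref <- .normalize(spindle$pole2 - spindle$pole1)
  out <- data.frame(step_index = integer(0), position = numeric(0),
                    twist_deg = numeric(0), n_kmt = integer(0))
  if (k < 2) return(out)
  n <- length(fiber$kmt_ids)
  for (s in seq_len(k - 1L)) {
    tg <- fr$tangents[s, ]
    ref <- if (sum(tg * axis_ref) >= 0) tg else -tg
    common <- which(samp$present[, s] & samp$present[, s + 1L])
    if (length(common) == 0L) next
    # centers over the members present at BOTH steps, so a KMT ending
    # between the steps cannot shift the center and fake a rotation
    c1 <- colMeans(matrix(samp$member[common, s, ], ncol = 3))
    c2 <- colMeans(matrix(samp$member[common, s + 1L, ], ncol = 3))
    angs <- numeric(0)
    for (j in common) {
      r1 <- samp$member[j, s, ] - c1
      r2 <- samp$member[j, s + 1L, ] - c2
      r1 <- r1 - sum(r1 * ref) * ref
      r2 <- r2 - sum(r2 * ref) * ref
      if (sqrt(sum(r1^2)) < 1e-9 || sqrt(sum(r2^2)) < 1e-9) next
      angs <- c(angs, .signed_angle_deg(r1, r2, ref))
    }
    if (length(angs) == 0L) next
    out <- rbind(out, data.frame(
      step_index = s,
      position = (samp$positions[s] + samp$positions[s + 1L]) / 2,
      twist_deg = mean(angs), n_kmt = length(angs)))
  }
  out
}

#' Total k-fiber twist
#'
#' Sum of all local (per-step mean) twists along the fiber, in degrees.  A
#' randomly zig-zagging fiber cancels toward 0; a consistently chiral
#' fiber accumulates signed twist.
#'
#' @inheritParams local_twist
#' @return Total twist in degrees.
#' @export
total_twist <- function(spindle, fiber_id) {
  lt <- local_twist(spindle, fiber_id)
  sum(lt$twist_deg)
}

#' K-fiber helicity
#'
#' Rotation of the fiber center curve about the pole-to-pole axis, summed
#' over the center-curve steps (signed, right-handed about the pole 1 to
#' pole 2 direction) and divided by the center-curve length, in degrees per
#' micrometer.  An ideal helix of pitch p about the spindle axis gives
#' approximately 360/p deg/um at small radius.
#'
#' @inheritParams local_twist
#' @return Helicity in degrees per micrometer; `NA` (with a warning) for a
#'   fiber whose center curve spans fewer than two steps.
#' @export
helicity <- function(spindle, fiber_id) {
  fiber <- .get_fiber(spindle, fiber_id)
  cc <- fiber$center_curve
  if (is.null(cc) || nrow(cc) < 2) {
    warning("fiber ", fiber_id, ": center curve spans <2 steps; helicity NA",
            call. = FALSE)
    return(NA_real_)
  }
  a <- .normalize(spindle$pole2 - spindle$pole1)
  # sign reference follows the traversal direction along the axis, so the
  # handedness of a fiber does not depend on which pole it belongs to
  ref <- if (sum((cc[nrow(cc), ] - cc[1, ]) * a) < 0) -a else a
  rel <- sweep(cc, 2, spindle$pole1)
  radial <- rel - tcrossprod(as.numeric(rel %*% a), a)
  tot <- 0
  for (s in seq_len(nrow(cc) - 1L)) {
    r1 <- radial[s, ]; r2 <- radial[s + 1L, ]
    if (sqrt(sum(r1^2)) < 1e-9 || sqrt(sum(r2^2)) < 1e-9) next
    tot <- tot + .signed_angle_deg(r1, r2, ref)
  }
  tot / (.polyline_length(cc) / 1000)
}

## Intersection points of member KMTs with the plane through center[s,]
## normal to the local tangent, projected to 2D in-plane coordinates.
.cross_section_points <- function(spindle, fiber, s, frames) {
  samp <- frames$samp
  tg <- frames$tangents[s, ]
  c0 <- samp$center[s, ]
  basis <- .plane_basis(tg)
  half_sp <- spindle$resample_spacing / 2
  pts2 <- NULL
  for (id in fiber$kmt_ids) {
    op <- .oriented_points(spindle$microtubules[[id]])
    h <- as.numeric(sweep(op, 2, c0) %*% tg)
    cross <- which(h[-length(h)] * h[-1] < 0)
    exact <- which(h == 0)
    cand <- NULL
    if (length(exact)) cand <- op[exact, , drop = FALSE]
    for (i in cross) {
      t <- h[i] / (h[i] - h[i + 1L])
      cand <- rbind(cand, op[i, ] + t * (op[i + 1L, ] - op[i, ]))
    }
    if (is.null(cand) || nrow(cand) == 0L) {
      # tangent touch: nearest sample within half the resample spacing
      i <- which.min(abs(h))
      if (abs(h[i]) <= half_sp) cand <- op[i, , drop = FALSE]
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    # the crossing nearest the fiber center represents this KMT
    d2 <- rowSums(sweep(cand, 2, c0)^2)
    p <- cand[which.min(d2), ]
    pts2 <- rbind(pts2, c(sum((p - c0) * basis$u), sum((p - c0) * basis$v)))
  }
  pts2
}

#' K-fiber cross-section area profile
#'
#' At each center-curve step the member KMT intersection points with the
#' plane normal to the local center-curve tangent are projected to 2D and
#' the area of their alpha shape is computed ([alpha_shape_area()];
#' `alpha_radius = Inf` gives the convex hull).  Steps crossed by fewer
#' than 3 KMTs, or with collinear crossings, give `NA`.
#'
#' @inheritParams local_twist
#' @param alpha_radius alpha-disk radius in nm (`Inf` = convex hull).
#' @return Data frame with `position` (nm), `n_kmt`, `area_nm2`; attribute
#'   `total_area` holds the mean of the defined local areas.
#' @export
fiber_cross_section_area <- function(spindle, fiber_id, alpha_radius = Inf) {
  fiber <- .get_fiber(spindle, fiber_id)
  frames <- .twist_frames(spindle, fiber)
  k <- length(frames$samp$positions)
  pos <- frames$samp$positions
  n_kmt <- integer(k)
  area <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    pts2 <- .cross_section_points(spindle, fiber, s, frames)
    n_kmt[s] <- if (is.null(pts2)) 0L else nrow(pts2)
    if (n_kmt[s] >= 3L) area[s] <- alpha_shape_area(pts2, alpha_radius)
  }
  out <- data.frame(position = pos, n_kmt = n_kmt, area_nm2 = area)
  attr(out, "total_area") <- if (any(!is.na(area))) mean(area, na.rm = TRUE) else NA_real_
  out
}

#' KMT packing density profile
#'
#' Number of KMTs crossing the fiber cross-section plane divided by the
#' local alpha-shape area, reported per square micrometer.  `NA` area gives
#' `NA` density.
#'
#' @inheritParams fiber_cross_section_area
#' @return Data frame with `position` (nm), `n_kmt`, `area_nm2`,
#'   `density_per_um2`.
#' @export
kmt_density <- function(spindle, fiber_id, alpha_radius = Inf) {
  ar <- fiber_cross_section_area(spindle, fiber_id, alpha_radius)
  ar$density_per_um2 <- ifelse(is.na(ar$area_nm2), NA_real_,
                               ar$n_kmt / ar$area_nm2 * 1e6)
  ar
}

#' Outer-kinetochore distances
#'
#' For every sister k-fiber pair, the Euclidean distance between the two
#' plus-end centroids (each the mean 3D position of that fiber's KMT plus
#' ends) — the outer-kinetochore distance.
#'
#' @param spindle a `spindle` with sisters paired.
#' @return A `metric_table` (one row per pair, `object_id` =
#'   `"fiberA-fiberB"`), plus summary rows (mean, median, n).
#' @export
outer_kinetochore_distance <- function(spindle) {
  fb <- spindle$fibers
  if (is.null(fb) || length(fb) == 0L) {
    warning("no fibers; empty table", call. = FALSE)
    return(metric_table("outer_kinetochore_distance",
                        .mt_rows(spindle$graph_id, character(0), numeric(0), "nm")))
  }
  ids <- vapply(fb, `[[`, 1L, "fiber_id")
  sis <- vapply(fb, `[[`, 1L, "sister_fiber_id")
  seen <- character(0)
  obj <- character(0); val <- numeric(0)
  for (i in seq_along(fb)) {
    if (is.na(sis[i])) next
    key <- paste(sort(c(ids[i], sis[i])), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    j <- which(ids == sis[i])[1]
    obj <- c(obj, key)
    val <- c(val, sqrt(sum((fb[[i]]$plus_end_centroid -
                              fb[[j]]$plus_end_centroid)^2)))
  }
  if (length(val) == 0L) {
    warning("no sister pairs; empty table", call. = FALSE)
  } else {
    obj <- c(obj, "mean", "median", "n")
    val <- c(val, mean(val), stats::median(val), length(val))
  }
  metric_table("outer_kinetochore_distance",
               .mt_rows(spindle$graph_id, obj, val, "nm"))
}

#' KMT-number statistics
#'
#' Per fiber: KMT count, plus-end-centroid position along the spindle axis
#' and radial offset from it, the sister fiber's KMT count and the
#' inter-sister plus-end distance (NA when unpaired); plus Pearson and
#' Spearman correlations of the count against each covariate across fibers
#' (descriptive, no multiplicity correction).
#'
#' @param spindle a `spindle` with fibers built and sisters paired where
#'   possible.
#' @return List with `per_fiber` (data frame) and `correlations` (data
#'   frame with `covariate`, `pearson_r`, `spearman_rho`, `n`);
#'   correlations are `NA` with fewer than 3 fibers or zero variance.
#' @export
kmt_number_stats <- function(spindle) {
  fb <- spindle$fibers
  if (is.null(fb) || length(fb) == 0L) stop("no fibers built")
  a <- .normalize(spindle$pole2 - spindle$pole1)
  ids <- vapply(fb, `[[`, 1L, "fiber_id")
  n_kmt <- vapply(fb, function(f) length(f$kmt_ids), 1L)
  cen <- t(vapply(fb, `[[`, numeric(3), "plus_end_centroid"))
  rel <- sweep(cen, 2, spindle$pole1)
  axial <- as.numeric(rel %*% a)
  radial <- sqrt(rowSums((rel - tcrossprod(axial, a))^2))
  sis <- vapply(fb, `[[`, 1L, "sister_fiber_id")
  sn <- rep(NA_integer_, length(fb))
  sd_ <- rep(NA_real_, length(fb))
  for (i in seq_along(fb)) {
    if (is.na(sis[i])) next
    j <- which(ids == sis[i])[1]
    sn[i] <- n_kmt[j]
    sd_[i] <- sqrt(sum((cen[i, ] - cen[j, ])^2))
  }
  per_fiber <- data.frame(graph_id = spindle$graph_id, fiber_id = ids,
                          n_kmt = n_kmt, axial_position_nm = axial,
                          radial_offset_nm = radial, sister_fiber_id = sis,
                          sister_n_kmt = sn, interkinetochore_nm = sd_,
                          row.names = NULL)
  covs <- list(axial_position_nm = axial, radial_offset_nm = radial,
               sister_n_kmt = as.numeric(sn), interkinetochore_nm = sd_)
  cors <- do.call(rbind, lapply(names(covs), function(nm) {
    x <- n_kmt; y <- covs[[nm]]
    ok <- !is.na(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      data.frame(covariate = nm, pearson_r = NA_real_,
                 spearman_rho = NA_real_, n = sum(ok),
                 zero_variance = sum(ok) >= 3L &&
                   (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0))
    } else {
      data.frame(covariate = nm,
                 pearson_r = stats::cor(x[ok], y[ok]),
                 spearman_rho = stats::cor(x[ok], y[ok], method = "spearman"),
                 n = sum(ok), zero_variance = FALSE)
    }
  }))
  list(per_fiber = per_fiber, correlations = cors)
}
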