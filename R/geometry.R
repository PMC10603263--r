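# Internal geometry kernels. All coordinates are n x 3 numeric matrices,
# lengths in nm unless stated otherwise.

.seg_lengths <- function(pts) {
  d <- diff(pts)
  sqrt(rowSums(d * d))
}

.arc_lengths <- function(pts) c(0, cumsum(.seg_lengths(pts)))

.polyline_length <- function(pts) sum(.seg_lengths(pts))

.chord_length <- function(pts) {
  sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
}

## Point on the polyline at arc-length position s (clamped to [0, L]).
.point_at_arc <- function(pts, s) {
  arc <- .arc_lengths(pts)
  L <- arc[length(arc)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  if (i >= nrow(pts)) return(pts[nrow(pts), ])
  den <- arc[i + 1] - arc[i]
  t <- if (den > 0) (s - arc[i]) / den else 0
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

## Resample a polyline to uniform arc-length spacing.  Interior points sit
## exactly `spacing` apart in arc length; the final interval is <= spacing;
## both endpoints are kept exactly.  Degenerate inputs (total length <=
## spacing) collapse to their two endpoints, flagged via attribute.
.resample_polyline <- function(pts, spacing) {
  stopifnot(spacing > 0, nrow(pts) >= 2)
  arc <- .arc_lengths(pts)
  L <- arc[length(arc)]
  if (L <= spacing) {
    out <- pts[c(1L, nrow(pts)), , drop = FALSE]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  targets <- seq(0, L, by = spacing)
  if (L - targets[length(targets)] > 1e-6 * max(1, L)) {
    targets <- c(targets, L)
  } else {
    targets[length(targets)] <- L
  }
  idx <- findInterval(targets, arc, rightmost.closed = TRUE)
  idx[idx >= length(arc)] <- length(arc) - 1L
  den <- arc[idx + 1L] - arc[idx]
  t <- ifelse(den > 0, (targets - arc[idx]) / den, 0)
  out <- pts[idx, , drop = FALSE] + t * (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE])
  out[1L, ] <- pts[1L, ]
  out[nrow(out), ] <- pts[nrow(pts), ]
  attr(out, "degenerate") <- FALSE
  out
}

## Drop consecutive duplicate points (within tol) from a polyline.
.dedupe_points <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 2) return(pts)
  keep <- c(TRUE, .seg_lengths(pts) > tol)
  pts[keep, , drop = FALSE]
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

## Signed angle (degrees) rotating u onto v about the reference direction
## `ref` (unit vector).  Positive = right-handed rotation about ref.
.signed_angle_deg <- function(u, v, ref) {
  atan2(sum(.cross3(u, v) * ref), sum(u * v)) * 180 / pi
}

## Proper rotation matrix mapping unit vector u onto unit vector v
## (Rodrigues).  Never a reflection: handedness (twist sign) is preserved.
.rotation_between <- function(u, v) {
  u <- .normalize(u); v <- .normalize(v)
  w <- .cross3(u, v)
  s <- sqrt(sum(w^2))
  cth <- sum(u * v)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis perpendicular to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- .normalize(.cross3(u, a))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

## Two orthonormal vectors spanning the plane perpendicular to unit t.
.plane_basis <- function(t) {
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .normalize(.cross3(t, a))
  v <- .cross3(t, u)
  list(u = u, v = v)
}

## Minimum distances from each row of P (m x 3) to a polyline `pts`.
## Segment-exact.  Returns per-point min distance and the arc-length
## position of the foot on the polyline.
.points_polyline_mindist <- function(P, pts) {
  m <- nrow(P)
  best <- rep(Inf, m)
  bestarc <- rep(NA_real_, m)
  arc <- .arc_lengths(pts)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]
    b <- pts[i + 1L, ]
    ab <- b - a
    den <- sum(ab * ab)
    pa <- P - rep(a, each = m)
    t <- if (den > 0) pmin(pmax(c(pa %*% ab) / den, 0), 1) else rep(0, m)
    dvec <- pa - tcrossprod(t, ab)
    d <- sqrt(rowSums(dvec * dvec))
    upd <- d < best
    if (any(upd)) {
      best[upd] <- d[upd]
      bestarc[upd] <- arc[i] + t[upd] * (arc[i + 1L] - arc[i])
    }
  }
  list(dist = best, arc = bestarc)
}

## Central-difference unit tangents along a polyline (n x 3 in, n x 3 out).
.polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(NA_real_, n, 3)
  if (n == 1) return(tg)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  nn <- sqrt(rowSums(tg * tg))
  nn[nn == 0] <- 1
  tg / nn
}

## Axis-aligned bounding box of a point matrix, expanded by `pad`.
.bbox <- function(pts, pad = 0) {
  rbind(apply(pts, 2, min) - pad, apply(pts, 2, max) + pad)
}

.bbox_overlap <- function(b1, b2) {
  all(b1[1, ] <= b2[2, ] & b2[1, ] <= b1[2, ])
}
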