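# 2D Delaunay triangulation (Bowyer-Watson) and alpha-complex area.
#
# The fiber cross-section area is the area of the 2D alpha shape of the
# KMT intersection points: the union of Delaunay triangles whose
# circumradius does not exceed the alpha disk radius.  alpha = Inf keeps
# every triangle and reproduces the convex hull exactly.

## Signed distance of p from the triangle abc (0 when inside), used to
## locate the cavity seed during incremental insertion.
.tri_dist <- function(p, a, b, c) {
  cr <- function(u, v, w) (v[1] - u[1]) * (w[2] - u[2]) - (v[2] - u[2]) * (w[1] - u[1])
  s <- c(cr(a, b, p), cr(b, c, p), cr(c, a, p))
  if (all(s >= -1e-14) || all(s <= 1e-14)) return(0)
  seg <- function(u, v) {
    uv <- v - u
    t <- min(max(sum((p - u) * uv) / max(sum(uv * uv), 1e-300), 0), 1)
    sum((u + t * uv - p)^2)
  }
  sqrt(min(seg(a, b), seg(b, c), seg(c, a)))
}

## Bowyer-Watson Delaunay triangulation of a 2D point set, with the
## flood-fill cavity variant: the retriangulated region is the connected
## component of circumcircle-violating triangles around the triangle
## containing the inserted point, which keeps the cavity star-shaped under
## floating-point noise.  Returns an integer matrix (m x 3) of point
## indices; 0 rows when the input is degenerate (fewer than 3 distinct
## points or all collinear).
.delaunay2d <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  # normalize into the unit box for numerical robustness
  lo <- apply(pts, 2, min)
  span <- max(apply(pts, 2, max) - lo, 1e-300)
  q <- sweep(pts, 2, lo) / span
  # super-triangle far outside the unit box: its vertices must lie beyond
  # the circumcircles of boundary sliver triangles, or those get clipped
  # (much larger values trade this against incircle precision)
  P <- rbind(q, c(-1000, -1000), c(2000, -1000), c(0.5, 2000))
  sv <- n + 1:3
  tris <- matrix(sv, 1, 3)
  circ <- matrix(.circumcircle(P[sv[1], ], P[sv[2], ], P[sv[3], ]), 1, 3)
  for (i in seq_len(n)) {
    p <- P[i, ]
    d2 <- (circ[, 1] - p[1])^2 + (circ[, 2] - p[2])^2
    cand <- which(d2 <= circ[, 3] * (1 + 1e-9) + 1e-14)
    if (length(cand) == 0L) next  # duplicate/degenerate point; skip
    # seed = candidate triangle containing (or nearest to) the point
    td <- vapply(cand, function(k) {
      .tri_dist(p, P[tris[k, 1], ], P[tris[k, 2], ], P[tris[k, 3], ])
    }, 1)
    seed <- cand[which.min(td)]
    # flood fill across shared edges within the candidate set
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    cedges <- lapply(cand, function(k) {
      tr <- tris[k, ]
      ekey(tr[c(1, 2, 3)], tr[c(2, 3, 1)])
    })
    names(cedges) <- as.character(cand)
    bad <- seed
    frontier <- seed
    while (length(frontier) > 0L) {
      fe <- unlist(cedges[as.character(frontier)])
      nxt <- cand[vapply(as.character(cand), function(k) {
        !(as.integer(k) %in% bad) && any(cedges[[k]] %in% fe)
      }, TRUE)]
      bad <- c(bad, nxt)
      frontier <- nxt
    }
    # boundary = edges of the cavity appearing exactly once
    ed <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    keep <- key %in% names(which(table(key) == 1L))
    ed <- ed[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    if (nrow(ed) > 0L) {
      newt <- cbind(ed, i)
      newc <- t(apply(newt, 1, function(tr) .circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])))
      tris <- rbind(tris, newt)
      circ <- rbind(circ, newc)
    }
  }
  keep <- rowSums(matrix(tris %in% sv, nrow(tris), 3)) == 0L
  tris <- tris[keep, , drop = FALSE]
  dimnames(tris) <- NULL
  tris
}

## Circumcircle (cx, cy, r^2) of a 2D triangle; r^2 = Inf when collinear.
.circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(0, 0, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
}

.triangle_area2d <- function(a, b, c) {
  abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

#' Area of the 2D alpha shape of a point set
#'
#' Computes the area enclosed by the alpha shape (alpha complex) of a planar
#' point set: the union of Delaunay triangles with circumradius at most
#' `alpha`.  With `alpha = Inf` this is exactly the convex hull area.  Used
#' for k-fiber cross-section areas.
#'
#' @param pts numeric matrix (n x 2) of planar coordinates (nm).
#' @param alpha alpha-disk radius in the same units as `pts`; `Inf`
#'   reproduces the convex hull.
#' @return Area in squared input units, or `NA` when fewer than 3 distinct
#'   points remain or all points are collinear.
#' @examples
#' sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
#' alpha_shape_area(sq)            # 10000
#' @export
alpha_shape_area <- function(pts, alpha = Inf) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  if (nrow(pts) < 3) return(NA_real_)
  tris <- .delaunay2d(pts)
  if (nrow(tris) == 0L) return(NA_real_)
  total <- 0
  for (k in seq_len(nrow(tris))) {
    a <- pts[tris[k, 1], ]; b <- pts[tris[k, 2], ]; c <- pts[tris[k, 3], ]
    A <- .triangle_area2d(a, b, c)
    if (A <= 0) next
    if (is.finite(alpha)) {
      r <- sqrt(.circumcircle(a, b, c)[3])
      if (r > alpha) next
    }
    total <- total + A
  }
  total
}
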