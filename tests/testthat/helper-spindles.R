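# Test helpers: programmatic fixtures and independent oracles.

# straight microtubule from `from` to `to`, n points
straight_mt <- function(from, to, n = 2, mt_id = 1L, mt_class = "nonKMT",
                        fiber_id = NA_integer_) {
  t <- seq(0, 1, length.out = n)
  pts <- rep(from, each = n) + tcrossprod(t, to - from)
  microtubule(pts, mt_id = mt_id, mt_class = mt_class, fiber_id = fiber_id)
}

# random open 3D polyline (a jittered walk), nm scale
random_polyline <- function(n = 20, step = 100) {
  steps <- matrix(rnorm(3 * (n - 1), sd = step), ncol = 3)
  steps[, 3] <- abs(steps[, 3]) + step / 2  # keep it open (monotone in z)
  apply(rbind(c(0, 0, 0), steps), 2, cumsum)
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# apply a rigid (or mirror) map p -> R p + t to a whole spindle, then
# rebuild the fibers in the new frame
transform_spindle <- function(sp, R = diag(3), t = c(0, 0, 0)) {
  tf <- function(m) t(R %*% t(m)) + rep(t, each = nrow(m))
  sp$microtubules <- lapply(sp$microtubules, function(mt) {
    mt$points <- tf(mt$points)
    mt
  })
  sp$pole1 <- as.numeric(R %*% sp$pole1 + t)
  sp$pole2 <- as.numeric(R %*% sp$pole2 + t)
  if (!is.null(sp$fibers)) {
    sp <- build_kfibers(sp, if (is.null(sp$twist_step)) 500 else sp$twist_step)
  }
  sp
}

mirror_x <- diag(c(-1, 1, 1))

# a small spindle with n straight parallel KMTs per fiber (one fiber per
# pole pair), fully preprocessed
parallel_fiber_spindle <- function(offsets = rbind(c(0, 0), c(100, 0), c(50, 87)),
                                   z_from = 4500, z_to = 1000,
                                   pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000),
                                   npts = 50) {
  mts <- lapply(seq_len(nrow(offsets)), function(i) {
    straight_mt(c(offsets[i, 1], offsets[i, 2], z_from),
                c(offsets[i, 1], offsets[i, 2], z_to),
                n = npts, mt_id = i, mt_class = "KMT", fiber_id = 1L)
  })
  sp <- new_spindle(mts, pole1 = pole1, pole2 = pole2)
  sp <- infer_plus_minus_ends(sp)
  build_kfibers(sp)
}

# independent scalar point-to-segment distance (oracle; no shared code
# with the package kernels)
oracle_point_seg <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

oracle_point_polyline <- function(p, pts) {
  min(vapply(seq_len(nrow(pts) - 1),
             function(i) oracle_point_seg(p, pts[i, ], pts[i + 1, ]), 1))
}

# shoelace polygon area of the convex hull (grDevices::chull oracle)
oracle_hull_area <- function(pts2) {
  h <- grDevices::chull(pts2)
  x <- pts2[h, 1]; y <- pts2[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# random valid spatial graph for round-trip tests
random_graph <- function(n_edges = 5) {
  polys <- lapply(seq_len(n_edges), function(i) random_polyline(sample(3:12, 1)))
  spatial_graph_from_polylines(
    polys,
    labels = list(KMT = sample(0:1, n_edges, replace = TRUE),
                  KFiberID = sample(0:3, n_edges, replace = TRUE)))
}
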