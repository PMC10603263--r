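# Preprocessing: resampling, reorientation, end assignment, fiber
# construction, sister pairing.

test_that("resampling produces the expected uniform spacing", {
  mt <- straight_mt(c(0, 0, 0), c(1000, 0, 0), n = 7)
  r <- resample_uniform(mt, 20)
  expect_equal(nrow(r$points), 51)
  expect_equal(unique(round(diff(r$points[, 1]), 9)), 20)
  expect_true(all(r$points[, 2] == 0 & r$points[, 3] == 0))

  # idempotence on an already-uniform polyline
  r2 <- resample_uniform(r, 20)
  expect_equal(r2$points, r$points, tolerance = 1e-9)

  # arc length of a finely sampled half-circle is preserved to 0.5%
  hc <- make_half_circle(1000, 181)  # 1 degree sampling
  rhc <- resample_uniform(hc, 20)
  expect_equal(polyline_length(rhc), pi * 1000, tolerance = 5e-3)
  # endpoints preserved exactly
  expect_identical(rhc$points[1, ], hc$points[1, ])
  expect_identical(rhc$points[nrow(rhc$points), ], hc$points[nrow(hc$points), ])

  # spacing >= length collapses to the endpoints and is flagged
  short <- straight_mt(c(0, 0, 0), c(10, 0, 0), n = 5)
  rs <- resample_uniform(short, 20)
  expect_equal(nrow(rs$points), 2)
  expect_true(rs$degenerate)
})

test_that("reorientation is a distance-preserving rigid map onto the spindle axis", {
  set.seed(7)
  mts <- lapply(1:6, function(i) microtubule(random_polyline(10), mt_id = i))
  sp <- new_spindle(mts, pole1 = c(0, 0, 0), pole2 = c(3000, 4000, 0))
  before <- do.call(rbind, lapply(sp$microtubules, `[[`, "points"))
  d_before <- dist(rbind(before, sp$pole1, sp$pole2))
  sp2 <- reorient_to_axis(sp)
  after <- do.call(rbind, lapply(sp2$microtubules, `[[`, "points"))
  d_after <- dist(rbind(after, sp2$pole1, sp2$pole2))
  expect_lt(max(abs(d_after - d_before) / pmax(d_before, 1e-9)), 1e-6)
  # poles: pole1 at the origin, pole2 on +z at the original separation
  expect_equal(sp2$pole1, c(0, 0, 0))
  expect_equal(sp2$pole2, c(0, 0, 5000), tolerance = 1e-9)
  expect_lt(max(abs(sp2$pole2[1:2])), 1e-6)

  # already aligned: identity within tolerance
  sp3 <- new_spindle(mts, pole1 = c(0, 0, 0), pole2 = c(0, 0, 5000))
  sp4 <- reorient_to_axis(sp3)
  expect_equal(sp4$microtubules[[1]]$points, sp3$microtubules[[1]]$points,
               tolerance = 1e-9)
  expect_error(reorient_to_axis(new_spindle(mts)), "pole")
})

test_that("plus ends are assigned away from the pole, with ties flagged", {
  mt <- straight_mt(c(0, 0, 2000), c(0, 0, 500), n = 5, mt_class = "KMT")
  sp <- new_spindle(list(mt), pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  sp <- infer_plus_minus_ends(sp)
  expect_equal(sp$microtubules[[1]]$plus_end, "first")
  expect_equal(sp$microtubules[[1]]$pole_id, "pole1")
  expect_false(sp$microtubules[[1]]$tie)

  # symmetric about the pole plane: tie flagged, broken toward `first`
  tie <- microtubule(rbind(c(0, 500, 1000), c(0, 0, 1000), c(0, -500, 1000)),
                     mt_class = "KMT")
  spt <- infer_plus_minus_ends(new_spindle(list(tie), pole1 = c(0, 0, 0),
                                           pole2 = c(0, 0, 10000)))
  expect_true(spt$microtubules[[1]]$tie)
  expect_equal(spt$microtubules[[1]]$plus_end, "first")

  # generator ground truth: 100% agreement
  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 4, kmts_per_fiber = 3,
                                       nonkmt_n = 5, seed = 11))
  sp <- as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)
  sp <- infer_plus_minus_ends(sp)
  truth <- g$truth$mts
  for (i in which(truth$mt_class == "KMT")) {
    expect_equal(sp$microtubules[[i]]$plus_end, truth$plus_end[i])
  }
})

test_that("k-fiber construction: centroid line, pole consistency, single-KMT fibers", {
  sp <- parallel_fiber_spindle()
  f <- sp$fibers[["1"]]
  expect_equal(sort(f$kmt_ids), 1:3)
  # center curve of a symmetric parallel bundle is the straight centroid line
  expect_equal(f$center_curve[, 1], rep(50, nrow(f$center_curve)), tolerance = 1e-9)
  expect_equal(f$center_curve[, 2], rep(29, nrow(f$center_curve)), tolerance = 1)
  expect_equal(f$plus_end_centroid, c(50, 29, 4500), tolerance = 1)

  # single-KMT fiber: center curve follows that KMT's own track
  lone <- straight_mt(c(0, 0, 4000), c(0, 0, 1000), n = 20,
                      mt_class = "KMT", fiber_id = 9L)
  sp1 <- new_spindle(list(lone), pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  sp1 <- build_kfibers(infer_plus_minus_ends(sp1))
  cc <- sp1$fibers[["9"]]$center_curve
  expect_true(nrow(cc) >= 2)
  expect_equal(cc[1, ], c(0, 0, 4000))
  expect_equal(unique(cc[, 1]), 0)

  # fiber members on different poles is an error
  m1 <- straight_mt(c(0, 0, 4000), c(0, 0, 1000), n = 5, mt_id = 1,
                    mt_class = "KMT", fiber_id = 2L)
  m2 <- straight_mt(c(0, 0, 6000), c(0, 0, 9000), n = 5, mt_id = 2,
                    mt_class = "KMT", fiber_id = 2L)
  spx <- infer_plus_minus_ends(new_spindle(list(m1, m2), pole1 = c(0, 0, 0),
                                           pole2 = c(0, 0, 10000)))
  expect_error(build_kfibers(spx), "fiber 2")

  # no fiber labels: warning, no fibers
  spn <- new_spindle(list(straight_mt(c(0, 0, 100), c(0, 0, 2000), n = 5,
                                      mt_class = "KMT")),
                     pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  spn <- infer_plus_minus_ends(spn)
  expect_warning(spn2 <- build_kfibers(spn), "membership")
  expect_null(spn2$fibers)
})

test_that("facing fibers pair as sisters; lone fibers stay unpaired", {
  f1 <- straight_mt(c(0, 0, 4500), c(0, 0, 1000), n = 30, mt_id = 1,
                    mt_class = "KMT", fiber_id = 1L)
  f2 <- straight_mt(c(0, 0, 5500), c(0, 0, 9000), n = 30, mt_id = 2,
                    mt_class = "KMT", fiber_id = 2L)
  lone <- straight_mt(c(2000, 0, 4500), c(2000, 0, 1000), n = 30, mt_id = 3,
                      mt_class = "KMT", fiber_id = 3L)
  sp <- new_spindle(list(f1, f2, lone), pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  sp <- build_kfibers(infer_plus_minus_ends(sp))
  expect_warning(sp <- pair_sister_kfibers(sp), "unpaired")
  expect_equal(sp$fibers[["1"]]$sister_fiber_id, 2L)
  expect_equal(sp$fibers[["2"]]$sister_fiber_id, 1L)
  expect_true(is.na(sp$fibers[["3"]]$sister_fiber_id))
})

test_that("sister pairing is robust to 100 nm kinetochore jitter (>=95% over 20 seeds)", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 6, kmts_per_fiber = 3,
                                         nonkmt_n = 0, kin_jitter_nm = 100,
                                         noise_sigma_nm = 0, seed = seed))
    sp <- as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)
    sp <- suppressWarnings(preprocess_spindle(sp))
    truth <- g$truth$sisters
    for (r in seq_len(nrow(truth))) {
      total <- total + 1L
      sid <- sp$fibers[[as.character(truth$fiber1[r])]]$sister_fiber_id
      if (identical(sid, truth$fiber2[r])) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("classification partitions the microtubules", {
  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 3, kmts_per_fiber = 2,
                                       nonkmt_n = 7, seed = 2))
  sp <- as_spindle(g$graph)
  cls <- vapply(sp$microtubules, `[[`, "", "mt_class")
  expect_equal(sum(cls == "KMT") + sum(cls == "nonKMT"), length(sp$microtubules))
  expect_equal(sum(cls == "KMT"), 12)
})

test_that("pole estimation recovers generator poles well enough to orient the spindle", {
  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 6, kmts_per_fiber = 4,
                                       nonkmt_n = 10, seed = 5))
  sp <- estimate_poles(as_spindle(g$graph))
  # KMT minus ends end ~200-600 nm short of the true poles, so the
  # estimate sits near, not on, the pole; the axis direction is what the
  # analyses need
  a_est <- (sp$pole2 - sp$pole1) / sqrt(sum((sp$pole2 - sp$pole1)^2))
  expect_gt(abs(sum(a_est * c(0, 0, 1))), 0.99)
})
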