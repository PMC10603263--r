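# Length, tortuosity, twist, helicity, area, density and fiber-level
# statistics.

test_that("polyline length sums consecutive 3D distances", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(1000, 0, 0), c(1000, 1000, 0))),
               2000)
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3000, 4000, 0))), 5000)
  hc <- make_half_circle(1000, 2001)
  expect_equal(polyline_length(hc), pi * 1000, tolerance = 1e-3)
  # never shorter than the chord
  set.seed(3)
  for (i in 1:20) {
    pts <- random_polyline(15)
    expect_gte(polyline_length(pts), sqrt(sum((pts[15, ] - pts[1, ])^2)))
  }
})

test_that("tortuosity is 1 for straight lines, pi/2 for a half-circle, and L/l in general", {
  expect_identical(tortuosity(straight_mt(c(0, 0, 0), c(2000, 0, 0), n = 101)), 1)
  expect_equal(round(tortuosity(make_half_circle(1000, 1001)), 2), 1.57)
  # matches an independent direct L/l computation on random walks
  set.seed(11)
  for (i in 1:25) {
    pts <- random_polyline(sample(5:30, 1))
    L <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
    l <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    expect_equal(tortuosity(pts), L / l, tolerance = 1e-12)
    expect_gte(tortuosity(pts), 1)
  }
  # exactly closed curve: +Inf
  th <- seq(0, 2 * pi, length.out = 100)
  circle <- cbind(cos(th), sin(th), 0) * 1000
  circle[100, ] <- circle[1, ]
  expect_identical(tortuosity(circle), Inf)
})

test_that("local tortuosity windows slide along the arc and flag impossible windows", {
  hc <- resample_uniform(make_half_circle(1000, 1001), 20)
  lt <- tortuosity(hc, window = 500)
  expect_true(all(lt$tortuosity >= 1))
  expect_true(all(diff(lt$position) > 0))
  # a 500 nm arc window of a r=1000 circle subtends 0.5 rad:
  # tau = 0.5 / (2 sin(0.25))
  expect_equal(unique(round(lt$tortuosity, 3)),
               round(0.5 / (2 * sin(0.25)), 3))
  expect_error(tortuosity(straight_mt(c(0, 0, 0), c(100, 0, 0)), window = 500),
               "window")
})

test_that("length_distribution reports per-microtubule lengths and summaries", {
  mts <- list(straight_mt(c(0, 0, 4000), c(0, 0, 3000), n = 5, mt_id = 1, mt_class = "KMT"),
              straight_mt(c(0, 0, 4000), c(0, 0, 2000), n = 5, mt_id = 2, mt_class = "KMT"),
              straight_mt(c(0, 0, 4000), c(0, 0, 1000), n = 5, mt_id = 3, mt_class = "KMT"))
  sp <- new_spindle(mts, pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  tb <- length_distribution(sp, "KMT")
  expect_equal(tb$value[tb$object_id == "mean"], 2000)
  expect_equal(tb$value[tb$object_id == "n"], 3)
  expect_equal(tb$value[1:3], c(1000, 2000, 3000))
  expect_warning(empty <- length_distribution(sp, "nonKMT"), "no microtubules")
  expect_equal(nrow(empty), 0)
})

test_that("twist is zero for straight bundles, 360*step/pitch for helix bundles, and sums", {
  sp <- parallel_fiber_spindle()
  lt <- local_twist(sp, 1)
  expect_true(nrow(lt) >= 5)
  expect_equal(lt$twist_deg, rep(0, nrow(lt)), tolerance = 1e-9)
  expect_equal(total_twist(sp, 1), 0, tolerance = 1e-9)

  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 1, kmts_per_fiber = 5,
                                       nonkmt_n = 0, helix_pitch_um = 10,
                                       helix_about = "fiber", bundle_radius_nm = 100,
                                       noise_sigma_nm = 0,
                                       fiber_length_um = c(mean = 4, sd = 0),
                                       seed = 4))
  sp2 <- suppressWarnings(preprocess_spindle(
    as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)))
  lt2 <- local_twist(sp2, 1)
  expect_true(nrow(lt2) >= 6)
  expect_equal(abs(lt2$twist_deg), rep(18, nrow(lt2)), tolerance = 0.05)
  # total twist is exactly the sum of local twists
  expect_identical(total_twist(sp2, 1), sum(lt2$twist_deg))

  # mirror reflection negates every local twist
  spm <- transform_spindle(sp2, R = mirror_x)
  ltm <- local_twist(spm, 1)
  expect_equal(ltm$twist_deg, -lt2$twist_deg, tolerance = 1e-6)
})

test_that("helicity: zero on straight on-axis fibers, ~360/pitch on axis helices, chiral", {
  sp <- parallel_fiber_spindle()
  expect_equal(helicity(sp, 1), 0, tolerance = 1e-6)

  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 1, kmts_per_fiber = 5,
                                       nonkmt_n = 0, helix_pitch_um = 10,
                                       helix_about = "axis", plate_radius_um = 0.2,
                                       bundle_radius_nm = 40, noise_sigma_nm = 0,
                                       fiber_length_um = c(mean = 4, sd = 0),
                                       seed = 6))
  sp2 <- suppressWarnings(preprocess_spindle(
    as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)))
  h <- unname(vapply(names(sp2$fibers), function(f) helicity(sp2, f), 1))
  expect_equal(abs(h), rep(36, length(h)), tolerance = 0.05)
  # both sisters have the same handedness sign
  expect_equal(length(unique(sign(h))), 1)
  # reflection flips the sign
  spm <- transform_spindle(sp2, R = mirror_x)
  hm <- unname(vapply(names(spm$fibers), function(f) helicity(spm, f), 1))
  expect_equal(hm, -h, tolerance = 1e-6)
})

test_that("alpha-shape area: closed forms, hull oracle, monotonicity in alpha", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  expect_equal(alpha_shape_area(sq), 10000)
  tri <- rbind(c(0, 0), c(100, 0), c(50, 50 * sqrt(3)))
  expect_equal(alpha_shape_area(tri), sqrt(3) / 4 * 100^2)
  # degenerate inputs
  expect_true(is.na(alpha_shape_area(rbind(c(0, 0), c(1, 1)))))
  expect_true(is.na(alpha_shape_area(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3)))))

  set.seed(9)
  for (i in 1:20) {
    pts <- matrix(runif(2 * sample(4:40, 1), 0, 200), ncol = 2)
    expect_equal(alpha_shape_area(pts), oracle_hull_area(pts), tolerance = 1e-9)
    # monotone non-decreasing in alpha
    alphas <- c(20, 40, 80, 160, Inf)
    areas <- vapply(alphas, function(a) alpha_shape_area(pts, a), 1)
    areas[is.na(areas)] <- 0
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("cross-section area and density: 100 nm square of 4 KMTs", {
  off <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  sp <- parallel_fiber_spindle(offsets = off)
  ar <- fiber_cross_section_area(sp, 1)
  expect_true(all(ar$n_kmt == 4))
  expect_equal(ar$area_nm2, rep(10000, nrow(ar)), tolerance = 1e-6)
  d <- kmt_density(sp, 1)
  expect_equal(d$density_per_um2, rep(400, nrow(d)), tolerance = 1e-6)

  # equilateral 100 nm triangle
  tri <- rbind(c(0, 0), c(100, 0), c(50, 50 * sqrt(3)))
  spt <- parallel_fiber_spindle(offsets = tri)
  art <- fiber_cross_section_area(spt, 1)
  expect_equal(art$area_nm2, rep(sqrt(3) / 4 * 1e4, nrow(art)), tolerance = 1e-6)

  # 1-2 KMTs give NA area and NA density
  sp2 <- parallel_fiber_spindle(offsets = rbind(c(0, 0), c(100, 0)))
  ar2 <- kmt_density(sp2, 1)
  expect_true(all(is.na(ar2$area_nm2)))
  expect_true(all(is.na(ar2$density_per_um2)))
})

test_that("outer-kinetochore distance is the plus-end-centroid separation of sisters", {
  f1 <- straight_mt(c(0, 0, 4500), c(0, 0, 1000), n = 30, mt_id = 1,
                    mt_class = "KMT", fiber_id = 1L)
  f2 <- straight_mt(c(0, 0, 5500), c(0, 0, 9000), n = 30, mt_id = 2,
                    mt_class = "KMT", fiber_id = 2L)
  sp <- new_spindle(list(f1, f2), pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  sp <- pair_sister_kfibers(build_kfibers(infer_plus_minus_ends(sp)))
  tb <- outer_kinetochore_distance(sp)
  expect_equal(tb$value[tb$object_id == "1-2"], 1000)
  # single-KMT fiber centroid is that KMT's plus end
  expect_equal(sp$fibers[["1"]]$plus_end_centroid, c(0, 0, 4500))
})

test_that("generator inter-kinetochore distance is recovered", {
  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 4, kmts_per_fiber = 4,
                                       nonkmt_n = 0, interkinetochore_nm = 1100,
                                       seed = 13))
  sp <- suppressWarnings(preprocess_spindle(
    as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)))
  tb <- outer_kinetochore_distance(sp)
  vals <- tb$value[!tb$object_id %in% c("mean", "median", "n")]
  expect_equal(mean(vals), 1100, tolerance = 0.02)
})

test_that("kmt_number_stats reports counts, covariates and correlations", {
  f1 <- lapply(1:5, function(i)
    straight_mt(c(i * 30, 0, 4500), c(i * 30, 0, 1000), n = 20, mt_id = i,
                mt_class = "KMT", fiber_id = 1L))
  f2 <- lapply(1:7, function(i)
    straight_mt(c(i * 30, 0, 5500), c(i * 30, 0, 9000), n = 20, mt_id = 5 + i,
                mt_class = "KMT", fiber_id = 2L))
  sp <- new_spindle(c(f1, f2), pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
  sp <- pair_sister_kfibers(build_kfibers(infer_plus_minus_ends(sp)))
  st <- kmt_number_stats(sp)
  expect_equal(st$per_fiber$n_kmt, c(5L, 7L))
  expect_equal(st$per_fiber$sister_n_kmt, c(7L, 5L))
  # < 3 fibers: correlations NA
  expect_true(all(is.na(st$correlations$pearson_r)))

  # counts generated linear in axial position: positive r recovered in
  # >= 95% of 50 seeds
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    mts <- list(); fid <- 0L; id <- 0L
    for (k in 1:8) {
      fid <- fid + 1L
      z <- 2500 + k * 300
      n <- max(2L, round(2 + 0.004 * z + rnorm(1, 0, 1)))
      for (j in seq_len(n)) {
        id <- id + 1L
        mts[[id]] <- straight_mt(c(k * 500 + j * 30, 0, z),
                                 c(k * 500 + j * 30, 0, 500), n = 10,
                                 mt_id = id, mt_class = "KMT", fiber_id = fid)
      }
    }
    sp <- new_spindle(mts, pole1 = c(0, 0, 0), pole2 = c(0, 0, 10000))
    sp <- build_kfibers(infer_plus_minus_ends(sp))
    st <- kmt_number_stats(sp)
    r <- st$correlations$pearson_r[st$correlations$covariate == "axial_position_nm"]
    if (!is.na(r) && r > 0) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("all scalar metrics are invariant under rigid motion", {
  g <- generate_spindle(spindle_recipe(n_fibers_per_pole = 2, kmts_per_fiber = 4,
                                       nonkmt_n = 5, helix_pitch_um = 8,
                                       seed = 21))
  sp <- suppressWarnings(preprocess_spindle(
    as_spindle(g$graph, pole1 = g$truth$pole1, pole2 = g$truth$pole2)))
  set.seed(99)
  sp2 <- transform_spindle(sp, R = random_rotation(), t = c(1234, -567, 89))
  releq <- function(a, b, tol = 1e-6) {
    expect_equal(a, b, tolerance = tol)
  }
  for (i in seq_along(sp$microtubules)) {
    releq(polyline_length(sp2$microtubules[[i]]), polyline_length(sp$microtubules[[i]]))
    releq(tortuosity(sp2$microtubules[[i]]), tortuosity(sp$microtubules[[i]]))
  }
  for (fn in names(sp$fibers)) {
    releq(total_twist(sp2, fn), total_twist(sp, fn))
    releq(helicity(sp2, fn), helicity(sp, fn))
    a1 <- fiber_cross_section_area(sp, fn)$area_nm2
    a2 <- fiber_cross_section_area(sp2, fn)$area_nm2
    releq(a2, a1, tol = 1e-5)
    releq(kmt_density(sp2, fn)$density_per_um2, kmt_density(sp, fn)$density_per_um2,
          tol = 1e-5)
  }
})
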