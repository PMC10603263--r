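# Ground-truth synthetic spindle generator.  Emits valid AmiraMesh ASCII
# spatial graphs of a bipolar spindle: two poles on the configured axis,
# sister k-fibers of helical or straight KMTs with known lengths, twist
# and packing geometry, background non-KMTs, and optionally planted
# minus-end branching events.

#' Define a synthetic spindle recipe
#'
#' Parameters of the generated spindle.  Defaults describe a small HeLa-
#' like metaphase spindle: a 10 um pole-to-pole axis, kinetochore pairs on
#' a 2.5 um metaphase plate separated by 1 um, 9 KMTs per fiber packed on
#' a 60 nm ring, KMT lengths 4 +/- 1 um, and 5 nm tracing jitter applied
#' to raw trace nodes spaced 250 nm apart.
#'
#' @param n_fibers_per_pole kinetochore (fiber) pairs; one fiber per pole
#'   each.
#' @param kmts_per_fiber KMTs per k-fiber.
#' @param fiber_length_um mean and sd of KMT length (um), truncated to
#'   at least 0.6 um and at most the kinetochore-to-pole distance.
#' @param bundle_radius_nm KMT ring radius about the fiber center.
#' @param helix_pitch_um helical pitch of KMTs (0 = straight).
#' @param helix_about `"fiber"`: KMTs wind about their fiber center line;
#'   `"axis"`: the whole fiber winds about the spindle axis (the fiber
#'   center curve itself is a helix, used for helicity benchmarks).
#' @param nonkmt_n number of background non-KMTs.
#' @param nonkmt_length_um mean and sd of non-KMT length (um).
#' @param n_branch_events planted minus-end branching events.
#' @param branch_distance_nm min/max of the planted minus-end-to-target
#'   distance (drawn uniformly).
#' @param noise_sigma_nm isotropic Gaussian positional noise per trace
#'   node.
#' @param point_spacing_nm node spacing of the emitted raw traces.
#' @param interkinetochore_nm separation of sister kinetochores along the
#'   axis.
#' @param kin_jitter_nm isotropic jitter of each kinetochore position
#'   (perturbs the paired plate geometry; 0 = perfectly paired).
#' @param spindle_length_um pole-to-pole distance.
#' @param plate_radius_um radius of the metaphase plate disc.
#' @param seed integer seed; the same recipe and seed reproduce the output
#'   byte for byte.
#' @return A `spindle_recipe` list.
#' @export
spindle_recipe <- function(n_fibers_per_pole = 10,
                           kmts_per_fiber = 9,
                           fiber_length_um = c(mean = 4, sd = 1),
                           bundle_radius_nm = 60,
                           helix_pitch_um = 0,
                           helix_about = c("fiber", "axis"),
                           nonkmt_n = 40,
                           nonkmt_length_um = c(mean = 2, sd = 0.8),
                           n_branch_events = 0,
                           branch_distance_nm = c(min = 5, max = 20),
                           noise_sigma_nm = 5,
                           point_spacing_nm = 250,
                           interkinetochore_nm = 1000,
                           kin_jitter_nm = 0,
                           spindle_length_um = 10,
                           plate_radius_um = 2.5,
                           seed = 1L) {
  helix_about <- match.arg(helix_about)
  stopifnot(n_fibers_per_pole >= 0, kmts_per_fiber >= 1, nonkmt_n >= 0,
            n_branch_events >= 0, noise_sigma_nm >= 0, point_spacing_nm > 0,
            spindle_length_um > 0)
  if (n_branch_events > 0 && nonkmt_n < n_branch_events) {
    stop("need at least as many non-KMTs as planted branch events")
  }
  structure(as.list(environment()), class = "spindle_recipe")
}

## One helical KMT path about the straight line kin -> pole.
.kmt_path <- function(kin, pole_dir, length_nm, radius, pitch_nm, phase,
                      spacing) {
  s <- seq(0, length_nm, by = spacing)
  if (s[length(s)] < length_nm - 1e-9) s <- c(s, length_nm)
  basis <- .plane_basis(pole_dir)
  ang <- rep(phase, length(s)) + if (pitch_nm > 0) 2 * pi * s / pitch_nm else 0
  core <- rep(kin, each = length(s)) + tcrossprod(s, pole_dir)
  core + radius * (tcrossprod(cos(ang), basis$u) + tcrossprod(sin(ang), basis$v))
}

#' Generate a synthetic spindle with ground truth
#'
#' Builds the spindle geometry of a [spindle_recipe()], emits it as a
#' valid `spatial_graph` (KMT and KFiberID edge labels) and returns the
#' generator's ground truth: every drawn KMT length, fiber membership and
#' pole, sister pairs with their true plus-end-centroid separations,
#' planted branch events, and the poles.  KMT polylines are stored plus
#' end first.
#'
#' @param recipe a [spindle_recipe()].
#' @return List with `graph` (a `spatial_graph`), `truth` (list:
#'   `mts` data frame, `sisters` data frame, `branches` data frame,
#'   `pole1`, `pole2`, `recipe`), and `write` convenience fields.
#' @export
generate_spindle <- function(recipe) {
  stopifnot(inherits(recipe, "spindle_recipe"))
  set.seed(recipe$seed)
  Lz <- recipe$spindle_length_um * 1000
  pole1 <- c(0, 0, 0)
  pole2 <- c(0, 0, Lz)
  plate_r <- recipe$plate_radius_um * 1000
  pitch_nm <- recipe$helix_pitch_um * 1000
  spacing <- recipe$point_spacing_nm
  nf <- recipe$n_fibers_per_pole
  nk <- recipe$kmts_per_fiber

  polylines <- list()
  kmt_lab <- integer(0)
  fiber_lab <- integer(0)
  truth_mt <- list()
  sisters <- list()

  # kinetochore pairs on the plate disc (golden-angle layout: deterministic,
  # evenly spread, no accidental near-coincidences)
  mt_id <- 0L
  for (f in seq_len(nf)) {
    th <- f * 2.399963
    rr <- plate_r * sqrt(f / max(nf, 1))
    base <- c(rr * cos(th), rr * sin(th), Lz / 2)
    kin <- list(base + c(0, 0, -recipe$interkinetochore_nm / 2),
                base + c(0, 0, +recipe$interkinetochore_nm / 2))
    if (recipe$kin_jitter_nm > 0) {
      kin <- lapply(kin, function(k) k + stats::rnorm(3, 0, recipe$kin_jitter_nm))
    }
    for (p in 1:2) {
      pole <- if (p == 1) pole1 else pole2
      fid <- (f - 1L) * 2L + p
      u <- .normalize(pole - kin[[p]])
      max_len <- sqrt(sum((pole - kin[[p]])^2)) - 200
      for (k in seq_len(nk)) {
        len <- stats::rnorm(1, recipe$fiber_length_um["mean"] * 1000,
                            recipe$fiber_length_um["sd"] * 1000)
        len <- min(max(len, 600), max_len)
        phase <- 2 * pi * (k - 1) / nk + stats::runif(1, 0, 2 * pi / nk / 4)
        if (recipe$helix_about == "axis") {
          # whole fiber winds about the spindle axis: radial offset of the
          # kinetochore rotates with axial position
          s <- seq(0, len, by = spacing)
          if (s[length(s)] < len - 1e-9) s <- c(s, len)
          zdir <- if (p == 1) -1 else 1
          z <- kin[[p]][3] + zdir * s * abs(u[3])
          rho <- sqrt(sum(kin[[p]][1:2]^2))
          phi0 <- atan2(kin[[p]][2], kin[[p]][1])
          phi <- phi0 + if (pitch_nm > 0) 2 * pi * (z - kin[[p]][3]) / pitch_nm else 0
          pts <- cbind(rho * cos(phi), rho * sin(phi), z)
          # KMT ring offset about that helical center
          basis <- .plane_basis(c(0, 0, zdir))
          pts <- pts + recipe$bundle_radius_nm *
            (tcrossprod(rep(cos(phase), length(s)), basis$u) +
             tcrossprod(rep(sin(phase), length(s)), basis$v))
        } else {
          pts <- .kmt_path(kin[[p]], u, len, recipe$bundle_radius_nm,
                           pitch_nm, phase, spacing)
        }
        if (recipe$noise_sigma_nm > 0) {
          pts <- pts + matrix(stats::rnorm(length(pts), 0, recipe$noise_sigma_nm),
                              nrow(pts), 3)
        }
        mt_id <- mt_id + 1L
        polylines[[mt_id]] <- pts
        kmt_lab[mt_id] <- 1L
        fiber_lab[mt_id] <- fid
        truth_mt[[mt_id]] <- data.frame(
          mt_id = mt_id, mt_class = "KMT", fiber_id = fid,
          pole_id = paste0("pole", p), length_nm = .polyline_length(pts),
          drawn_length_nm = len, plus_end = "first",
          stringsAsFactors = FALSE)
      }
    }
    sisters[[f]] <- data.frame(
      fiber1 = (f - 1L) * 2L + 1L, fiber2 = (f - 1L) * 2L + 2L,
      interkinetochore_nm = sqrt(sum((kin[[1]] - kin[[2]])^2)))
  }

  # background non-KMTs: straight, random positions/directions
  nonkmt_ids <- integer(0)
  for (m in seq_len(recipe$nonkmt_n)) {
    len <- max(stats::rnorm(1, recipe$nonkmt_length_um["mean"] * 1000,
                            recipe$nonkmt_length_um["sd"] * 1000), 400)
    th <- stats::runif(1, 0, 2 * pi)
    ctr <- c(sqrt(stats::runif(1)) * plate_r * 1.2 * cos(th),
             sqrt(stats::runif(1)) * plate_r * 1.2 * sin(th),
             stats::runif(1, 0.1 * Lz, 0.9 * Lz))
    d <- .normalize(stats::rnorm(3) + c(0, 0, 2))
    s <- seq(0, len, by = spacing)
    if (s[length(s)] < len - 1e-9) s <- c(s, len)
    pts <- rep(ctr - d * len / 2, each = length(s)) + tcrossprod(s, d)
    if (recipe$noise_sigma_nm > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, recipe$noise_sigma_nm),
                          nrow(pts), 3)
    }
    mt_id <- mt_id + 1L
    polylines[[mt_id]] <- pts
    kmt_lab[mt_id] <- 0L
    fiber_lab[mt_id] <- 0L
    nonkmt_ids <- c(nonkmt_ids, mt_id)
    truth_mt[[mt_id]] <- data.frame(
      mt_id = mt_id, mt_class = "nonKMT", fiber_id = NA_integer_,
      pole_id = NA_character_, length_nm = .polyline_length(pts),
      drawn_length_nm = len, plus_end = NA_character_,
      stringsAsFactors = FALSE)
  }

  # planted branch events: relocate one dedicated non-KMT per event so it
  # passes at the drawn perpendicular distance from a chosen KMT minus end
  branches <- data.frame(kmt_id = integer(0), target_id = integer(0),
                         distance_nm = numeric(0))
  if (recipe$n_branch_events > 0) {
    kmt_ids <- which(kmt_lab == 1L)
    src <- kmt_ids[sample.int(length(kmt_ids), recipe$n_branch_events)]
    tgt <- nonkmt_ids[sample.int(length(nonkmt_ids), recipe$n_branch_events)]
    for (e in seq_len(recipe$n_branch_events)) {
      minus <- polylines[[src[e]]][nrow(polylines[[src[e]]]), ]
      d <- stats::runif(1, recipe$branch_distance_nm["min"],
                        recipe$branch_distance_nm["max"])
      off <- .normalize(stats::rnorm(3))
      tdir <- .normalize(.cross3(off, .normalize(stats::rnorm(3))))
      tp <- polylines[[tgt[e]]]
      tlen <- .polyline_length(tp)
      s <- seq(0, tlen, by = spacing)
      if (s[length(s)] < tlen - 1e-9) s <- c(s, tlen)
      mid <- minus + d * off
      polylines[[tgt[e]]] <- rep(mid - tdir * tlen / 2, each = length(s)) +
        tcrossprod(s, tdir)
      truth_mt[[tgt[e]]]$length_nm <- .polyline_length(polylines[[tgt[e]]])
      branches <- rbind(branches, data.frame(
        kmt_id = src[e], target_id = tgt[e], distance_nm = d))
    }
  }

  graph <- spatial_graph_from_polylines(polylines,
                                        labels = list(KMT = kmt_lab,
                                                      KFiberID = fiber_lab),
                                        graph_id = 1L, units = "nm")
  truth <- list(mts = do.call(rbind, truth_mt),
                sisters = do.call(rbind, sisters),
                branches = branches,
                pole1 = pole1, pole2 = pole2,
                helix_pitch_um = recipe$helix_pitch_um,
                recipe = recipe)
  list(graph = graph, truth = truth)
}

#' Half-circle fixture microtubule
#'
#' A planar semicircular polyline sampled uniformly in angle — the worked
#' tortuosity example (a half-circle has tortuosity pi/2, about 1.57).
#'
#' @param radius radius in nm.
#' @param n_points number of points (>= 3).
#' @return A [microtubule()].
#' @examples
#' round(tortuosity(make_half_circle(1000, 1001)), 2)  # 1.57
#' @export
make_half_circle <- function(radius = 1000, n_points = 1001) {
  stopifnot(n_points >= 3, radius > 0)
  th <- seq(0, pi, length.out = n_points)
  microtubule(cbind(radius * cos(th), radius * sin(th), 0), mt_id = 1L)
}
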