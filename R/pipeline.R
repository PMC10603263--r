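# One-command batch pipeline: validate -> preprocess -> toggled analyses
# -> CSV tables + run manifest.

.DEFAULT_ANALYSES <- c(length = TRUE, kmt_number = TRUE,
                       outer_kinetochore = TRUE, curvature = TRUE,
                       twist = TRUE, helicity = TRUE, area = TRUE,
                       density = TRUE, branching = TRUE, interactions = TRUE)

.DEFAULT_PARAMS <- list(resample_spacing = 20, twist_step = 500,
                        tortuosity_window = 500, alpha_radius = Inf,
                        branch_threshold = 25, interaction_threshold = 100,
                        sister_cone_deg = 60, exclude_same_fiber = FALSE,
                        units = "nm", axis = "z")

#' Build a pipeline configuration
#'
#' Validates inputs, analysis toggles and parameter overrides for
#' [run_pipeline()].  Unknown analysis or parameter names are an error
#' before any work starts.
#'
#' @param input one or more spatial-graph file paths.
#' @param output_dir directory for the per-graph table directories and the
#'   run manifest.
#' @param analyses named logical vector switching individual analyses on
#'   or off (names: length, kmt_number, outer_kinetochore, curvature,
#'   twist, helicity, area, density, branching, interactions); unnamed
#'   defaults are all on.
#' @param params named list of parameter overrides (names:
#'   resample_spacing, twist_step, tortuosity_window, alpha_radius,
#'   branch_threshold, interaction_threshold, sister_cone_deg,
#'   exclude_same_fiber, units, axis).
#' @param format output table format; see [export_tables()].
#' @param pole1,pole2 optional pole coordinates (nm) applied to every
#'   input; when absent, poles are estimated per graph.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, output_dir, analyses = NULL, params = NULL,
                            format = "csv", pole1 = NULL, pole2 = NULL) {
  stopifnot(length(input) >= 1)
  tog <- .DEFAULT_ANALYSES
  if (!is.null(analyses)) {
    bad <- setdiff(names(analyses), names(tog))
    if (length(bad)) stop("unknown analysis toggle(s): ", paste(bad, collapse = ", "))
    tog[names(analyses)] <- as.logical(analyses)
  }
  if (!any(tog)) stop("at least one analysis must be switched on")
  par <- .DEFAULT_PARAMS
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(par))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    par[names(params)] <- params
  }
  for (nm in c("resample_spacing", "twist_step", "branch_threshold",
               "interaction_threshold")) {
    if (!is.numeric(par[[nm]]) || par[[nm]] <= 0) {
      stop("parameter ", nm, " must be > 0")
    }
  }
  structure(list(input = input, output_dir = output_dir, analyses = tog,
                 params = par, format = format, pole1 = pole1, pole2 = pole2),
            class = "analysis_config")
}

.analyze_one <- function(spindle, cfg) {
  par <- cfg$params
  tables <- list()
  warn <- character(0)
  note <- function(...) warn <<- c(warn, paste0(...))
  has_fibers <- !is.null(spindle$fibers) && length(spindle$fibers) > 0
  gid <- spindle$graph_id

  if (cfg$analyses[["length"]]) {
    tables$length_kmt <- withCallingHandlers(
      length_distribution(spindle, "KMT"),
      warning = function(w) {note(conditionMessage(w)); invokeRestart("muffleWarning")})
    attr(tables$length_kmt, "analysis") <- "length_kmt"
    tables$length_nonkmt <- suppressWarnings(length_distribution(spindle, "nonKMT"))
    attr(tables$length_nonkmt, "analysis") <- "length_nonkmt"
  }
  if (cfg$analyses[["curvature"]]) {
    mts <- Filter(function(m) m$mt_class == "KMT", spindle$microtubules)
    if (length(mts) == 0) mts <- spindle$microtubules
    tt <- vapply(mts, tortuosity, 1)
    ids <- as.character(vapply(mts, `[[`, 1L, "mt_id"))
    fin <- is.finite(tt)
    tables$tortuosity <- metric_table("tortuosity", .mt_rows(
      gid, c(ids, "mean", "n"),
      c(tt, mean(tt[fin]), sum(fin)), ""))
    if (has_fibers) {
      ft <- vapply(spindle$fibers, function(f) {
        if (nrow(f$center_curve) >= 2) tortuosity(f) else NA_real_
      }, 1)
      tables$fiber_tortuosity <- metric_table("fiber_tortuosity", .mt_rows(
        gid, names(spindle$fibers), ft, ""))
    }
  }
  if (has_fibers && (cfg$analyses[["twist"]] || cfg$analyses[["helicity"]])) {
    tw <- list(); hel <- numeric(0); tot <- numeric(0)
    for (fn in names(spindle$fibers)) {
      lt <- local_twist(spindle, fn)
      if (nrow(lt)) {
        lt <- cbind(graph_id = gid, fiber_id = fn, lt)
        tw[[fn]] <- lt
      }
      tot[fn] <- sum(lt$twist_deg)
      hel[fn] <- suppressWarnings(helicity(spindle, fn))
    }
    if (cfg$analyses[["twist"]]) {
      tables$local_twist <- metric_table("local_twist", if (length(tw))
        do.call(rbind, tw) else
        data.frame(graph_id = integer(0), fiber_id = character(0),
                   step_index = integer(0), position = numeric(0),
                   twist_deg = numeric(0), n_kmt = integer(0)))
      tables$total_twist <- metric_table("total_twist",
        .mt_rows(gid, names(tot), as.numeric(tot), "deg"))
    }
    if (cfg$analyses[["helicity"]]) {
      tables$helicity <- metric_table("helicity",
        .mt_rows(gid, names(hel), as.numeric(hel), "deg/um"))
      if (anyNA(hel)) note("helicity NA for fiber(s) spanning <2 steps")
    }
  }
  if (has_fibers && (cfg$analyses[["area"]] || cfg$analyses[["density"]])) {
    ar <- list()
    for (fn in names(spindle$fibers)) {
      d <- kmt_density(spindle, fn, alpha_radius = par$alpha_radius)
      ar[[fn]] <- cbind(graph_id = gid, fiber_id = fn, d)
    }
    ad <- do.call(rbind, ar)
    if (cfg$analyses[["area"]]) {
      tables$fiber_area <- metric_table("fiber_area",
        ad[, c("graph_id", "fiber_id", "position", "n_kmt", "area_nm2")])
    }
    if (cfg$analyses[["density"]]) {
      tables$kmt_density <- metric_table("kmt_density",
        ad[, c("graph_id", "fiber_id", "position", "n_kmt", "density_per_um2")])
    }
  }
  if (has_fibers && cfg$analyses[["outer_kinetochore"]]) {
    tables$outer_kinetochore <- withCallingHandlers(
      outer_kinetochore_distance(spindle),
      warning = function(w) {note(conditionMessage(w)); invokeRestart("muffleWarning")})
    attr(tables$outer_kinetochore, "analysis") <- "outer_kinetochore"
  }
  if (has_fibers && cfg$analyses[["kmt_number"]]) {
    kn <- kmt_number_stats(spindle)
    tables$kmt_number <- metric_table("kmt_number", kn$per_fiber)
    tables$kmt_number_correlations <- metric_table("kmt_number_correlations",
                                                   kn$correlations)
  }
  with_gid <- function(df) {
    cbind(data.frame(graph_id = rep(gid, nrow(df))), df)
  }
  if (cfg$analyses[["branching"]]) {
    br <- detect_kmt_branching(spindle, threshold = par$branch_threshold,
                               exclude_same_fiber = par$exclude_same_fiber)
    tables$branching <- metric_table("branching", with_gid(br))
  }
  if (cfg$analyses[["interactions"]]) {
    ia <- detect_mt_interactions(spindle, threshold = par$interaction_threshold)
    tables$interactions <- metric_table("interactions", with_gid(ia))
  }
  if (!has_fibers && any(cfg$analyses[c("twist", "helicity", "area", "density",
                                        "outer_kinetochore", "kmt_number")])) {
    note("no k-fiber labels: fiber-level analyses skipped")
  }
  list(tables = tables, warnings = warn)
}

#' Run the analysis pipeline
#'
#' For each input spatial graph: validate, preprocess (resample, reorient,
#' assign ends, build fibers, pair sisters) and run the toggled analyses,
#' writing one table directory per input plus a run manifest.  A file that
#' fails validation is reported in the manifest with a hint and skipped
#' while the remaining files proceed; only zero valid inputs is an error.
#' Given identical inputs and configuration the table files are
#' byte-identical across runs (the manifest carries the only timestamp).
#'
#' @param config an [analysis_config()].
#' @return Invisibly, the manifest list (`n_ok`, `n_failed`, per-file
#'   status and warnings).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  n_ok <- 0L
  for (i in seq_along(config$input)) {
    path <- config$input[i]
    stem <- sub("\\.[^.]*$", "", basename(path))
    rec <- list(file = path, status = "ok", warnings = character(0), hint = NULL)
    res <- tryCatch({
      wrn <- character(0)
      sp <- withCallingHandlers({
        g <- read_spatial_graph(path, graph_id = i,
                                units = config$params$units)
        sp <- as_spindle(g, pole1 = config$pole1, pole2 = config$pole2,
                         axis = config$params$axis,
                         resample_spacing = config$params$resample_spacing)
        preprocess_spindle(sp, spacing = config$params$resample_spacing,
                           twist_step = config$params$twist_step,
                           cone_deg = config$params$sister_cone_deg)
      }, warning = function(w) {
        wrn <<- c(wrn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      out <- .analyze_one(sp, config)
      export_tables(out$tables, file.path(config$output_dir, stem),
                    format = config$format)
      rec$warnings <- c(wrn, out$warnings)
      rec$tables <- names(out$tables)
      rec
    }, error = function(e) {
      rec$status <- "failed"
      rec$error <- conditionMessage(e)
      rec$hint <- paste("check that the file is an ASCII AmiraMesh",
                        "HxSpatialGraph export with matching VERTEX/EDGE/POINT",
                        "counts and a KMT edge label")
      rec
    })
    if (identical(res$status, "ok")) n_ok <- n_ok + 1L
    files[[stem]] <- res
  }
  if (n_ok == 0L) {
    stop("no valid input files (", length(config$input), " failed)")
  }
  manifest <- list(package_version = as.character(utils::packageVersion("spindlegraph")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = list(analyses = as.list(config$analyses),
                                 params = config$params,
                                 format = config$format),
                   n_ok = n_ok, n_failed = length(files) - n_ok,
                   files = files)
  jsonlite::write_json(manifest, file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
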