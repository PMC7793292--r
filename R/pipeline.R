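# End-to-end orchestration: a declarative config (JSON file or R list)
# selects analysis stages; each stage draws from its own seed derived from
# the root seed, so adding a stage never perturbs another stage's stream.
# Partial failure of one stage is recorded and the remaining independent
# stages still run.

#' Validate and normalize a run configuration
#'
#' A config is a named list (or path to a JSON file) with an optional `seed`
#' (default 1) and one block per requested stage:
#' \describe{
#'   \item{ensemble}{synthetic two-protomer generator arguments
#'     ([ensemble_params]); provides the trajectory to the geometry stages.}
#'   \item{trajectory}{alternatively, a multi-model PDB path.}
#'   \item{rmsf}{list(align, target) selections per protomer (chain ids).}
#'   \item{vectors / asymmetry}{anchor resids and body-frame resid range.}
#'   \item{hinges}{segments B/C/N resid ranges and atom name.}
#'   \item{pocket}{pair (two atom specs) and binning.}
#'   \item{sasa}{pocket resids, probe radius, n_sphere_points.}
#'   \item{saxs}{model source ("sphere" generator or PDB path) and q grid.}
#'   \item{hill}{path to a curves CSV (concentration_nM, replicate,
#'     response) or inline generator arguments.}
#' }
#' @param config named list or JSON file path.
#' @return normalized config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("config schema error: expected a named list")
  config$seed <- as.integer(config$seed %||% 1L)
  known <- c("seed", "output_dir", "ensemble", "trajectory", "rmsf",
             "vectors", "asymmetry", "hinges", "pocket", "sasa", "saxs",
             "hill")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("config schema error: unknown block(s): ",
         paste(unknown, collapse = ", "))
  needs_traj <- intersect(names(config),
                          c("rmsf", "vectors", "asymmetry", "pocket", "sasa",
                            "hinges"))
  if (length(needs_traj) && is.null(config$ensemble) &&
      is.null(config$trajectory))
    stop("configuration error: stage(s) ", paste(needs_traj, collapse = ", "),
         " need an `ensemble` or `trajectory` block")
  for (st in c("vectors", "asymmetry"))
    if (!is.null(config[[st]]) &&
        (is.null(config[[st]]$anchorA_resid) ||
         is.null(config[[st]]$anchorB_resid)))
      stop("configuration error: stage `", st,
           "` requires anchorA_resid and anchorB_resid")
  config
}

stage_seed <- function(root_seed, stage) {
  # deterministic per-stage stream, independent of stage order; < 2^31
  (root_seed * 10007L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Run the configured analyses
#'
#' Executes the requested stages in dependency order; the returned report is
#' byte-identical across runs with the same (config, seed).
#'
#' @param config a config list or JSON path (see [run_config]).
#' @param verbose print stage progress to stderr.
#' @return an `analysis_report`: list(results = per-stage outputs,
#'   errors = per-stage failure messages, provenance).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- run_config(config)
  results <- list(); errors <- list()
  note <- function(...) if (verbose) message("[protasym] ", ...)
  run_stage <- function(name, fun) {
    if (is.null(cfg[[name]])) return()
    note("stage ", name)
    r <- tryCatch(fun(cfg[[name]]), error = function(e) e)
    if (inherits(r, "error")) errors[[name]] <<- conditionMessage(r)
    else results[[name]] <<- r
  }

  traj <- NULL
  if (!is.null(cfg$ensemble)) {
    ens_args <- cfg$ensemble
    ens_args$seed <- ens_args$seed %||% stage_seed(cfg$seed, "ensemble")
    gen <- make_two_protomer_ensemble(protomer_template(),
                                      do.call(ensemble_params, ens_args))
    traj <- gen$trajectory
    results$ensemble <- list(n_frames = n_frames(traj),
                             n_atoms = nrow(traj$topology),
                             seed = ens_args$seed)
  } else if (!is.null(cfg$trajectory)) {
    traj <- as_trajectory(cfg$trajectory)
  }

  core_range <- c(201, 265); mobile_range <- c(266, 360)

  run_stage("rmsf", function(b) {
    lapply(stats::setNames(nm = b$chains %||% c("A", "B")), function(ch) {
      prof <- compute_rmsf(
        traj,
        atom_selection(chain = ch,
                       resid_range = b$align_resids %||% core_range),
        atom_selection(chain = ch))
      list(profile = prof,
           mean_mobile = mean_rmsf(prof, ch,
                                   b$mobile_resids %||% mobile_range))
    })
  })

  vectors_fun <- function(b) {
    lapply(stats::setNames(nm = b$chains %||% c("A", "B")), function(ch)
      interdomain_vector_series(
        traj,
        atom_selection(chain = ch, resids = b$anchorA_resid,
                       names = b$anchor_name %||% "CA"),
        atom_selection(chain = ch, resids = b$anchorB_resid,
                       names = b$anchor_name %||% "CA"),
        atom_selection(chain = ch,
                       resid_range = b$body_resids %||% core_range)))
  }
  run_stage("vectors", vectors_fun)
  run_stage("asymmetry", function(b) {
    ser <- results$vectors %||% vectors_fun(b)
    res <- asymmetry_index(ser[[1]], ser[[2]])
    list(delta_theta = res$delta_theta, delta_phi = res$delta_phi,
         delta_d = res$delta_d, n_frames = res$n_frames)
  })

  run_stage("hinges", function(b) {
    hinge_angles(frame_model(traj, b$frame %||% 1L),
                 unlist(b$segB), unlist(b$segC), unlist(b$segN),
                 atom_name = b$atom_name %||% "CA", chain = b$chain)
  })

  run_stage("pocket", function(b) {
    lapply(stats::setNames(nm = b$chains %||% c("A", "B")), function(ch) {
      ser <- atom_pair_distance_series(
        traj,
        atom_selection(chain = ch, resids = b$pair_resids[1],
                       names = b$pair_names[1]),
        atom_selection(chain = ch, resids = b$pair_resids[2],
                       names = b$pair_names[2]))
      pop <- distance_population(ser, b$bin_width %||% 0.1)
      list(series = ser, population = pop,
           open_mass = population_mass(pop, b$open_A %||% 6.9,
                                       b$halfwidth %||% 0.6))
    })
  })

  run_stage("sasa", function(b) {
    lapply(stats::setNames(nm = b$chains %||% c("A", "B")), function(ch) {
      res <- pocket_sasa(traj,
                         atom_selection(chain = ch,
                                        resids = unlist(b$pocket_resids)),
                         probe_radius = b$probe_radius %||% 2.8,
                         n_sphere_points = b$n_sphere_points %||% 960L)
      list(mean_area_A2 = mean(res$area_A2), probe_radius = res$probe_radius)
    })
  })

  run_stage("saxs", function(b) {
    model <- if (identical(b$model, "sphere"))
      make_sphere_bead_model(b$radius %||% 10,
                             b$n_beads %||% 5000L,
                             seed = b$seed %||% stage_seed(cfg$seed, "saxs"))
    else read_structure(b$model)[[1]]
    qg <- seq(b$qmin %||% 0.005, b$qmax %||% 0.8,
              length.out = b$nq %||% 200)
    prof <- debye_profile(model, qg)
    pr <- pair_distance_distribution(model, b$pr_bin %||% 0.5)
    gu <- guinier_fit(prof, b$qrg_limit %||% 1.3)
    po <- porod_volume_mw(prof, gu$i0)
    kr <- kratky_transform(prof)
    list(rg_guinier = gu$rg, i0 = gu$i0, rg_pr = rg_from_pr(pr),
         dmax = pr$dmax, porod_volume = po$porod_volume,
         mw_kda = po$mw_kda, kratky_compact = kr$compact)
  })

  run_stage("hill", function(b) {
    d <- if (!is.null(b$data)) {
      dd <- utils::read.csv(b$data)
      class(dd) <- c("dose_response", "data.frame")
      dd
    } else {
      b$seed <- b$seed %||% stage_seed(cfg$seed, "hill")
      make_dose_response(b$ec50, b$hill_n, b$y0 %||% 0, b$ymax %||% 1,
                         noise_sigma = b$noise_sigma %||% 0.02,
                         n_replicates = b$n_replicates %||% 2L,
                         seed = b$seed)$data
    }
    fit <- fit_hill(d)
    list(ec50_nM = fit$ec50, hill_n = fit$hill_n, se_ec50 = fit$se_ec50,
         se_hill = fit$se_hill, converged = fit$converged)
  })

  report <- structure(list(results = results, errors = errors,
                           provenance = list(seed = cfg$seed,
                                             package = "protasym",
                                             version = "0.1.0")),
                      class = "analysis_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Write an analysis report to a directory
#'
#' JSON summary (scalar metrics) plus CSV tables for profile/series outputs.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summarize <- function(x) {
    if (is.data.frame(x)) return(NULL)
    if (is.list(x)) {
      out <- lapply(x, summarize)
      out <- out[!vapply(out, is.null, logical(1))]
      if (length(out)) out else NULL
    } else if (is.numeric(x) || is.logical(x) || is.character(x)) x
    else NULL
  }
  jsonlite::write_json(
    list(results = summarize(report$results), errors = report$errors,
         provenance = report$provenance),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  dump_tables <- function(x, prefix) {
    if (is.data.frame(x))
      utils::write.csv(x, file.path(dir, paste0(prefix, ".csv")),
                       row.names = FALSE)
    else if (is.list(x))
      for (nm in names(x)) dump_tables(x[[nm]], paste(prefix, nm, sep = "_"))
  }
  dump_tables(report$results, "protasym")
  invisible(dir)
}
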