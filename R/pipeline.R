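# Orchestration: validated run configuration, stage execution, manifests and
# report tables.

.CONFIG_KEYS <- c("output_dir", "seed", "stride_ns", "stages", "structure",
                  "ligand_sidecar", "trajectory", "criteria", "min_frequency",
                  "surfaces", "exposure", "msm", "hydration", "metadyn",
                  "synth")

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected by name. Returns the configuration with
#' defaults resolved (analysis defaults: interaction criteria at their
#' published values, 3 Angstrom exposure cutoff, 1.4 Angstrom probe, 40 ns
#' lag with 2 independent components and 3 metastable states, 0.5 overlap,
#' 10 Angstrom shell, 15 Angstrom dissociation distance, 1 ns stride).
#'
#' @param config named list or path to a YAML file.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  config$seed <- config$seed %||% 2022
  config$stride_ns <- config$stride_ns %||% 1
  config$stages <- config$stages %||% c("interactions", "exposure")
  config$min_frequency <- config$min_frequency %||% 0.15
  config$criteria <- do.call(interaction_criteria,
                             config$criteria %||% list())
  config$surfaces <- modifyList(list(probe = 1.4, n_points = 480),
                                config$surfaces %||% list())
  config$exposure <- modifyList(list(cutoff = 3.0, residues = NULL),
                                config$exposure %||% list())
  config$msm <- modifyList(list(lag_ns = 40, n_tica = 2, n_states = 3,
                                k = NULL),
                           config$msm %||% list())
  config$hydration <- modifyList(list(radius = 1.0, shell = 10.0,
                                      overlap_offset = 1.4,
                                      overlap_threshold = 0.5, sites = NULL),
                                 config$hydration %||% list())
  config$metadyn <- modifyList(list(threshold = 15.0, traces = NULL),
                               config$metadyn %||% list())
  config
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (interactions,
#' surfaces and exposure are independent; the MSM stage feeds the hydration
#' weighting), writing one TSV per stage plus a manifest that echoes the
#' resolved configuration, seeds and stage statuses - enough to re-run the
#' analysis bit-identically. A stage error aborts the run with the stage
#' name; completed outputs are retained.
#'
#' @param config named list or YAML path, see [validate_config()].
#' @param inputs optional list of in-memory inputs (trajectory, features,
#'   water_positions, sites, ligand, metad_traces) overriding file paths.
#' @return list of stage results, invisibly; outputs land in
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config, inputs = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "restime",
                   version = as.character(utils::packageVersion("restime")),
                   seed = cfg$seed, stride_ns = cfg$stride_ns,
                   stages = list())
  results <- list()
  tsv <- function(x, name) {
    path <- file.path(cfg$output_dir, name)
    write.table(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  traj <- inputs$trajectory
  if (is.null(traj) && !is.null(cfg$trajectory)) {
    s <- read_pdb_structure(cfg$structure, cfg$ligand_sidecar)
    traj <- read_trajectory(cfg$trajectory, s, cfg$stride_ns)
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    elapsed <- round(proc.time()[3] - t0, 2)
    manifest$stages[[name]] <<- list(status = "ok", seconds = elapsed)
    message(sprintf("[restime] stage=%s status=ok seconds=%.2f seed=%d",
                    name, elapsed, cfg$seed))
    results[[name]] <<- res
    res
  }
  if ("interactions" %in% cfg$stages) run_stage("interactions", function() {
    ev <- detect_interactions(traj, cfg$criteria)
    tab <- tabulate_frequencies(ev, n_frames(traj), cfg$min_frequency)
    tsv(tab, "interactions.tsv")
    tab
  })
  if ("surfaces" %in% cfg$stages) run_stage("surfaces", function() {
    su <- surface_trajectory(traj, probe = cfg$surfaces$probe,
                             n_points = cfg$surfaces$n_points)
    tsv(su, "surfaces.tsv")
    tsv(report_box_stats(su[, -1, drop = FALSE]), "surfaces_summary.tsv")
    su
  })
  if ("exposure" %in% cfg$stages) run_stage("exposure", function() {
    res <- cfg$exposure$residues %||%
      unique(traj$structure$atoms$resno[traj$structure$atoms$sidechain])
    tr <- exposure_trace(traj, res, cutoff = cfg$exposure$cutoff)
    tsv(tr, "exposure.tsv")
    tsv(summarise_exposure(tr), "exposure_summary.tsv")
    tr
  })
  if ("msm" %in% cfg$stages) run_stage("msm", function() {
    feats <- inputs$features %||% featurize_backbone_torsions(traj)
    fit <- fit_msm(feats, lag_ns = cfg$msm$lag_ns,
                   stride_ns = cfg$stride_ns, n_tica = cfg$msm$n_tica,
                   k = cfg$msm$k, n_states = cfg$msm$n_states,
                   seed = cfg$seed)
    tsv(data.frame(state = seq_along(fit$pcca$pi), pi = fit$pcca$pi),
        "msm_pi.tsv")
    fit
  })
  if ("hydration" %in% cfg$stages) run_stage("hydration", function() {
    sites <- inputs$sites
    if (is.null(sites) && !is.null(cfg$hydration$sites))
      sites <- read_hydration_sites(cfg$hydration$sites)
    if (is.null(sites)) {
      lig <- ligand_geometry(inputs$ligand %||% frame_structure(traj, 1))
      sites <- cluster_hydration_sites(inputs$water_positions,
                                       radius = cfg$hydration$radius,
                                       shell_center = lig$xyz,
                                       shell = cfg$hydration$shell)
      sites$delta_g <- estimate_site_energy(sites$occupancy, sites$n_frames[1],
                                            radius = cfg$hydration$radius)
    }
    sc <- ligand_displacement_score(sites,
                                    inputs$ligand %||% frame_structure(traj, 1),
                                    threshold = cfg$hydration$overlap_threshold,
                                    offset = cfg$hydration$overlap_offset)
    tsv(sc$sites, "hydration_sites.tsv")
    pi <- if (!is.null(results$msm)) results$msm$pcca$pi else NULL
    if (!is.null(pi)) {
      ws <- weighted_state_score(rep(sc$score, length(pi)), pi)
      tsv(data.frame(state = seq_along(pi), score = ws$state_scores, pi = pi,
                     weighted_average = ws$weighted_average),
          "hydration_weighted.tsv")
    }
    sc
  })
  if ("metadyn" %in% cfg$stages) run_stage("metadyn", function() {
    traces <- inputs$metad_traces
    if (is.null(traces) && !is.null(cfg$metadyn$traces)) {
      files <- cfg$metadyn$traces
      traces <- data.frame(compound = files$compound, state = files$state)
      traces$max_cv <- vapply(files$path, function(p)
        max(read_cv_trace(p)$cv), numeric(1))
    }
    tab <- build_dissociation_table(traces, threshold = cfg$metadyn$threshold)
    tsv(as.data.frame(tab), "dissociation.tsv")
    tab
  })
  yaml::write_yaml(list(manifest = manifest,
                        config = config_for_manifest(cfg)),
                   file.path(cfg$output_dir, "manifest.yaml"))
  invisible(results)
}

config_for_manifest <- function(cfg) {
  cfg$criteria <- unclass(cfg$criteria)
  cfg
}

#' Box-plot summary statistics
#'
#' Median, quartiles (linear interpolation of order statistics, type 7),
#' whiskers at the furthest points within 1.5 IQR of the quartiles, and the
#' outlier count, for every numeric column.
#'
#' @param df data.frame of numeric columns.
#' @return data.frame(variable, median, q25, q75, whisker_low, whisker_high,
#'   n_outliers).
#' @export
report_box_stats <- function(df) {
  do.call(rbind, lapply(names(df), function(v) {
    x <- df[[v]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(variable = v, median = q[2], q25 = q[1], q75 = q[3],
               whisker_low = lo, whisker_high = hi,
               n_outliers = sum(x < lo | x > hi))
  }))
}

#' Assemble report tables from stage outputs
#'
#' @param results list returned by [run_pipeline()].
#' @param min_frequency strict frequency filter for the interaction table.
#' @return list of summary tables; an empty frequency table is rendered as
#'   the string "no interactions above threshold".
#' @export
build_report <- function(results, min_frequency = 0.15) {
  out <- list()
  if (!is.null(results$interactions)) {
    tab <- results$interactions
    tab <- tab[tab$frequency > min_frequency, , drop = FALSE]
    out$interactions <- if (nrow(tab)) tab else "no interactions above threshold"
  }
  if (!is.null(results$surfaces))
    out$surfaces <- report_box_stats(results$surfaces[, -1, drop = FALSE])
  if (!is.null(results$exposure))
    out$exposure <- summarise_exposure(results$exposure)
  if (!is.null(results$metadyn)) out$dissociation <- results$metadyn
  if (!is.null(results$msm))
    out$equilibrium <- data.frame(state = seq_along(results$msm$pcca$pi),
                                  pi = results$msm$pcca$pi)
  out
}
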