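#' Run a configuration-driven analysis battery
#'
#' Orchestrates the package's analyses over one trajectory ensemble from a
#' single YAML (or list) configuration: per-frame gate-state classification
#' and ensemble fractions (`gate`), chi dihedral series (`chi`), water
#' occupancy maps (`occupancy`), ion-site binding traces (`ions`), and
#' residue probe accessibility (`sasa`). Analyses run in declared order;
#' per-analysis CSV/JSON/DX files are written under the output directory
#' together with a combined machine-readable report (config hash, package
#' version, frame counts, and an md5 checksum for every output file).
#' Referenced files are validated before any computation; any module error
#' aborts the run with that module's message.
#'
#' Configuration fields: `topology` (PDB path), `trajectories` (character
#' vector of DCD/PDB paths), `outdir`, and `analyses`, a named list whose
#' entries select and parameterize the modules, e.g.
#' `analyses: gate: {cutoff: 3.2}`, `chi: {resid: 332, chi: 2}`,
#' `occupancy: {centerResid: 98, radius: 20, spacing: 1.0}`,
#' `ions: {site: Cl, persistenceWindow: 25}`,
#' `sasa: {resid: 107, probeRadius: 3.0}`. Defaults mirror the analyses'
#' conventional parameters (3.2 A gate cutoff, 3.0 A probe, 2.5/3.5 A ion
#' cutoffs, 20 A region radius).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param outdir optional override of the config's output directory.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
runAnalysis <- function(config, outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("config must name an output directory", call. = FALSE)
  known <- c("gate", "chi", "occupancy", "ions", "sasa")
  anNames <- names(config$analyses)
  if (!length(anNames)) stop("config enables no analyses", call. = FALSE)
  bad <- setdiff(anNames, known)
  if (length(bad))
    stop("unknown analysis block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$topology) || !file.exists(config$topology))
    stop("topology file not found: ", config$topology, call. = FALSE)
  trajPaths <- unlist(config$trajectories)
  missing <- trajPaths[!file.exists(trajPaths)]
  if (length(missing))
    stop("trajectory file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  st <- readStructure(config$topology)
  trajs <- lapply(trajPaths, function(p)
    readTrajectory(p, st$topology, label = basename(p)))
  outputs <- character(0)
  results <- list()
  emit <- function(path) outputs <<- c(outputs, path)

  for (an in anNames) {
    p <- config$analyses[[an]]
    if (is.null(p)) p <- list()
    message("runAnalysis: ", an, " over ", length(trajs), " trajectories")
    if (an == "gate") {
      cutoff <- p$cutoff %||% 3.2
      series <- lapply(trajs, classifyGateStates, cutoff = cutoff,
                       stride = p$stride %||% 1L)
      perFrame <- do.call(rbind, lapply(series, function(s)
        data.frame(trajectory = trajLabel(s),
                   frame = seq_along(s@states), state = as.character(s@states),
                   dist_gln = s@distGln, dist_glu = s@distGlu)))
      f1 <- file.path(outdir, "gate.csv")
      utils::write.csv(perFrame, f1, row.names = FALSE); emit(f1)
      fr <- stateFractions(series)
      f2 <- file.path(outdir, "gate_fractions.csv")
      utils::write.csv(data.frame(state = rownames(fr@fractions),
                                  fr@fractions, mean = fr@mean, sd = fr@sd,
                                  check.names = FALSE),
                       f2, row.names = FALSE); emit(f2)
      f3 <- file.path(outdir, "gate_fractions.json")
      jsonlite::write_json(list(mean = as.list(fr@mean), sd = as.list(fr@sd),
                                n_trajectories = fr@nTrajectories),
                           f3, auto_unbox = TRUE, digits = NA); emit(f3)
      results$gate <- list(mean = fr@mean, sd = fr@sd)
    } else if (an == "chi") {
      resid <- p$resid %||% 332L
      chiIndex <- p$chi %||% 1L
      perTraj <- do.call(rbind, lapply(trajs, function(tr) {
        s <- chiSeries(tr, resid, chiIndex)
        cbind(trajectory = trajLabel(tr), s)
      }))
      f1 <- file.path(outdir, sprintf("chi%d_res%d.csv", chiIndex, resid))
      utils::write.csv(perTraj, f1, row.names = FALSE); emit(f1)
      results$chi <- table(perTraj$rotamer) / nrow(perTraj)
    } else if (an == "occupancy") {
      grid <- buildRegionGrid(st$topology, st$frame,
                              centerResid = p$centerResid %||% 98L,
                              radius = p$radius %||% 20,
                              spacing = p$spacing %||% 1.0)
      map <- occupancyMap(trajs, grid, st$frame)
      f1 <- file.path(outdir, "occupancy.dx")
      writeGridDX(map, f1); emit(f1)
      results$occupancy <- list(maxOccupancy = max(map@values),
                                nFrames = map@nFramesTotal)
    } else if (an == "ions") {
      site <- p$site %||% "Cl"
      traces <- lapply(trajs, bindingTrace, site = site,
                       persistenceWindow = p$persistenceWindow %||% 25L)
      perFrame <- do.call(rbind, lapply(traces, function(tr)
        data.frame(trajectory = tr@label, frame = seq_along(tr@bound),
                   coordination = tr@counts, bound = tr@bound)))
      f1 <- file.path(outdir, sprintf("ions_%s.csv", site))
      utils::write.csv(perFrame, f1, row.names = FALSE); emit(f1)
      stats <- dwellStatistics(traces)
      f2 <- file.path(outdir, sprintf("ions_%s.json", site))
      jsonlite::write_json(stats, f2, auto_unbox = TRUE, digits = NA); emit(f2)
      results$ions <- stats
    } else if (an == "sasa") {
      resid <- p$resid %||% 107L
      params <- sasaParameters(probeRadius = p$probeRadius %||% 3.0,
                               nSpherePoints = p$nSpherePoints %||% 960L)
      acc <- residueAccessibility(trajs, resid, params)
      f1 <- file.path(outdir, sprintf("sasa_res%d.json", resid))
      jsonlite::write_json(list(per_traj = acc$perTrajectory$mean,
                                mean = acc$mean, sd = acc$sd,
                                n_traj = acc$nTrajectories),
                           f1, auto_unbox = TRUE, digits = NA); emit(f1)
      f2 <- file.path(outdir, sprintf("sasa_res%d.csv", resid))
      utils::write.csv(acc$perTrajectory, f2, row.names = FALSE); emit(f2)
      results$sasa <- list(mean = acc$mean, sd = acc$sd)
    }
  }
  report <- list(
    config_hash = .hashConfig(config),
    package_version = as.character(utils::packageVersion("gatescope")),
    topology_atoms = nAtoms(st$topology),
    frame_counts = vapply(trajs, nFrames, integer(1)),
    analyses = anNames,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hashConfig <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}
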