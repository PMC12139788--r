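#' Build a zeroed occupancy grid around a reference selection
#'
#' Axis-aligned cubic-voxel grid of edge `2 * radius`, centred on the
#' centroid of the centre selection in the reference frame. Voxels outside
#' the sphere are retained but flagged (`inSphere = FALSE`).
#'
#' @param topology a [Topology-class].
#' @param reference `n x 3` reference frame.
#' @param centerResid residue number(s) of the centre selection.
#' @param radius Angstrom (default 20).
#' @param spacing Angstrom per voxel edge (default 1).
#' @param centerNames optional atom names for the centre selection
#'   (default all atoms of the residue).
#' @return a zeroed [OccupancyGrid-class].
#' @export
buildRegionGrid <- function(topology, reference, centerResid = 98L,
                            radius = 20, spacing = 1, centerNames = NULL) {
  if (radius <= 0 || spacing <= 0)
    stop("radius and spacing must be positive", call. = FALSE)
  sel <- selectAtoms(topology, resid = centerResid, names = centerNames)
  center <- colMeans(reference[sel, , drop = FALSE])
  n <- as.integer(ceiling(2 * radius / spacing))
  counts <- rep(n, 3L)
  origin <- center - n * spacing / 2
  centers <- (seq_len(n) - 0.5) * spacing
  cx <- origin[1] + centers - center[1]
  cy <- origin[2] + centers - center[2]
  cz <- origin[3] + centers - center[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  new("OccupancyGrid", origin = origin, spacing = spacing,
      counts = counts, values = array(0, counts),
      inSphere = array(d2 <= radius^2, counts), nFramesTotal = 0L)
}

#' Volumetric occupancy map over a trajectory ensemble
#'
#' Each frame is first superposed onto the reference frame over the
#' alignment selection (so maps are computed in a common protein frame);
#' then a voxel's per-frame indicator is 1 if at least one selected atom
#' centre falls inside it. The value is the mean indicator over all frames
#' of all trajectories, pooled with equal weight. Frames in which the
#' species selection places no atom in the region simply contribute zero
#' indicators.
#'
#' @param trajectories list of [Trajectory-class] (or one) sharing a
#'   topology.
#' @param grid a zeroed grid from [buildRegionGrid()].
#' @param reference `n x 3` reference frame the grid was built against.
#' @param speciesResname,speciesNames species selection (default water
#'   oxygens: resname HOH, name O).
#' @param alignResname,alignNames alignment selection (default all CA
#'   atoms).
#' @param perTrajectory if TRUE, also return one map per trajectory.
#' @return the filled [OccupancyGrid-class]; with `perTrajectory = TRUE`, a
#'   list with `pooled` and `perTrajectory`.
#' @export
occupancyMap <- function(trajectories, grid, reference,
                         speciesResname = "HOH", speciesNames = "O",
                         alignResname = NULL, alignNames = "CA",
                         perTrajectory = FALSE) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  top <- trajectories[[1]]@topology
  species <- .selectQuiet(top, resname = speciesResname, names = speciesNames)
  if (!length(species))
    warning("species selection resolves to 0 atoms; map will be identically 0")
  alignSel <- selectAtoms(top, resname = alignResname, names = alignNames)
  if (max(alignSel) > nrow(reference))
    stop("reference frame does not cover the alignment selection", call. = FALSE)
  refSel <- reference[alignSel, , drop = FALSE]
  n <- grid@counts
  tallyOne <- function(traj) {
    tally <- integer(prod(n))
    nf <- nFrames(traj)
    for (f in seq_len(nf)) {
      fr <- frameCoords(traj, f)
      k <- .kabsch(fr[alignSel, , drop = FALSE], refSel)
      fr <- sweep(sweep(fr, 2, k$xc) %*% t(k$R), 2, k$yc, FUN = "+")
      if (!length(species)) next
      idx <- floor(sweep(fr[species, , drop = FALSE], 2, grid@origin) /
                     grid@spacing) + 1
      ok <- idx[, 1] >= 1 & idx[, 1] <= n[1] & idx[, 2] >= 1 &
        idx[, 2] <= n[2] & idx[, 3] >= 1 & idx[, 3] <= n[3]
      if (!any(ok)) next
      lin <- unique((idx[ok, 3] - 1L) * n[1] * n[2] +
                      (idx[ok, 2] - 1L) * n[1] + idx[ok, 1])
      tally[lin] <- tally[lin] + 1L
    }
    list(tally = tally, nf = nf)
  }
  per <- lapply(trajectories, tallyOne)
  total <- Reduce(`+`, lapply(per, `[[`, "tally"))
  nfTotal <- sum(vapply(per, `[[`, integer(1), "nf"))
  pooled <- new("OccupancyGrid", origin = grid@origin, spacing = grid@spacing,
                counts = n, values = array(total / nfTotal, n),
                inSphere = grid@inSphere, nFramesTotal = as.integer(nfTotal))
  if (!perTrajectory) return(pooled)
  maps <- lapply(per, function(p)
    new("OccupancyGrid", origin = grid@origin, spacing = grid@spacing,
        counts = n, values = array(p$tally / p$nf, n),
        inSphere = grid@inSphere, nFramesTotal = as.integer(p$nf)))
  list(pooled = pooled, perTrajectory = maps)
}
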