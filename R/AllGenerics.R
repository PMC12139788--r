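#' Accessors for gatescope objects
#'
#' Small accessor generics; prefer these over direct slot access.
#'
#' @param x a gatescope S4 object.
#' @param ... further arguments for methods.
#' @return `atoms()` the atom data.frame; `nAtoms()`/`nFrames()` integers;
#'   `frameCoords()` an `n_atoms x 3` coordinate matrix; `trajLabel()` a
#'   character label; `gateStates()` the per-frame state factor;
#'   `fractionTable()` the 4 x n fraction matrix; `gridValues()` the voxel
#'   array; `boundFlags()` the per-frame logical vector;
#'   `dwellSegments()` the segment data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @param i frame index (1-based).
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("trajLabel", function(x) standardGeneric("trajLabel"))
#' @rdname accessors
#' @export
setGeneric("gateStates", function(x) standardGeneric("gateStates"))
#' @rdname accessors
#' @export
setGeneric("fractionTable", function(x) standardGeneric("fractionTable"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("boundFlags", function(x) standardGeneric("boundFlags"))
#' @rdname accessors
#' @export
setGeneric("dwellSegments", function(x) standardGeneric("dwellSegments"))

#' @rdname accessors
#' @export
setMethod("atoms", "Topology", function(x, ...) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x, ...) x@topology@atoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i = 1L) {
  stopifnot(i >= 1L, i <= dim(x@coords)[3])
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})
#' @rdname accessors
#' @export
setMethod("trajLabel", "Trajectory", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("gateStates", "GateStateSeries", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("nFrames", "GateStateSeries", function(x) length(x@states))
#' @rdname accessors
#' @export
setMethod("trajLabel", "GateStateSeries", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("fractionTable", "StateFractions", function(x) x@fractions)
#' @rdname accessors
#' @export
setMethod("gridValues", "OccupancyGrid", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("boundFlags", "BindingTrace", function(x) x@bound)
#' @rdname accessors
#' @export
setMethod("dwellSegments", "BindingTrace", function(x) x@segments)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = " ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory '%s': %d frames x %d atoms\n",
              object@label, nFrames(object), nAtoms(object)))
})

setMethod("show", "GateStateSeries", function(object) {
  tab <- table(object@states) / length(object@states)
  cat(sprintf("GateStateSeries '%s': %d frames\n", object@label,
              length(object@states)))
  print(round(tab, 4))
})

setMethod("show", "StateFractions", function(object) {
  cat(sprintf("StateFractions over %d trajectories\n", object@nTrajectories))
  print(round(rbind(mean = object@mean, sd = object@sd), 4))
})

setMethod("show", "OccupancyGrid", function(object) {
  cat(sprintf(
    "OccupancyGrid: %d x %d x %d voxels, spacing %.3g A, origin (%.4g, %.4g, %.4g)\n",
    object@counts[1], object@counts[2], object@counts[3], object@spacing,
    object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  %d frames averaged; occupancy range [%.4g, %.4g]\n",
              object@nFramesTotal, min(object@values), max(object@values)))
})

setMethod("show", "BindingTrace", function(object) {
  cat(sprintf(
    "BindingTrace (site %s, trajectory '%s'): %d frames, %d segments, %s\n",
    object@site, object@label, length(object@bound), nrow(object@segments),
    if (is.na(object@firstUnbinding)) "no lasting unbinding"
    else sprintf("first unbinding at frame %d", object@firstUnbinding)))
})

setMethod("show", "RateConstantFit", function(object) {
  cat(sprintf(
    "RateConstantFit: k = %.4g M^-1 min^-1 (95%% CI +/- %.3g), c_half = %.4g M, t = %g min\n",
    object@k, object@kCI, object@cHalf, object@exposureTime))
})
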