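#' @import methods
NULL

#' Topology of a molecular system
#'
#' Ordered atom table for one molecular system. Atom order is file order and
#' is never re-sorted; residue numbers are the author-assigned numbers (no
#' re-indexing). Van der Waals radii are assigned from the embedded Bondi
#' table at construction (see [vdwRadius()]).
#'
#' @slot atoms data.frame with columns `serial` (integer), `name` (PDB-style
#'   atom name), `element` (element symbol), `resname` (3-letter residue
#'   code), `resid` (integer author residue number), `chain` (single
#'   character), `radius` (van der Waals radius, Angstrom).
#'
#' @seealso [readStructure()], [selectAtoms()], [makeToyTransporter()]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain", "radius")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1) return("topology must contain at least one atom")
  if (any(!is.finite(a$radius)) || any(a$radius <= 0))
    return("all vdW radii must be positive and finite")
  if (any(duplicated(paste(a$chain, a$resid, a$name))))
    return("duplicate (chain, resid, name) atom identifiers")
  TRUE
})

#' Trajectory of frames sharing one topology
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom.
#' All frames share the topology; every trajectory has at least one frame.
#'
#' @slot topology a [Topology-class] object.
#' @slot coords numeric array, `n_atoms x 3 x n_frames`, Angstrom.
#' @slot times numeric vector of frame times in ps (length `n_frames`, or
#'   length 0 when times are unknown).
#' @slot box numeric matrix of box lengths (`n_frames x 3`, Angstrom), or a
#'   0-row matrix when no box is recorded.
#' @slot label character replica identifier.
#'
#' @seealso [readTrajectory()], [simulateGateTrajectories()]
#' @export
setClass("Trajectory", representation(
  topology = "Topology", coords = "array", times = "numeric",
  box = "matrix", label = "character"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[3] < 1L) return("a trajectory must contain at least one frame")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("coordinate count (%d) does not match topology atom count (%d)",
                   d[1], nrow(object@topology@atoms)))
  if (any(!is.finite(object@coords))) return("all coordinates must be finite")
  if (length(object@times) && length(object@times) != d[3])
    return("times must have one entry per frame (or length 0)")
  TRUE
})

#' Per-frame gate-state series
#'
#' One categorical gate state per frame of a trajectory, from the four-way
#' decomposition of the extracellular Arg contact network: hydrogen-bonded to
#' the conserved glutamine only (`GLN_ONLY`), to the acidic gate partner only
#' (`GLU_ONLY`), to `BOTH`, or to `NEITHER`.
#'
#' @slot states factor of length `n_frames` with levels
#'   `GLN_ONLY`, `GLU_ONLY`, `BOTH`, `NEITHER`.
#' @slot distGln numeric minimum donor-acceptor distance to the glutamine
#'   acceptor set, per frame (Angstrom).
#' @slot distGlu numeric minimum donor-acceptor distance to the glutamate
#'   acceptor set, per frame (Angstrom).
#' @slot label character trajectory label.
#' @seealso [classifyGateStates()], [stateFractions()]
#' @export
setClass("GateStateSeries", representation(
  states = "factor", distGln = "numeric", distGlu = "numeric",
  label = "character"))

gateStateLevels <- c("GLN_ONLY", "GLU_ONLY", "BOTH", "NEITHER")

setValidity("GateStateSeries", function(object) {
  if (!identical(levels(object@states), gateStateLevels))
    return("states must have levels GLN_ONLY, GLU_ONLY, BOTH, NEITHER")
  if (anyNA(object@states)) return("states must not contain NA")
  TRUE
})

#' Gate-state fractions across an ensemble
#'
#' Per-trajectory occupancy fraction of each gate state, with the ensemble
#' mean and across-trajectory sample standard deviation per category.
#'
#' @slot fractions numeric matrix, 4 categories x n trajectories; each column
#'   sums to 1.
#' @slot mean named numeric, ensemble mean fraction per category.
#' @slot sd named numeric, sample SD (denominator n-1) across trajectories;
#'   reported as 0 (with a warning at computation time) when n = 1.
#' @slot nTrajectories integer.
#' @seealso [stateFractions()]
#' @export
setClass("StateFractions", representation(
  fractions = "matrix", mean = "numeric", sd = "numeric",
  nTrajectories = "integer"))

setValidity("StateFractions", function(object) {
  f <- object@fractions
  if (nrow(f) != 4L) return("fractions must have 4 rows (gate states)")
  if (any(abs(colSums(f) - 1) > 1e-12))
    return("each trajectory's four fractions must sum to 1")
  if (any(object@sd < 0)) return("SDs must be non-negative")
  TRUE
})

#' Volumetric occupancy grid
#'
#' Axis-aligned cubic-voxel grid whose value in each voxel is the fraction of
#' frames in which at least one selected atom centre lies inside the voxel.
#'
#' @slot origin numeric length-3, Angstrom (corner of voxel \[1,1,1\]).
#' @slot spacing numeric scalar, Angstrom per voxel edge.
#' @slot counts integer length-3 voxel counts per axis.
#' @slot values numeric array `counts[1] x counts[2] x counts[3]`, in \[0,1\].
#' @slot inSphere logical array of the same shape flagging voxels whose
#'   centre lies inside the spherical region of interest.
#' @slot nFramesTotal integer number of frames averaged.
#' @seealso [buildRegionGrid()], [occupancyMap()], [writeGridDX()]
#' @export
setClass("OccupancyGrid", representation(
  origin = "numeric", spacing = "numeric", counts = "integer",
  values = "array", inSphere = "array", nFramesTotal = "integer"))

setValidity("OccupancyGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  if (length(object@counts) != 3L || any(object@counts <= 0L))
    return("counts must be 3 positive integers")
  if (!identical(dim(object@values), as.integer(object@counts)))
    return("values array shape must equal counts")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    return("occupancy values must lie in [0, 1]")
  TRUE
})

#' Ion-site binding trace
#'
#' Per-frame coordination counts and bound flags for one ion against one site
#' definition, with run-length dwell segments and the first lasting unbinding
#' frame.
#'
#' @slot counts integer per-frame coordination count.
#' @slot bound logical per-frame flag, `counts >= min_coordination`.
#' @slot segments data.frame with columns `start`, `end` (1-based inclusive
#'   frame indices) and `bound`; segments tile the trajectory.
#' @slot firstUnbinding integer 1-based frame index of the first unbound
#'   segment persisting at least `persistence_window` frames, or
#'   `NA_integer_` if the ion never (lastingly) unbinds.
#' @slot site character site name.
#' @slot label character trajectory label.
#' @seealso [bindingTrace()], [dwellStatistics()]
#' @export
setClass("BindingTrace", representation(
  counts = "integer", bound = "logical", segments = "data.frame",
  firstUnbinding = "integer", site = "character", label = "character"))

setValidity("BindingTrace", function(object) {
  if (length(object@counts) != length(object@bound))
    return("counts and bound must have equal length")
  s <- object@segments
  if (nrow(s)) {
    if (s$start[1] != 1L || s$end[nrow(s)] != length(object@bound) ||
        (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)] + 1L)))
      return("segments must tile the trajectory without gaps or overlap")
  }
  TRUE
})

#' Inactivation-kinetics fit
#'
#' Pseudo-first-order fit of fractional activity versus reagent
#' concentration at fixed exposure time, A(c) = exp(-k c t). The
#' half-maximal inactivation concentration satisfies k * c_half * t = ln 2.
#'
#' @slot k numeric second-order modification rate constant (M^-1 min^-1).
#' @slot cHalf numeric half-maximal inactivation concentration (M).
#' @slot exposureTime numeric exposure time t (min).
#' @slot kCI numeric half-width of the 95 percent confidence interval on k,
#'   from the local quadratic approximation at the optimum.
#' @slot residualNorm numeric root-sum-of-squares of fit residuals.
#' @slot nObs integer number of fitted observations.
#' @seealso [fitInactivation()], [relativeChange()]
#' @export
setClass("RateConstantFit", representation(
  k = "numeric", cHalf = "numeric", exposureTime = "numeric",
  kCI = "numeric", residualNorm = "numeric", nObs = "integer"))

setValidity("RateConstantFit", function(object) {
  if (object@k <= 0) return("k must be positive")
  if (abs(object@k * object@cHalf * object@exposureTime - log(2)) > 1e-9)
    return("k * c_half * t must equal ln 2")
  TRUE
})
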