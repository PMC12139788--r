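#' Minimum cross-pair distance between two selections
#'
#' Minimum Euclidean distance over the cross product of two atom
#' selections, excluding self-pairs. Ties break deterministically toward
#' the lowest atom indices (first of `selectionA`, then of `selectionB`).
#'
#' @param frame `n x 3` coordinate matrix.
#' @param selectionA,selectionB integer atom-index vectors (non-empty).
#' @return list with `distance` (Angstrom) and `pair` (the two atom
#'   indices).
#' @export
minPairDistance <- function(frame, selectionA, selectionB) {
  if (!length(selectionA) || !length(selectionB))
    stop("empty selection in minPairDistance", call. = FALSE)
  best <- Inf; pair <- c(NA_integer_, NA_integer_)
  for (i in selectionA) for (j in selectionB) {
    if (i == j) next
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (d < best) { best <- d; pair <- c(i, j) }
  }
  if (!is.finite(best))
    stop("no valid atom pair (selections consist of the same single atom)",
         call. = FALSE)
  list(distance = best, pair = pair)
}

#' Hydrogen-bond presence under the heavy-atom distance criterion
#'
#' A contact is present when the minimum donor-acceptor heavy-atom distance
#' is strictly below the cutoff; a pair at exactly the cutoff is absent.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param donor,acceptor integer atom-index selections.
#' @param cutoff Angstrom, default 3.2, strict `<`.
#' @return list with `present` (logical) and `distance` (Angstrom).
#' @export
hbondPresent <- function(frame, donor, acceptor, cutoff = 3.2) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  mp <- minPairDistance(frame, donor, acceptor)
  list(present = mp$distance < cutoff, distance = mp$distance)
}

#' Classify one frame's gate state
#'
#' Four-way decomposition of the gate arginine's contact network: `BOTH` if
#' the glutamine and glutamate contacts are both present, `GLN_ONLY` /
#' `GLU_ONLY` if exactly one is, `NEITHER` otherwise.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param donor integer indices of the arginine donor atoms.
#' @param acceptorGln,acceptorGlu integer indices of the two acceptor sets.
#' @param cutoff Angstrom, strict `<` (default 3.2).
#' @return character scalar, one of `GLN_ONLY`, `GLU_ONLY`, `BOTH`,
#'   `NEITHER`.
#' @export
classifyGateState <- function(frame, donor, acceptorGln, acceptorGlu,
                              cutoff = 3.2) {
  gln <- hbondPresent(frame, donor, acceptorGln, cutoff)$present
  glu <- hbondPresent(frame, donor, acceptorGlu, cutoff)$present
  if (gln && glu) "BOTH" else if (gln) "GLN_ONLY" else if (glu) "GLU_ONLY"
  else "NEITHER"
}

#' Per-frame gate-state series for a trajectory
#'
#' Vectorised classification of every frame (optionally strided) under the
#' heavy-atom distance criterion. Default selections address the serotonin
#' transporter's gate residues by author numbering: donors Arg104
#' NE/NH1/NH2; glutamine acceptor Gln332 OE1; glutamate acceptors Glu493
#' OE1/OE2 (the carboxylate oxygens).
#'
#' @param trajectory a [Trajectory-class].
#' @param donorResid,donorNames donor residue and atom names.
#' @param glnResid,glnNames glutamine acceptor residue and atom names.
#' @param gluResid,gluNames glutamate acceptor residue and atom names.
#' @param cutoff Angstrom, strict `<` (default 3.2).
#' @param stride frame stride (default 1, every frame).
#' @return a [GateStateSeries-class].
#' @export
classifyGateStates <- function(trajectory,
                               donorResid = 104L,
                               donorNames = c("NE", "NH1", "NH2"),
                               glnResid = 332L, glnNames = "OE1",
                               gluResid = 493L, gluNames = c("OE1", "OE2"),
                               cutoff = 3.2, stride = 1L) {
  top <- trajectory@topology
  donor <- selectAtoms(top, resid = donorResid, names = donorNames)
  accGln <- selectAtoms(top, resid = glnResid, names = glnNames)
  accGlu <- selectAtoms(top, resid = gluResid, names = gluNames)
  keep <- seq(1L, nFrames(trajectory), by = as.integer(stride))
  coords <- trajectory@coords[, , keep, drop = FALSE]
  minOver <- function(acc) {
    m <- rep(Inf, length(keep))
    for (i in donor) for (j in acc) {
      if (i == j) next
      m <- pmin(m, .pairDistanceSeries(coords, i, j))
    }
    m
  }
  dGln <- minOver(accGln)
  dGlu <- minOver(accGlu)
  gln <- dGln < cutoff; glu <- dGlu < cutoff
  states <- ifelse(gln & glu, "BOTH",
                   ifelse(gln, "GLN_ONLY", ifelse(glu, "GLU_ONLY", "NEITHER")))
  new("GateStateSeries",
      states = factor(states, levels = gateStateLevels),
      distGln = dGln, distGlu = dGlu, label = trajectory@label)
}

#' Ensemble gate-state fractions
#'
#' Per-trajectory state fractions, then mean and sample standard deviation
#' (denominator n-1) across trajectories — the across-replica error-bar
#' convention. For a single trajectory the SD is undefined and reported as 0
#' with a warning.
#'
#' @param series list of [GateStateSeries-class] (or a single one).
#' @return a [StateFractions-class].
#' @export
stateFractions <- function(series) {
  if (is(series, "GateStateSeries")) series <- list(series)
  if (!length(series)) stop("empty series list", call. = FALSE)
  frac <- vapply(series, function(s) {
    tab <- table(s@states)
    as.numeric(tab) / length(s@states)
  }, numeric(4))
  frac <- matrix(frac, nrow = 4,
                 dimnames = list(gateStateLevels,
                                 vapply(series, trajLabel, character(1))))
  m <- rowMeans(frac)
  if (ncol(frac) == 1L) {
    warning("single trajectory: across-trajectory SD undefined, reported as 0")
    s <- stats::setNames(rep(0, 4), gateStateLevels)
  } else s <- apply(frac, 1, stats::sd)
  new("StateFractions", fractions = frac, mean = m, sd = s,
      nTrajectories = ncol(frac))
}
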