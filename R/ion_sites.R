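#' Ion-site definition
#'
#' A site is a list of coordinating (residue, atom-name) pairs with an
#' inclusive distance cutoff and a minimum coordination number: the ion is
#' bound in a frame when at least `minCoordination` coordinating atoms lie
#' within `cutoff` of it.
#'
#' @param name site name.
#' @param coordinatingAtoms data.frame with columns `resid` and `name`.
#' @param cutoff Angstrom, inclusive (`<=`).
#' @param minCoordination minimum coordination number (default 2).
#' @param ionResname residue name of the ion atom (used to resolve the ion
#'   selection, e.g. "SOD" or "CLA").
#' @return list of class `IonSite`.
#' @export
ionSite <- function(name, coordinatingAtoms, cutoff, minCoordination = 2L,
                    ionResname = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (minCoordination < 1) stop("minCoordination must be >= 1", call. = FALSE)
  if (!nrow(coordinatingAtoms))
    stop("coordinating atom list must be non-empty", call. = FALSE)
  structure(list(name = name, coordinatingAtoms = coordinatingAtoms,
                 cutoff = cutoff,
                 minCoordination = as.integer(minCoordination),
                 ionResname = ionResname),
            class = "IonSite")
}

#' Built-in ion-site presets (Na1, Na2, Cl)
#'
#' Coordinating-atom lists for the transporter's three ion sites, with
#' inclusive cutoffs of 2.5 Angstrom for Na+ and 3.5 Angstrom for Cl- and a
#' minimum coordination number of 2: Na1 = Ala96 O, Asn101 OD1, Ser336
#' O/OG, Asn368 OD1; Na2 = Gly94 O, Val97 O, Leu434 O, Ser438 OG; Cl =
#' Asn101 ND2, Tyr121 OH, Gln332 NE2, Ser336 OG, Ser372 OG.
#'
#' @param name "Na1", "Na2" or "Cl".
#' @return an [ionSite()] definition.
#' @examples
#' ionSitePreset("Cl")$coordinatingAtoms
#' @export
ionSitePreset <- function(name = c("Na1", "Na2", "Cl")) {
  name <- match.arg(name)
  switch(name,
    Na1 = ionSite("Na1", data.frame(
      resid = c(96L, 101L, 336L, 336L, 368L),
      name = c("O", "OD1", "O", "OG", "OD1")), cutoff = 2.5,
      ionResname = "SOD"),
    Na2 = ionSite("Na2", data.frame(
      resid = c(94L, 97L, 434L, 438L),
      name = c("O", "O", "O", "OG")), cutoff = 2.5,
      ionResname = "SOD"),
    Cl = ionSite("Cl", data.frame(
      resid = c(101L, 121L, 332L, 336L, 372L),
      name = c("ND2", "OH", "NE2", "OG", "OG")), cutoff = 3.5,
      ionResname = "CLA"))
}

# Resolve the site's coordinating atoms and ion atom against a topology.
.resolveSite <- function(topology, site, ionIndex = NULL) {
  coordIdx <- vapply(seq_len(nrow(site$coordinatingAtoms)), function(i)
    selectAtoms(topology, resid = site$coordinatingAtoms$resid[i],
                names = site$coordinatingAtoms$name[i])[1], integer(1))
  if (is.null(ionIndex)) {
    if (is.null(site$ionResname))
      stop("site has no ion selection; give `ionIndex`", call. = FALSE)
    ionIndex <- selectAtoms(topology, resname = site$ionResname)[1]
  }
  list(coordIdx = coordIdx, ionIndex = ionIndex)
}

#' Coordination count of an ion against a site
#'
#' Number of coordinating atoms within the site's inclusive cutoff of the
#' ion in one frame.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param topology the matching [Topology-class].
#' @param site an [ionSite()] (or preset name).
#' @param ionIndex optional explicit atom index of the ion.
#' @return integer coordination count.
#' @export
coordinationCount <- function(frame, topology, site, ionIndex = NULL) {
  if (is.character(site)) site <- ionSitePreset(site)
  rs <- .resolveSite(topology, site, ionIndex)
  d <- sqrt(rowSums(sweep(frame[rs$coordIdx, , drop = FALSE], 2,
                          frame[rs$ionIndex, ])^2))
  sum(d <= site$cutoff)
}

#' Per-frame binding trace of an ion at a site
#'
#' Coordination counts and bound flags (`count >= minCoordination`) per
#' frame, run-length dwell segments, and the first lasting unbinding frame:
#' the first frame of the first unbound segment persisting at least
#' `persistenceWindow` frames (1-based; `NA` if the ion never lastingly
#' unbinds). The default window of 25 frames (100 ps at 4 ps output)
#' suppresses single-frame flicker.
#'
#' @param trajectory a [Trajectory-class].
#' @param site an [ionSite()] or preset name.
#' @param persistenceWindow frames (default 25).
#' @param ionIndex optional explicit ion atom index.
#' @return a [BindingTrace-class].
#' @export
bindingTrace <- function(trajectory, site, persistenceWindow = 25L,
                         ionIndex = NULL) {
  if (is.character(site)) site <- ionSitePreset(site)
  if (nFrames(trajectory) < 1) stop("empty trajectory", call. = FALSE)
  rs <- .resolveSite(trajectory@topology, site, ionIndex)
  co <- trajectory@coords
  nf <- nFrames(trajectory)
  counts <- integer(nf)
  for (j in rs$coordIdx)
    counts <- counts + (.pairDistanceSeries(co, rs$ionIndex, j) <= site$cutoff)
  bound <- counts >= site$minCoordination
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  segments <- data.frame(start = c(1L, utils::head(ends, -1L) + 1L),
                         end = as.integer(ends), bound = r$values)
  unb <- which(!segments$bound &
                 (segments$end - segments$start + 1L) >= persistenceWindow)
  first <- if (length(unb)) segments$start[unb[1]] else NA_integer_
  new("BindingTrace", counts = as.integer(counts), bound = bound,
      segments = segments, firstUnbinding = first,
      site = site$name, label = trajectory@label)
}

#' Dwell statistics over an ensemble of binding traces
#'
#' Mean and median bound dwell length (frames, pooled over all bound
#' segments of all traces) and the fraction of trajectories with any
#' lasting unbinding event.
#'
#' @param traces list of [BindingTrace-class] (or one).
#' @return list with `meanBoundDwell`, `medianBoundDwell`,
#'   `unbindingFraction`, `nTraces`, `nBoundSegments`.
#' @export
dwellStatistics <- function(traces) {
  if (is(traces, "BindingTrace")) traces <- list(traces)
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  dwells <- unlist(lapply(traces, function(tr) {
    s <- tr@segments
    s$end[s$bound] - s$start[s$bound] + 1L
  }))
  unb <- vapply(traces, function(tr) !is.na(tr@firstUnbinding), logical(1))
  list(meanBoundDwell = if (length(dwells)) mean(dwells) else NA_real_,
       medianBoundDwell = if (length(dwells)) stats::median(dwells) else NA_real_,
       unbindingFraction = mean(unb),
       nTraces = length(traces), nBoundSegments = length(dwells))
}
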