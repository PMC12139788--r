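#' SASA parameters
#'
#' @param probeRadius probe radius in Angstrom; 1.4 approximates water, 3.0
#'   approximates the bulky thiosulfonate reagent used in accessibility
#'   assays.
#' @param nSpherePoints quadrature points per atom (>= 12; default 960).
#' @param includeHydrogens include H atoms in the calculation (default
#'   FALSE; excluded atoms get zero area and do not occlude).
#' @return list of class `SasaParameters`.
#' @export
sasaParameters <- function(probeRadius = 1.4, nSpherePoints = 960L,
                           includeHydrogens = FALSE) {
  if (probeRadius <= 0) stop("probeRadius must be positive", call. = FALSE)
  if (nSpherePoints < 12) stop("nSpherePoints must be >= 12", call. = FALSE)
  structure(list(probeRadius = probeRadius,
                 nSpherePoints = as.integer(nSpherePoints),
                 includeHydrogens = isTRUE(includeHydrogens)),
            class = "SasaParameters")
}

#' Deterministic near-uniform unit sphere points
#'
#' Golden-spiral lattice: a fixed, RNG-free point set so surface areas are
#' bit-reproducible. Identical output for identical `n`.
#'
#' @param n number of points (>= 12).
#' @return `n x 3` matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (n < 12) stop("need at least 12 sphere points", call. = FALSE)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Indices of atoms participating in the calculation under params.
.sasaAtoms <- function(topology, params) {
  a <- atoms(topology)
  if (params$includeHydrogens) seq_len(nrow(a))
  else which(toupper(a$element) != "H")
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' For each atom, the fraction of quadrature points on its expanded sphere
#' (radius `r_atom + probe`) not buried inside any neighbour's expanded
#' sphere, times the expanded sphere's area. Neighbour pruning at
#' `r_i + r_j + 2 probe` is exact: results are identical to the all-pairs
#' computation.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param topology the matching [Topology-class] (provides radii).
#' @param params a [sasaParameters()].
#' @return list with `perAtom` (numeric, length n; excluded atoms are 0)
#'   and `perResidue` (data.frame resid, resname, chain, area).
#' @examples
#' toy <- makeToyTransporter()
#' res <- sasa(toy$frame, toy$topology, sasaParameters(probeRadius = 3))
#' subset(res$perResidue, resid == 107)
#' @export
sasa <- function(frame, topology, params = sasaParameters()) {
  a <- atoms(topology)
  idx <- .sasaAtoms(topology, params)
  radii <- a$radius[idx] + params$probeRadius
  xyz <- frame[idx, , drop = FALSE]
  pts <- spherePoints(params$nSpherePoints)
  nA <- length(idx)
  area <- numeric(nrow(a))
  d2 <- as.matrix(stats::dist(xyz))^2
  for (ii in seq_len(nA)) {
    rexp_i <- radii[ii]
    nb <- which(d2[ii, ] < (rexp_i + radii)^2 & seq_len(nA) != ii)
    p <- pts * rexp_i
    p <- sweep(p, 2, xyz[ii, ], FUN = "+")
    exposed <- rep(TRUE, nrow(p))
    for (jj in nb) {
      if (!any(exposed)) break
      dx <- p[exposed, 1] - xyz[jj, 1]
      dy <- p[exposed, 2] - xyz[jj, 2]
      dz <- p[exposed, 3] - xyz[jj, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz >= radii[jj]^2
    }
    area[idx[ii]] <- mean(exposed) * 4 * pi * rexp_i^2
  }
  key <- paste(a$chain, a$resid)
  perRes <- stats::aggregate(area, list(key = key), sum)
  ord <- match(unique(key), perRes$key)
  firsts <- match(unique(key), key)
  perResidue <- data.frame(resid = a$resid[firsts],
                           resname = a$resname[firsts],
                           chain = a$chain[firsts],
                           area = perRes$x[ord])
  list(perAtom = area, perResidue = perResidue)
}

#' Random validation cluster for surface-area cross-checks
#'
#' Samples atoms uniformly in a cubic box under a minimum-separation
#' constraint (blue-noise-like), giving clusters with moderate sphere
#' overlap and no fully buried atoms — the regime in which comparing a
#' deterministic quadrature against a stochastic oracle is
#' well-conditioned. Elements are drawn from C/N/O/S.
#'
#' @param nAtomsCluster number of atoms (default 20).
#' @param seed integer seed.
#' @param box cube edge, Angstrom (default 20).
#' @param minSeparation minimum pairwise distance, Angstrom (default 7).
#' @return list with `frame` (`n x 3` matrix) and `topology`.
#' @export
makeValidationCluster <- function(nAtomsCluster = 20L, seed = 0L, box = 20,
                                  minSeparation = 7) {
  .withSeed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < nAtomsCluster) {
      tries <- tries + 1L
      if (tries > 1e5)
        stop("cannot place ", nAtomsCluster, " atoms at separation ",
             minSeparation, " in a ", box, " A box", call. = FALSE)
      cand <- stats::runif(3, 0, box)
      if (!nrow(pts) ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= minSeparation)
        pts <- rbind(pts, cand)
    }
    el <- sample(c("C", "N", "O", "S"), nAtomsCluster, replace = TRUE)
    top <- newTopology(data.frame(
      serial = seq_len(nAtomsCluster), name = paste0(el, seq_len(nAtomsCluster)),
      element = el, resname = "UNK", resid = seq_len(nAtomsCluster),
      chain = "A", stringsAsFactors = FALSE))
    list(frame = unname(pts), topology = top)
  })
}

#' Monte-Carlo rejection oracle for SASA
#'
#' Uniform random points on each atom's expanded sphere, accepted when
#' outside every neighbour's expanded sphere; area = acceptance fraction
#' times the expanded sphere area. An independent stochastic check on the
#' deterministic quadrature, with its binomial standard error.
#'
#' @param frame,topology,params as in [sasa()].
#' @param nSamples random samples per atom (default 1e5).
#' @param seed integer seed.
#' @return list with `perAtom` areas and `se` standard errors (both length
#'   n, zeros for excluded atoms).
#' @export
mcSasaOracle <- function(frame, topology, params = sasaParameters(),
                         nSamples = 1e5, seed = 0L) {
  a <- atoms(topology)
  idx <- .sasaAtoms(topology, params)
  radii <- a$radius[idx] + params$probeRadius
  xyz <- frame[idx, , drop = FALSE]
  nA <- length(idx)
  area <- se <- numeric(nrow(a))
  d2 <- as.matrix(stats::dist(xyz))^2
  .withSeed(seed, {
    for (ii in seq_len(nA)) {
      rexp_i <- radii[ii]
      v <- matrix(stats::rnorm(3 * nSamples), ncol = 3)
      v <- v / sqrt(rowSums(v^2)) * rexp_i
      p <- sweep(v, 2, xyz[ii, ], FUN = "+")
      nb <- which(d2[ii, ] < (rexp_i + radii)^2 & seq_len(nA) != ii)
      acc <- rep(TRUE, nSamples)
      for (jj in nb) {
        dx <- p[, 1] - xyz[jj, 1]; dy <- p[, 2] - xyz[jj, 2]
        dz <- p[, 3] - xyz[jj, 3]
        acc <- acc & (dx * dx + dy * dy + dz * dz >= radii[jj]^2)
      }
      f <- mean(acc)
      tot <- 4 * pi * rexp_i^2
      area[idx[ii]] <- f * tot
      se[idx[ii]] <- tot * sqrt(f * (1 - f) / nSamples)
    }
  })
  list(perAtom = area, se = se)
}

#' Residue accessibility over a trajectory ensemble
#'
#' Per-frame residue SASA (sum over the residue's atoms within the
#' whole-system calculation), averaged over frames per trajectory, then
#' ensemble mean and sample SD over the per-trajectory means — the
#' per-replica convention for reporting probe accessibility. Frame-level
#' SDs are also returned.
#'
#' @param trajectories list of [Trajectory-class] (or one).
#' @param resid residue number.
#' @param params a [sasaParameters()] (use `probeRadius = 3` for the
#'   reagent-mimetic probe).
#' @param sideChainOnly restrict attribution to side-chain atoms (exclude
#'   N, CA, C, O) (default FALSE: whole-residue).
#' @param chain optional chain id.
#' @return list with `perTrajectory` (data.frame label, mean, sd, nFrames),
#'   `mean`, `sd` (ensemble over trajectory means), `nTrajectories`.
#' @export
residueAccessibility <- function(trajectories, resid,
                                 params = sasaParameters(probeRadius = 3),
                                 sideChainOnly = FALSE, chain = NULL) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  top <- trajectories[[1]]@topology
  sel <- selectAtoms(top, resid = resid, chain = chain)
  if (sideChainOnly) {
    bb <- atoms(top)$name[sel] %in% c("N", "CA", "C", "O")
    sel <- sel[!bb]
    if (!length(sel)) stop("residue has no side-chain atoms", call. = FALSE)
  }
  perTraj <- lapply(trajectories, function(traj) {
    vals <- vapply(seq_len(nFrames(traj)), function(f)
      sum(sasa(frameCoords(traj, f), top, params)$perAtom[sel]), numeric(1))
    data.frame(label = traj@label, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               nFrames = length(vals))
  })
  perTraj <- do.call(rbind, perTraj)
  m <- mean(perTraj$mean)
  s <- if (nrow(perTraj) > 1) stats::sd(perTraj$mean) else 0
  list(perTrajectory = perTraj, mean = m, sd = s,
       nTrajectories = nrow(perTraj))
}
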