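#' Markov gate-ensemble specification
#'
#' Parameters for the Markov-switching gate-geometry generator. The hidden
#' state walks over the four gate categories; donor-acceptor distances are
#' emitted uniformly from `inRange` when a contact is on and from `outRange`
#' when it is off. The ranges must be separated by the 3.2 Angstrom
#' criterion, so noiseless emissions classify back to the generating label
#' exactly.
#'
#' The default transition matrix is a sticky chain, `P = 0.9 I + 0.1 1
#' pi'`, with stationary distribution `pi = (0.55, 0.12, 0.08, 0.25)` over
#' (GLN_ONLY, GLU_ONLY, BOTH, NEITHER). Its stationary salt-bridge
#' occupancy (GLU_ONLY + BOTH) is 0.20, emulating an outward-open-like
#' ensemble in which the gate salt bridge is formed about 20 percent of the
#' time.
#'
#' @param transitionMatrix 4 x 4 row-stochastic matrix over states
#'   (GLN_ONLY, GLU_ONLY, BOTH, NEITHER).
#' @param inRange length-2 numeric, Angstrom; uniform emission range for an
#'   "on" contact (default c(2.7, 3.1)).
#' @param outRange length-2 numeric, Angstrom; range for an "off" contact
#'   (default c(4.0, 8.0)).
#' @param jitterSigma Gaussian positional noise on the emitted donor atoms
#'   (Angstrom; default 0, i.e. noiseless).
#' @param nFrames frames per replica.
#' @param nTrajectories replicas; replica r uses `seed + r`.
#' @param seed base integer seed.
#' @return validated spec list of class `GateMarkovSpec`.
#' @export
gateMarkovSpec <- function(transitionMatrix = NULL, inRange = c(2.7, 3.1),
                           outRange = c(4.0, 8.0), jitterSigma = 0,
                           nFrames = 2000L, nTrajectories = 8L, seed = 0L) {
  if (is.null(transitionMatrix)) {
    pi0 <- c(0.55, 0.12, 0.08, 0.25)
    transitionMatrix <- 0.9 * diag(4) + 0.1 * matrix(pi0, 4, 4, byrow = TRUE)
  }
  P <- as.matrix(transitionMatrix)
  if (!identical(dim(P), c(4L, 4L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12))
    stop("transitionMatrix must be 4x4 row-stochastic (rows sum to 1 within 1e-12)",
         call. = FALSE)
  if (max(inRange) >= 3.2 || min(outRange) <= 3.2)
    stop("emission ranges must be separated by the 3.2 A criterion ",
         "(max(inRange) < 3.2 < min(outRange))", call. = FALSE)
  if (jitterSigma < 0) stop("jitterSigma must be >= 0", call. = FALSE)
  structure(list(P = P, inRange = inRange, outRange = outRange,
                 jitterSigma = jitterSigma, nFrames = as.integer(nFrames),
                 nTrajectories = as.integer(nTrajectories),
                 seed = as.integer(seed)),
            class = "GateMarkovSpec")
}

# Contact on/off pattern per gate state: columns (gln, glu)
.stateContacts <- matrix(c(TRUE, FALSE, TRUE, FALSE,   # gln contact
                           FALSE, TRUE, TRUE, FALSE),  # glu contact
                         ncol = 2,
                         dimnames = list(gateStateLevels, c("gln", "glu")))

#' Simulate Markov-switching gate ensembles with known labels
#'
#' The hidden state evolves by the spec's Markov chain, the initial state
#' drawn from its stationary distribution. Per frame, the NH1 donor
#' pseudo-atom is placed at the emitted distance from the glutamine acceptor
#' (Gln332 OE1) and NH2 at the emitted distance from the glutamate acceptor
#' (Glu493 OE1); acceptors are fixed, and the geometry guarantees the
#' cross-pair distances can never satisfy the criterion. Ground-truth labels
#' are returned alongside.
#'
#' @param spec a [gateMarkovSpec()].
#' @return list with `trajectories` (list of [Trajectory-class]), `labels`
#'   (list of character vectors, the true per-frame states), `topology`,
#'   `reference` frame, and `stationary` (the chain's stationary
#'   distribution, eigen-solved).
#' @export
simulateGateTrajectories <- function(spec) {
  stopifnot(inherits(spec, "GateMarkovSpec"))
  toy <- makeToyTransporter(spec$seed)
  top <- toy$topology
  base <- toy$frame
  iNH1 <- selectAtoms(top, resid = 104, names = "NH1")
  iNH2 <- selectAtoms(top, resid = 104, names = "NH2")
  aGln <- base[selectAtoms(top, resid = 332, names = "OE1"), ]
  aGlu <- base[selectAtoms(top, resid = 493, names = "OE1"), ]
  uGln <- c(-1, 0, 0)   # away from the glutamate side
  uGlu <- c(1, 0, 0)    # away from the glutamine side
  pi0 <- stationaryDistribution(spec$P)
  nf <- spec$nFrames
  trajs <- vector("list", spec$nTrajectories)
  labels <- vector("list", spec$nTrajectories)
  for (r in seq_len(spec$nTrajectories)) {
    res <- .withSeed(spec$seed + r, {
      st <- integer(nf)
      st[1] <- sample.int(4L, 1L, prob = pi0)
      if (nf > 1) for (f in 2:nf)
        st[f] <- sample.int(4L, 1L, prob = spec$P[st[f - 1], ])
      on <- .stateContacts[st, , drop = FALSE]
      dG <- ifelse(on[, "gln"],
                   stats::runif(nf, spec$inRange[1], spec$inRange[2]),
                   stats::runif(nf, spec$outRange[1], spec$outRange[2]))
      dE <- ifelse(on[, "glu"],
                   stats::runif(nf, spec$inRange[1], spec$inRange[2]),
                   stats::runif(nf, spec$outRange[1], spec$outRange[2]))
      jit <- if (spec$jitterSigma > 0)
        array(stats::rnorm(6 * nf, 0, spec$jitterSigma), c(3, 2, nf))
      else array(0, c(3, 2, nf))
      list(st = st, dG = dG, dE = dE, jit = jit)
    })
    coords <- array(base, c(nrow(base), 3L, nf))
    nh1 <- t(outer(res$dG, uGln) + rep(aGln, each = nf)) + res$jit[, 1, ]
    nh2 <- t(outer(res$dE, uGlu) + rep(aGlu, each = nf)) + res$jit[, 2, ]
    coords[iNH1, , ] <- nh1
    coords[iNH2, , ] <- nh2
    trajs[[r]] <- newTrajectory(top, coords, times = 4 * seq_len(nf),
                                label = sprintf("rep%02d", r))
    labels[[r]] <- gateStateLevels[res$st]
  }
  list(trajectories = trajs, labels = labels, topology = top,
       reference = base, stationary = stats::setNames(pi0, gateStateLevels))
}

#' Ion-dwell trajectory specification
#'
#' @param meanDwell mean dwell length in frames (continuous exponential,
#'   rounded up to whole frames); must be >= 1.
#' @param site site name (`"Na1"`, `"Na2"` or `"Cl"`) or an [ionSite()]
#'   definition.
#' @param nEvents number of bound dwell segments; 0 gives a single
#'   fully-bound trajectory.
#' @param unboundDisplacement Angstrom the ion is displaced from the site
#'   centre while unbound (default 10).
#' @param seed integer seed.
#' @return spec list of class `IonDwellSpec`.
#' @export
ionDwellSpec <- function(meanDwell = 50, site = "Cl", nEvents = 200L,
                         unboundDisplacement = 10, seed = 0L) {
  if (meanDwell < 1) stop("meanDwell must be >= 1 frame", call. = FALSE)
  structure(list(meanDwell = meanDwell, site = site,
                 nEvents = as.integer(nEvents),
                 unboundDisplacement = unboundDisplacement,
                 seed = as.integer(seed)),
            class = "IonDwellSpec")
}

#' Simulate an ion-binding trajectory with known dwell segments
#'
#' The ion alternates bound (at the toy system's site centre, satisfying the
#' site's coordination criterion) and unbound (displaced by
#' `unboundDisplacement` along a fixed direction), with dwell lengths drawn
#' as continuous exponentials of mean `meanDwell` rounded up to whole
#' frames. All other atoms are static.
#'
#' @param spec an [ionDwellSpec()].
#' @return list with `trajectory` ([Trajectory-class]), `segments` (true
#'   dwell table: start, end, bound) and `site` (the [ionSite()] used).
#' @export
simulateIonBinding <- function(spec) {
  stopifnot(inherits(spec, "IonDwellSpec"))
  site <- if (is.character(spec$site)) ionSitePreset(spec$site) else spec$site
  toy <- makeToyTransporter(spec$seed)
  center <- toy$siteCenters[[site$name]]
  if (is.null(center))
    stop("toy system has no site centre named '", site$name, "'", call. = FALSE)
  ionIdx <- selectAtoms(toy$topology, resname = site$ionResname)
  if (spec$nEvents == 0L) {
    lens <- 100L; bound <- TRUE
  } else {
    lens0 <- .withSeed(spec$seed,
                       ceiling(stats::rexp(2L * spec$nEvents, 1 / spec$meanDwell)))
    lens <- as.integer(lens0)
    bound <- rep(c(TRUE, FALSE), spec$nEvents)
  }
  nf <- sum(lens)
  ends <- cumsum(lens)
  segments <- data.frame(start = c(1L, utils::head(ends, -1L) + 1L),
                         end = as.integer(ends), bound = bound)
  u <- c(1, 1, 1) / sqrt(3)
  coords <- array(toy$frame, c(nrow(toy$frame), 3L, nf))
  flags <- rep(bound, lens)
  off <- outer(ifelse(flags, 0, spec$unboundDisplacement), u)
  coords[ionIdx, 1, ] <- center[1] + off[, 1]
  coords[ionIdx, 2, ] <- center[2] + off[, 2]
  coords[ionIdx, 3, ] <- center[3] + off[, 3]
  traj <- newTrajectory(toy$topology, coords, times = 4 * seq_len(nf),
                        label = sprintf("ion-%s", site$name))
  list(trajectory = traj, segments = segments, site = site)
}

#' Hydration-field specification
#'
#' @param density water-particle density, particles per cubic Angstrom
#'   (bulk water oxygen density is about 0.0334).
#' @param regionRadius Angstrom radius of the spherical region around the
#'   centre atom (default 20).
#' @param nFrames number of frames.
#' @param centerResid residue number of the centre selection (default 98).
#' @param seed integer seed.
#' @return spec list of class `HydrationSpec`.
#' @export
hydrationSpec <- function(density = 0.0334, regionRadius = 20,
                          nFrames = 100L, centerResid = 98L, seed = 0L) {
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  structure(list(density = density, regionRadius = regionRadius,
                 nFrames = as.integer(nFrames),
                 centerResid = as.integer(centerResid),
                 seed = as.integer(seed)),
            class = "HydrationSpec")
}

#' Simulate water pseudo-atoms by a Poisson point process
#'
#' Per frame, water-oxygen pseudo-atoms are placed by a homogeneous Poisson
#' point process of the specified density inside `regionRadius` of the
#' centre-selection centroid, and appended to the topology as residue HOH.
#' The topology carries the maximum per-frame water count; waters beyond a
#' frame's own count are parked far outside the region so they never enter
#' any analysis grid.
#'
#' @param spec a [hydrationSpec()].
#' @param topology a [Topology-class] (default: the toy transporter's).
#' @param reference `n x 3` reference frame matching `topology`.
#' @return a [Trajectory-class] whose topology includes the HOH atoms.
#' @export
simulateHydration <- function(spec, topology = NULL, reference = NULL) {
  stopifnot(inherits(spec, "HydrationSpec"))
  if (is.null(topology)) {
    toy <- makeToyTransporter(spec$seed)
    topology <- toy$topology; reference <- toy$frame
  }
  centerIdx <- selectAtoms(topology, resid = spec$centerResid)
  center <- colMeans(reference[centerIdx, , drop = FALSE])
  vol <- 4 / 3 * pi * spec$regionRadius^3
  sim <- .withSeed(spec$seed, {
    counts <- stats::rpois(spec$nFrames, spec$density * vol)
    pos <- lapply(counts, function(k) {
      if (k == 0) return(matrix(numeric(0), 0, 3))
      r <- spec$regionRadius * stats::runif(k)^(1 / 3)
      v <- matrix(stats::rnorm(3 * k), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      sweep(v * r, 2, center, FUN = "+")
    })
    list(counts = counts, pos = pos)
  })
  nmax <- max(sim$counts, 0L)
  a <- atoms(topology)
  if (nmax > 0) {
    wat <- data.frame(serial = max(a$serial) + seq_len(nmax), name = "O",
                      element = "O", resname = "HOH",
                      resid = 5000L + seq_len(nmax), chain = "W",
                      stringsAsFactors = FALSE)
    topW <- newTopology(rbind(a[, c("serial", "name", "element", "resname",
                                    "resid", "chain")], wat))
  } else topW <- topology
  park <- center + 10 * spec$regionRadius + 100
  nat <- nAtoms(topW)
  coords <- array(0, c(nat, 3L, spec$nFrames))
  nprot <- nAtoms(topology)
  for (f in seq_len(spec$nFrames)) {
    fr <- matrix(rep(park, each = nat), ncol = 3)
    fr[seq_len(nprot), ] <- reference
    k <- sim$counts[f]
    if (k > 0) fr[nprot + seq_len(k), ] <- sim$pos[[f]]
    coords[, , f] <- fr
  }
  newTrajectory(topW, coords, times = 4 * seq_len(spec$nFrames),
                label = "hydration")
}

#' Inactivation-assay specification
#'
#' @param kTrue true second-order modification rate constant (M^-1 min^-1).
#' @param exposureTime reagent exposure time (min).
#' @param concentrations reagent concentrations (M); must include 0 (the
#'   untreated control) and be non-negative. The default emulates a 96-well
#'   plate design: triplicate untreated control wells plus six
#'   concentrations bracketing the half-maximal inactivation concentration
#'   (about 0.7 mM at the default `kTrue` and `exposureTime`).
#' @param cv multiplicative (lognormal) noise coefficient of variation.
#' @param nReplicates replicates per concentration.
#' @param seed integer seed.
#' @return spec list of class `AssaySpec`.
#' @export
assaySpec <- function(kTrue = 500, exposureTime = 2,
                      concentrations = c(0, 0, 0, 1e-4, 2.5e-4, 5e-4,
                                         1e-3, 2e-3, 4e-3),
                      cv = 0.05, nReplicates = 3L, seed = 0L) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (!any(concentrations == 0))
    stop("concentrations must include 0 (untreated control)", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (exposureTime <= 0) stop("exposureTime must be > 0", call. = FALSE)
  structure(list(kTrue = kTrue, exposureTime = exposureTime,
                 concentrations = concentrations, cv = cv,
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)),
            class = "AssaySpec")
}

#' Simulate a reagent-inactivation assay
#'
#' Fractional activity A(c) = exp(-k c t) times mean-one lognormal noise of
#' coefficient of variation `cv`, replicated `nReplicates` times per
#' concentration (untreated control included). Bit-reproducible for a fixed
#' seed.
#'
#' @param spec an [assaySpec()].
#' @return data.frame with columns `concentration_M`, `activity`,
#'   `replicate`, carrying the exposure time (min) as attribute
#'   `exposureTime`.
#' @export
simulateInactivationAssay <- function(spec) {
  stopifnot(inherits(spec, "AssaySpec"))
  conc <- rep(spec$concentrations, times = spec$nReplicates)
  repl <- rep(seq_len(spec$nReplicates), each = length(spec$concentrations))
  mu <- exp(-spec$kTrue * conc * spec$exposureTime)
  noise <- if (spec$cv > 0) .withSeed(spec$seed, {
    sdl <- sqrt(log(1 + spec$cv^2))
    stats::rlnorm(length(conc), meanlog = -sdl^2 / 2, sdlog = sdl)
  }) else rep(1, length(conc))
  out <- data.frame(concentration_M = conc, activity = mu * noise,
                    replicate = repl)
  attr(out, "exposureTime") <- spec$exposureTime
  attr(out, "kTrue") <- spec$kTrue
  out
}

#' Materialise synthetic gate fixtures on disk
#'
#' Writes the topology as PDB, each replica as DCD, and the ground-truth
#' per-frame state labels as CSV, so external tools can consume the same
#' ensemble the in-memory generator produces.
#'
#' @param spec a [gateMarkovSpec()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
materializeSynthetic <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateGateTrajectories(spec)
  files <- file.path(outdir, "topology.pdb")
  writeStructure(sim$topology, sim$reference, files)
  for (r in seq_along(sim$trajectories)) {
    f <- file.path(outdir, sprintf("replica%02d.dcd", r))
    writeDCD(sim$trajectories[[r]], f)
    files <- c(files, f)
  }
  lab <- data.frame(replica = rep(seq_along(sim$labels),
                                  each = spec$nFrames),
                    frame = rep(seq_len(spec$nFrames),
                                times = length(sim$labels)),
                    state = unlist(sim$labels))
  labFile <- file.path(outdir, "true_states.csv")
  utils::write.csv(lab, labFile, row.names = FALSE)
  invisible(c(files, labFile))
}
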