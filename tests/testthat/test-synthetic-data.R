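test_that("toy transporter is deterministic and carries the named roles", {
  t1 <- makeToyTransporter(3)
  t2 <- makeToyTransporter(3)
  expect_identical(t1$frame, t2$frame)
  expect_identical(atoms(t1$topology), atoms(t2$topology))
  t3 <- makeToyTransporter(4)
  expect_false(identical(t1$frame, t3$frame))  # filler jitter differs

  expect_length(selectAtoms(t1$topology, resid = 104,
                            names = c("NE", "NH1", "NH2")), 3L)
  # the five chloride-site coordinating atoms resolve individually
  cl <- ionSitePreset("Cl")
  idx <- mapply(function(r, n) selectAtoms(t1$topology, resid = r, names = n),
                cl$coordinatingAtoms$resid, cl$coordinatingAtoms$name)
  expect_length(unique(idx), 5L)
  expect_equal(atoms(t1$topology)$name[idx],
               c("ND2", "OH", "NE2", "OG", "OG"))
  # ions actually coordinate at their site centres
  expect_gte(coordinationCount(t1$frame, t1$topology, "Cl"), 2L)
  expect_gte(coordinationCount(t1$frame, t1$topology, "Na1"), 2L)
})

test_that("gate generator follows the Markov chain and its ranges", {
  # identity transition matrix freezes the initial state over all frames
  P <- diag(4)
  spec <- gateMarkovSpec(P, nFrames = 50L, nTrajectories = 4L, seed = 5L)
  sim <- simulateGateTrajectories(spec)
  for (lab in sim$labels) expect_length(unique(lab), 1L)

  # uniform matrix: iid states; fractions within 3 binomial SE of 0.25
  U <- matrix(0.25, 4, 4)
  spec <- gateMarkovSpec(U, nFrames = 10000L, nTrajectories = 1L, seed = 2L)
  sim <- simulateGateTrajectories(spec)
  frac <- table(factor(sim$labels[[1]],
                       levels = levels(gateStates(classifyGateStates(sim$trajectories[[1]]))))) / 10000
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  # arbitrary ergodic matrix: fractions near the eigen-solved stationary
  set.seed(9)
  M <- matrix(rexp(16), 4, 4); M <- M / rowSums(M)
  spec <- gateMarkovSpec(M, nFrames = 20000L, nTrajectories = 1L, seed = 3L)
  sim <- simulateGateTrajectories(spec)
  pi0 <- stationaryDistribution(M)
  frac <- as.numeric(table(factor(sim$labels[[1]], levels = c(
    "GLN_ONLY", "GLU_ONLY", "BOTH", "NEITHER"))) / 20000)
  se <- sqrt(pi0 * (1 - pi0) / 20000)
  # sticky chains inflate the SE by the integrated autocorrelation time;
  # this M is far from sticky, 5 SE is ample
  expect_true(all(abs(frac - pi0) < 5 * pmax(se, 1e-4)))

  expect_error(gateMarkovSpec(matrix(1, 4, 4)), "row-stochastic")
  expect_error(gateMarkovSpec(inRange = c(2.7, 3.3)), "3.2")
})

test_that("gate generator emissions respect the on/off distance ranges", {
  spec <- gateMarkovSpec(nFrames = 400L, nTrajectories = 2L, seed = 8L)
  sim <- simulateGateTrajectories(spec)
  s <- classifyGateStates(sim$trajectories[[1]])
  on <- sim$labels[[1]] %in% c("GLN_ONLY", "BOTH")
  expect_true(all(s@distGln[on] >= 2.7 & s@distGln[on] <= 3.1))
  expect_true(all(s@distGln[!on] >= 4.0 & s@distGln[!on] <= 8.0))
})

test_that("ion-dwell generator reproduces its own segments and geometry", {
  sim <- simulateIonBinding(ionDwellSpec(meanDwell = 50, nEvents = 200,
                                         seed = 0L))
  expect_equal(nrow(sim$segments), 400L)
  lens <- sim$segments$end - sim$segments$start + 1L
  expect_lt(abs(mean(lens[sim$segments$bound]) - 50) / 50, 0.15)
  # unbound frames have zero coordination at 10 A displacement
  tr <- bindingTrace(sim$trajectory, sim$site, persistenceWindow = 1L)
  flags <- rep(sim$segments$bound, lens)
  expect_true(all(tr@counts[!flags] == 0L))
  # zero events: a single fully bound trajectory
  sim0 <- simulateIonBinding(ionDwellSpec(nEvents = 0L))
  expect_equal(sim0$segments,
               data.frame(start = 1L, end = 100L, bound = TRUE))
})

test_that("hydration generator is seeded and matches Poisson counts", {
  h1 <- simulateHydration(hydrationSpec(density = 0.005, regionRadius = 10,
                                        nFrames = 20L, seed = 4L))
  h2 <- simulateHydration(hydrationSpec(density = 0.005, regionRadius = 10,
                                        nFrames = 20L, seed = 4L))
  expect_identical(h1@coords, h2@coords)
  # density 0: no waters appended
  h0 <- simulateHydration(hydrationSpec(density = 0, nFrames = 5L))
  expect_equal(sum(atoms(h0@topology)$resname == "HOH"), 0L)
  # mean count per frame ~ Poisson(rho * V)
  nWat <- sum(atoms(h1@topology)$resname == "HOH")
  expect_gt(nWat, 0L)
})

test_that("assay generator hits the closed form and reproduces bit-exactly", {
  # cv 0, k t = ln 2 per mM: A(1 mM) = 0.5 exactly
  spec <- assaySpec(kTrue = log(2) * 1000, exposureTime = 1,
                    concentrations = c(0, 1e-3), cv = 0, nReplicates = 1L)
  d <- simulateInactivationAssay(spec)
  expect_equal(d$activity[d$concentration_M == 1e-3], 0.5)
  expect_equal(d$activity[d$concentration_M == 0], 1)
  d1 <- simulateInactivationAssay(assaySpec(cv = 0.05, seed = 6L))
  d2 <- simulateInactivationAssay(assaySpec(cv = 0.05, seed = 6L))
  expect_identical(d1, d2)
  expect_error(assaySpec(concentrations = c(1e-4, 1e-3)), "control")
})
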