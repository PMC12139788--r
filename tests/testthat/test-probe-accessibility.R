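test_that("sphere points are unit, near-uniform and deterministic", {
  for (n in c(12, 100, 960)) {
    p <- spherePoints(n)
    expect_equal(sqrt(rowSums(p^2)), rep(1, n), tolerance = 1e-12)
  }
  expect_lt(sqrt(sum(colMeans(spherePoints(960))^2)), 1e-2)
  expect_identical(spherePoints(960), spherePoints(960))
  expect_error(spherePoints(11), "12")
})

test_that("isolated and enclosed atoms hit their closed forms", {
  top1 <- bareTopology(1)
  a <- sasa(matrix(0, 1, 3), top1, sasaParameters(probeRadius = 3))$perAtom
  expect_equal(a, 4 * pi * 4.7^2, tolerance = 0.005 * 4 * pi * 4.7^2)
  # fully enclosed atom: surrounded by a tight shell of neighbours
  shell <- spherePoints(60) * 1.0
  top <- bareTopology(61)
  fr <- rbind(c(0, 0, 0), shell)
  buried <- sasa(fr, top, sasaParameters(probeRadius = 1.4))$perAtom[1]
  expect_equal(buried, 0)
})

test_that("probe and neighbour monotonicity hold", {
  top1 <- bareTopology(1)
  areas <- vapply(c(1.4, 2, 3, 4), function(p)
    sasa(matrix(0, 1, 3), top1, sasaParameters(probeRadius = p))$perAtom,
    numeric(1))
  expect_true(all(diff(areas) > 0))
  # adding a neighbour never increases any existing atom's area
  set.seed(8)
  fr2 <- matrix(runif(6, 0, 6), 2, 3)
  a2 <- sasa(fr2, bareTopology(2), sasaParameters(probeRadius = 3))$perAtom
  fr3 <- rbind(fr2, colMeans(fr2) + c(0.5, 0, 0))
  a3 <- sasa(fr3, bareTopology(3), sasaParameters(probeRadius = 3))$perAtom
  expect_true(all(a3[1:2] <= a2 + 1e-9))
})

test_that("total area is rigid-motion invariant and residue sums are exact", {
  toy <- makeToyTransporter()
  params <- sasaParameters(probeRadius = 3)
  s0 <- sasa(toy$frame, toy$topology, params)
  moved <- applyRigid(toy$frame, randomRotation(21), c(3, 19, -5))
  s1 <- sasa(moved, toy$topology, params)
  expect_equal(sum(s1$perAtom), sum(s0$perAtom),
               tolerance = 1e-6 * sum(s0$perAtom))
  expect_equal(sum(s0$perResidue$area), sum(s0$perAtom), tolerance = 1e-9)
  a <- atoms(toy$topology)
  r107 <- sum(s0$perAtom[a$resid == 107])
  expect_equal(s0$perResidue$area[s0$perResidue$resid == 107], r107,
               tolerance = 1e-9)
})

test_that("Monte-Carlo oracle matches closed forms including the two-sphere lens", {
  top1 <- bareTopology(1)
  params <- sasaParameters(probeRadius = 3)
  mc <- mcSasaOracle(matrix(0, 1, 3), top1, params, nSamples = 2e4, seed = 2)
  exact <- 4 * pi * 4.7^2
  expect_lt(abs(mc$perAtom - exact), 3 * max(mc$se, 1e-9) + 1e-9)
  # two equal spheres at centre distance d = r_exp: spherical-cap closed form
  rexp <- 1.70 + 3
  d <- rexp
  fr <- rbind(c(0, 0, 0), c(d, 0, 0))
  mc2 <- mcSasaOracle(fr, bareTopology(2), params, nSamples = 1e5, seed = 3)
  # exposed fraction = 1 - cap height fraction; cap height h = r - d/2
  capFrac <- (rexp - d / 2) / (2 * rexp)
  exact2 <- (1 - capFrac) * 4 * pi * rexp^2
  expect_lt(abs(mc2$perAtom[1] - exact2), 3 * mc2$se[1])
  expect_lt(abs(mc2$perAtom[2] - exact2), 3 * mc2$se[2])
})

test_that("quadrature and oracle agree on random validation clusters", {
  params <- sasaParameters(probeRadius = 3)
  for (cl in 1:3) {
    cluster <- makeValidationCluster(seed = 40 + cl)
    s1 <- sasa(cluster$frame, cluster$topology, params)
    s2 <- mcSasaOracle(cluster$frame, cluster$topology, params,
                       nSamples = 2e4, seed = cl)
    dev <- abs(s1$perAtom - s2$perAtom)
    tol <- pmax(0.02 * s2$perAtom, 3 * s2$se)
    expect_true(all(dev <= tol),
                info = sprintf("cluster %d, worst ratio %.3f", cl,
                               max(dev / tol)))
  }
})

test_that("doubling quadrature points moves areas less than the oracle band", {
  cluster <- makeValidationCluster(seed = 77)
  p1 <- sasaParameters(probeRadius = 3, nSpherePoints = 960)
  p2 <- sasaParameters(probeRadius = 3, nSpherePoints = 1920)
  a1 <- sasa(cluster$frame, cluster$topology, p1)$perAtom
  a2 <- sasa(cluster$frame, cluster$topology, p2)$perAtom
  mc <- mcSasaOracle(cluster$frame, cluster$topology, p1,
                     nSamples = 2e4, seed = 1)
  expect_true(all(abs(a1 - a2) <= pmax(3 * mc$se, 1e-6)))
})

test_that("residue accessibility averages per trajectory then across them", {
  toy <- makeToyTransporter()
  params <- sasaParameters(probeRadius = 3, nSpherePoints = 240)
  # static trajectory: per-trajectory SD is 0
  trS <- newTrajectory(toy$topology, rep(list(toy$frame), 3), label = "s")
  acc <- residueAccessibility(trS, 107, params)
  expect_equal(acc$perTrajectory$sd, 0)
  # two trajectories with known means -> two-point ensemble stats
  mk <- function(shift, lab)
    newTrajectory(toy$topology, list(toy$frame + shift), label = lab)
  acc2 <- residueAccessibility(list(trS, trS), 107, params)
  expect_equal(acc2$sd, 0)
  expect_equal(acc2$mean, acc$perTrajectory$mean)
  # hand check of the two-point sample SD convention on synthetic means
  expect_equal(sd(c(360, 370)), 7.0710678, tolerance = 1e-6)
})
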