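test_that("region grids have the requested shape, centre and sphere flags", {
  toy <- makeToyTransporter()
  g <- buildRegionGrid(toy$topology, toy$frame, centerResid = 98,
                       radius = 20, spacing = 1)
  expect_equal(g@counts, rep(40L, 3))
  g2 <- buildRegionGrid(toy$topology, toy$frame, centerResid = 98,
                        radius = 2, spacing = 1)
  expect_equal(g2@counts, rep(4L, 3))
  expect_error(buildRegionGrid(toy$topology, toy$frame, centerResid = 98,
                               radius = 2, spacing = 0), "positive")
  # grid centre equals the selection centroid
  centre <- colMeans(toy$frame[selectAtoms(toy$topology, resid = 98), ])
  expect_equal(g@origin + g@counts * g@spacing / 2, centre, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(any(g@inSphere) && !all(g@inSphere))
})

test_that("static and intermittent atoms give exact voxel fractions", {
  toy <- makeToyTransporter()
  # a single HOH atom parked at a known position
  a <- atoms(toy$topology)
  wat <- data.frame(serial = max(a$serial) + 1L, name = "O", element = "O",
                    resname = "HOH", resid = 9000L, chain = "W")
  top <- newTopology(rbind(a[, names(wat)], wat))
  centre <- colMeans(toy$frame[selectAtoms(toy$topology, resid = 98), ])
  inside <- centre + c(0.2, 0.2, 0.2)
  outside <- centre + c(500, 500, 500)
  mkFrame <- function(watPos) rbind(toy$frame, watPos)
  ref <- mkFrame(inside)
  grid <- buildRegionGrid(top, ref, centerResid = 98, radius = 5, spacing = 1)

  # static for 100 frames: its voxel is 1.0, all others 0
  tr <- newTrajectory(top, rep(list(ref), 100))
  m <- occupancyMap(tr, grid, ref)
  expect_equal(sum(gridValues(m) == 1), 1L)
  expect_equal(sum(gridValues(m)), 1)
  expect_equal(m@nFramesTotal, 100L)

  # inside for 3 of 4 frames: 0.75
  tr2 <- newTrajectory(top, c(rep(list(ref), 3), list(mkFrame(outside))))
  m2 <- occupancyMap(tr2, grid, ref)
  expect_equal(max(gridValues(m2)), 0.75)
})

test_that("uniform Poisson water matches the void-probability closed form", {
  rho <- 0.008
  h <- simulateHydration(hydrationSpec(density = rho, regionRadius = 8,
                                       nFrames = 400L, seed = 7L))
  ref <- frameCoords(h, 1)
  grid <- buildRegionGrid(h@topology, ref, centerResid = 98,
                          radius = 8, spacing = 1)
  m <- occupancyMap(h, grid, ref)
  expect_true(all(gridValues(m) >= 0 & gridValues(m) <= 1))
  centre <- colMeans(ref[selectAtoms(h@topology, resid = 98), ])
  n <- m@counts[1]
  ax <- m@origin[1] + (seq_len(n) - 0.5) * m@spacing
  ay <- m@origin[2] + (seq_len(n) - 0.5) * m@spacing
  az <- m@origin[3] + (seq_len(n) - 0.5) * m@spacing
  d <- sqrt(outer(outer((ax - centre[1])^2, (ay - centre[2])^2, `+`),
                  (az - centre[3])^2, `+`))
  interior <- d <= 8 - sqrt(3)  # voxels fully inside the sphere
  expected <- 1 - exp(-rho * m@spacing^3)
  obs <- mean(gridValues(m)[interior])
  se <- sd(gridValues(m)[interior]) / sqrt(sum(interior))
  expect_lt(abs(obs - expected), 3 * max(se, 1e-5))
})

test_that("maps are invariant under a rigid motion applied to every frame", {
  h <- simulateHydration(hydrationSpec(density = 0.01, regionRadius = 6,
                                       nFrames = 50L, seed = 9L))
  ref <- frameCoords(h, 1)
  grid <- buildRegionGrid(h@topology, ref, centerResid = 98,
                          radius = 6, spacing = 1)
  m0 <- occupancyMap(h, grid, ref)
  R <- randomRotation(11)
  moved <- h@coords
  for (f in seq_len(nFrames(h)))
    moved[, , f] <- applyRigid(moved[, , f], R, c(25, -12, 3))
  hM <- newTrajectory(h@topology, moved, label = h@label)
  mM <- occupancyMap(hM, grid, ref)
  expect_equal(gridValues(mM), gridValues(m0), tolerance = 1e-9)
})

test_that("an empty species selection yields an identically zero map", {
  toy <- makeToyTransporter()
  tr <- newTrajectory(toy$topology, list(toy$frame, toy$frame))
  grid <- buildRegionGrid(toy$topology, toy$frame, centerResid = 98,
                          radius = 5, spacing = 1)
  expect_warning(m <- occupancyMap(tr, grid, toy$frame), "0 atoms")
  expect_true(all(gridValues(m) == 0))
})

test_that("doubling frames of a stationary input moves voxel means only
           within Monte-Carlo error", {
  rho <- 0.01
  h1 <- simulateHydration(hydrationSpec(density = rho, regionRadius = 6,
                                        nFrames = 200L, seed = 13L))
  h2 <- simulateHydration(hydrationSpec(density = rho, regionRadius = 6,
                                        nFrames = 400L, seed = 14L))
  ref <- frameCoords(h1, 1)
  g1 <- buildRegionGrid(h1@topology, ref, centerResid = 98, radius = 6,
                        spacing = 1)
  m1 <- occupancyMap(h1, g1, ref)
  g2 <- buildRegionGrid(h2@topology, frameCoords(h2, 1), centerResid = 98,
                        radius = 6, spacing = 1)
  m2 <- occupancyMap(h2, g2, frameCoords(h2, 1))
  p <- 1 - exp(-rho)
  seDiff <- sqrt(p * (1 - p) / 200 + p * (1 - p) / 400)
  expect_lt(abs(mean(gridValues(m1)[m1@inSphere]) -
                  mean(gridValues(m2)[m2@inSphere])), 4 * seDiff)
})
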