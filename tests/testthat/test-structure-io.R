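test_that("PDB reading keeps file order, coordinates and altloc rules", {
  f <- twoAtomPDB(tempfile(fileext = ".pdb"))
  st <- readStructure(f)
  expect_equal(nAtoms(st$topology), 2L)
  expect_equal(st$frame, cbind(c(0, 1.5), c(0, 0), c(0, 0)),
               ignore_attr = TRUE)
  expect_equal(atoms(st$topology)$name, c("N", "CA"))

  fa <- altlocPDB(tempfile(fileext = ".pdb"))
  sa <- readStructure(fa)
  expect_equal(nAtoms(sa$topology), 2L)       # one altloc kept
  expect_equal(sa$frame[1, ], c(0, 0, 0))     # A's coordinates (occ 0.6)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readStructure(empty), "parse error")
})

test_that("altloc occupancy ties break toward label A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  BALA A   1       9.000   9.000   9.000  0.50  0.00           N",
    "ATOM      2  N  AALA A   1       0.000   0.000   0.000  0.50  0.00           N",
    "END"), f)
  st <- readStructure(f)
  expect_equal(nAtoms(st$topology), 1L)
  expect_equal(st$frame[1, ], c(0, 0, 0))
})

test_that("vdW radii come from the embedded table with a default fallback", {
  expect_equal(vdwRadius(c("C", "N", "O", "S", "H", "P")),
               c(1.70, 1.55, 1.52, 1.80, 1.20, 1.80))
  expect_equal(vdwRadius("ZZ"), 1.70)
  toy <- makeToyTransporter()
  expect_true(all(atoms(toy$topology)$radius > 0))
})

test_that("trajectory reading round-trips DCD and multi-model PDB", {
  toy <- makeToyTransporter()
  tr <- newTrajectory(toy$topology,
                      list(toy$frame, toy$frame + 0.25, toy$frame * 1.05))
  fd <- tempfile(fileext = ".dcd")
  writeDCD(tr, fd)
  rt <- suppressMessages(readTrajectory(fd, toy$topology))
  expect_equal(nFrames(rt), 3L)
  expect_lt(max(abs(rt@coords - tr@coords)), 1e-4)

  fp <- tempfile(fileext = ".pdb")
  writeStructure(toy$topology, tr, fp)
  rp <- suppressMessages(readTrajectory(fp, toy$topology))
  expect_equal(nFrames(rp), 3L)
  expect_lt(max(abs(rp@coords - tr@coords)), 1e-3)  # %8.3f quantization

  # atom-count mismatch is a structural error naming both counts
  small <- bareTopology(2)
  expect_error(suppressMessages(readTrajectory(fd, small)), "2")
})

test_that("selection is deterministic, order-stable and errors when empty", {
  toy <- makeToyTransporter()
  s <- selectAtoms(toy$topology, resid = 104, names = c("NE", "NH1", "NH2"))
  expect_length(s, 3L)
  expect_equal(atoms(toy$topology)$name[s], c("NE", "NH1", "NH2"))
  expect_identical(s, selectAtoms(toy$topology, resid = 104,
                                  names = c("NE", "NH1", "NH2")))
  all107 <- selectAtoms(toy$topology, resid = 107)
  expect_equal(sort(atoms(toy$topology)$name[all107]),
               sort(c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                      "CE1", "CE2", "CZ", "OH")))
  expect_identical(all107, selectAtoms(toy$topology, resid = 107, names = "*"))
  expect_false(is.unsorted(all107))
  expect_error(selectAtoms(toy$topology, resid = 9999), "empty selection")
})

test_that("superposition recovers rigid motions and reports selection RMSD", {
  toy <- makeToyTransporter()
  for (seed in 1:5) {
    R <- randomRotation(seed)
    moved <- applyRigid(toy$frame, R, c(7, -4, 2.5) * seed)
    sp <- superpose(moved, toy$frame)
    expect_lt(sp$rmsd, 1e-6)
    expect_lt(max(abs(sp$coords - toy$frame)), 1e-6)
  }
  # identity case
  sp0 <- superpose(toy$frame, toy$frame)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  # degenerate selections
  expect_error(superpose(toy$frame, toy$frame, selection = 1:2),
               "degenerate")
  lin <- cbind(1:5, 0, 0)
  expect_error(superpose(lin, lin), "collinear")
})

test_that("superposition of noisy clouds beats a brute-force rotation grid", {
  set.seed(42)
  ref <- matrix(runif(12, -3, 3), 4, 3)
  mob <- applyRigid(ref, randomRotation(7), c(1, 2, 3)) +
    matrix(rnorm(12, 0, 0.2), 4, 3)
  fitted <- superpose(mob, ref)$rmsd
  # grid-search oracle over 10-degree-step Euler angles, centroids aligned
  best <- Inf
  mobc <- sweep(mob, 2, colMeans(mob))
  refc <- sweep(ref, 2, colMeans(ref))
  ang <- seq(0, 350, by = 10) * pi / 180
  for (a in ang) for (b in seq(0, 170, by = 10) * pi / 180) for (g in ang) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    rot <- mobc %*% t(Rz2 %*% Ry %*% Rz1)
    best <- min(best, sqrt(mean(rowSums((rot - refc)^2))))
  }
  expect_lte(fitted, best + 1e-12)
})

test_that("superposition agrees with the bio3d reference implementation", {
  toy <- makeToyTransporter()
  set.seed(3)
  mob <- applyRigid(toy$frame, randomRotation(9), c(4, 4, -6)) +
    matrix(rnorm(length(toy$frame), 0, 0.3), ncol = 3)
  ours <- superpose(mob, toy$frame)
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(toy$frame)),
                                         mobile = as.vector(t(mob))))
  theirs <- matrix(ref, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(ours$coords - theirs)), 1e-6)
})

test_that("DX grid files round-trip values and header metadata", {
  vals <- array(seq(0, 1, length.out = 8), c(2L, 2L, 2L))
  g <- new("OccupancyGrid", origin = c(-10, -10, -10), spacing = 1.0,
           counts = c(2L, 2L, 2L), values = vals,
           inSphere = array(TRUE, c(2, 2, 2)), nFramesTotal = 4L)
  f <- tempfile(fileext = ".dx")
  writeGridDX(g, f)
  g2 <- readGridDX(f)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-6)
  expect_equal(g2@origin, c(-10, -10, -10))
  expect_equal(g2@spacing, 1.0)
  txt <- readLines(f)
  expect_true(any(grepl("^origin -10 -10 -10$", txt)))
  expect_true(any(grepl("^delta 1 0 0$", txt)))
  empty <- new("OccupancyGrid", origin = c(0, 0, 0), spacing = 1,
               counts = c(1L, 1L, 1L), values = array(0, c(1, 1, 1)),
               inSphere = array(TRUE, c(1, 1, 1)), nFramesTotal = 0L)
  empty@counts <- c(0L, 1L, 1L)  # force an empty grid past the constructor
  expect_error(writeGridDX(empty, tempfile()), "empty")
})
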