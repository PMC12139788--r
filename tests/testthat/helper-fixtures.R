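# Shared fixtures and small geometry helpers built in code.

# A random proper rotation matrix (via QR of a Gaussian matrix).
randomRotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

applyRigid <- function(xyz, R, shift) sweep(xyz %*% t(R), 2, shift, FUN = "+")

# Rotate point p about the axis a0 -> a1 by deg degrees (right-handed).
rotateAbout <- function(p, a0, a1, deg) {
  u <- (a1 - a0) / sqrt(sum((a1 - a0)^2))
  th <- deg * pi / 180
  v <- p - a0
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  v * cos(th) + cr * sin(th) + u * sum(u * v) * (1 - cos(th)) + a0
}

# Two-atom PDB fixture text (coordinates (0,0,0) and (1.5,0,0)).
twoAtomPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# Altloc fixture: one atom with altlocs A (occ 0.6) and B (occ 0.4), plus a
# normal atom.
altlocPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.40  0.00           N",
    "ATOM      3  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# Minimal single-residue topology for geometric tests.
bareTopology <- function(n, element = "C") {
  newTopology(data.frame(
    serial = seq_len(n), name = paste0(element, seq_len(n)),
    element = element, resname = "UNK", resid = seq_len(n), chain = "A",
    stringsAsFactors = FALSE))
}
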