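# Internal-coordinate atom placement: position D given A-B-C, the C-D bond
# length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
.placeAtom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Deterministic miniature transporter system
#'
#' Builds a toy topology and reference frame carrying the residues and atom
#' names that the analyses address by role: the gate arginine (ARG 104 with
#' NE/NH1/NH2), the chloride-sensing glutamine (GLN 332 with OE1/NE2 and the
#' chi2 quadruple), the acidic gate partner (GLU 493 with OE1/OE2), the
#' sodium-coordinating aspartate (ASP 98 with its chi1 quadruple, CG placed
#' at a +60 degree chi1 by construction), the extracellular-pathway tyrosine
#' (TYR 107, full side chain), the Na1, Na2 and Cl- coordinating-atom sets
#' (Ala96 O, Asn101 OD1, Ser336 O/OG, Asn368 OD1; Gly94 O, Val97 O, Leu434
#' O, Ser438 OG; Asn101 ND2, Tyr121 OH, Gln332 NE2, Ser336 OG, Ser372 OG), a
#' Na+ and a Cl- ion at their site centres, and filler scaffold CA atoms.
#' Geometry is schematic, not a real transporter fold: the glutamine and
#' glutamate acceptors sit 20 Angstrom apart so that donor emissions near one
#' can never satisfy the criterion at the other.
#'
#' @param seed integer; perturbs only the filler scaffold positions (0.1
#'   Angstrom deterministic jitter). Same seed, same coordinates.
#' @return list with `topology` ([Topology-class]), `frame` (`n x 3`
#'   matrix) and `siteCenters` (named list of Na1/Na2/Cl site centre
#'   coordinates used by the ion-dwell generator).
#' @examples
#' toy <- makeToyTransporter()
#' selectAtoms(toy$topology, resid = 104, names = c("NE", "NH1", "NH2"))
#' @export
makeToyTransporter <- function(seed = 0L) {
  clc <- c(2.0, 2.2, 0.8)      # Cl- site centre
  nac <- c(2.0, 5.7, 0.8)      # Na1 site centre
  na2c <- c(-5.0, -5.0, 10.0)  # Na2 site centre
  rows <- list()
  add <- function(name, element, resname, resid, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resname = resname, resid = resid,
      x = x, y = y, z = z, stringsAsFactors = FALSE)

  # ASP 98: chi1 quadruple with CG at +60 degrees by construction
  n98 <- c(-15, 10, 5); ca98 <- c(-13.55, 10, 5)
  cb98 <- .placeAtom(c(-15.5, 11.2, 5), n98, ca98, 1.53, 111, -120)
  cg98 <- .placeAtom(n98, ca98, cb98, 1.52, 114, 60)
  od1 <- cg98 + c(0.7, 0.9, 0.3); od2 <- cg98 + c(-0.8, 0.8, -0.4)
  add("N", "N", "ASP", 98, n98[1], n98[2], n98[3])
  add("CA", "C", "ASP", 98, ca98[1], ca98[2], ca98[3])
  add("CB", "C", "ASP", 98, cb98[1], cb98[2], cb98[3])
  add("CG", "C", "ASP", 98, cg98[1], cg98[2], cg98[3])
  add("OD1", "O", "ASP", 98, od1[1], od1[2], od1[3])
  add("OD2", "O", "ASP", 98, od2[1], od2[2], od2[3])

  # ARG 104: backbone plus guanidinium donors; NH1/NH2 rest in the "off"
  # band relative to both acceptors, NE is kept remote
  add("N",  "N", "ARG", 104, 8.0, 10.5, 0.0)
  add("CA", "C", "ARG", 104, 9.0, 11.5, 0.0)
  add("CB", "C", "ARG", 104, 9.5, 12.5, 1.0)
  add("CG", "C", "ARG", 104, 10.0, 13.5, 0.3)
  add("CD", "C", "ARG", 104, 10.2, 14.2, 1.3)
  add("NE", "N", "ARG", 104, 10.0, 15.0, 0.0)
  add("CZ", "C", "ARG", 104, 10.5, 16.2, 0.2)
  add("NH1", "N", "ARG", 104, 5.5, 0.0, 0.0)
  add("NH2", "N", "ARG", 104, 14.5, 0.0, 0.0)

  # TYR 107: full side chain (ring), plus backbone
  t107 <- list(
    N = c(0, -20, 0), CA = c(1.45, -20, 0), C = c(2.0, -21.3, 0),
    O = c(1.3, -22.3, 0), CB = c(2.0, -18.7, 0.5), CG = c(3.4, -18.5, 0.5),
    CD1 = c(4.1, -17.9, 1.5), CD2 = c(4.2, -19.0, -0.5),
    CE1 = c(5.5, -17.7, 1.4), CE2 = c(5.6, -18.8, -0.6),
    CZ = c(6.2, -18.2, 0.4), OH = c(7.6, -18.0, 0.3))
  for (nm in names(t107)) {
    el <- substr(nm, 1, 1)
    add(nm, el, "TYR", 107, t107[[nm]][1], t107[[nm]][2], t107[[nm]][3])
  }

  # GLN 332: chi2 quadruple N-CA-CB-CG-CD with OE1 at the origin (the gate
  # glutamine acceptor) and NE2 in the Cl- coordination shell
  add("N",  "N", "GLN", 332, 3.3, -4.2, 0.0)
  add("CA", "C", "GLN", 332, 3.6, -2.9, 0.0)
  add("CB", "C", "GLN", 332, 2.9, -1.6, 0.2)
  add("CG", "C", "GLN", 332, 1.5, -1.8, 0.4)
  add("CD", "C", "GLN", 332, 0.7, -0.6, 0.2)
  add("OE1", "O", "GLN", 332, 0.0, 0.0, 0.0)
  add("NE2", "N", "GLN", 332, 1.2, 0.6, 0.2)

  # GLU 493: carboxylate acceptors 20 A from the glutamine's
  add("N",  "N", "GLU", 493, 23.5, -4.1, 0.0)
  add("CA", "C", "GLU", 493, 22.9, -2.9, 0.0)
  add("CB", "C", "GLU", 493, 21.5, -2.8, 0.2)
  add("CG", "C", "GLU", 493, 21.0, -1.5, 0.4)
  add("CD", "C", "GLU", 493, 20.6, -0.9, 0.2)
  add("OE1", "O", "GLU", 493, 20.0, 0.0, 0.0)
  add("OE2", "O", "GLU", 493, 20.0, 1.4, 0.0)

  # Na1-site coordinating atoms (2.3 A shell) and the shared Ser336 OG
  add("O",   "O", "ALA", 96,  nac[1] + 2.3, nac[2], nac[3])
  add("OD1", "O", "ASN", 101, nac[1], nac[2] + 2.3, nac[3])
  add("O",   "O", "SER", 336, nac[1], nac[2], nac[3] + 2.3)
  add("OD1", "O", "ASN", 368, nac[1] - 1.63, nac[2] - 1.63, nac[3])
  add("OG",  "O", "SER", 336, nac[1], nac[2] - 2.3, nac[3])
  # Cl--site coordinating atoms (NE2 and Ser336 OG already placed)
  add("ND2", "N", "ASN", 101, clc[1] + 3.0, clc[2], clc[3])
  add("OH",  "O", "TYR", 121, clc[1], clc[2] - 3.0, clc[3])
  add("OG",  "O", "SER", 372, clc[1], clc[2], clc[3] + 3.0)
  # Na2-site coordinating atoms
  add("O",  "O", "GLY", 94,  na2c[1] + 2.3, na2c[2], na2c[3])
  add("O",  "O", "VAL", 97,  na2c[1], na2c[2] + 2.3, na2c[3])
  add("O",  "O", "LEU", 434, na2c[1], na2c[2], na2c[3] + 2.3)
  add("OG", "O", "SER", 438, na2c[1] - 1.63, na2c[2] - 1.63, na2c[3])
  # Ions at their site centres
  add("SOD", "NA", "SOD", 601, nac[1], nac[2], nac[3])
  add("CLA", "CL", "CLA", 602, clc[1], clc[2], clc[3])

  # Filler scaffold CA atoms on a 30 A ring, seed-jittered by 0.1 A
  nf <- 20L
  ang <- 2 * pi * (seq_len(nf) - 1) / nf
  jit <- .withSeed(seed, matrix(stats::runif(nf * 3, -0.1, 0.1), ncol = 3))
  for (i in seq_len(nf))
    add("CA", "C", "ALA", 200L + i - 1L,
        30 * cos(ang[i]) + jit[i, 1], 30 * sin(ang[i]) + jit[i, 2],
        10 * sin(2 * ang[i]) + jit[i, 3])

  tab <- do.call(rbind, rows)
  tab$serial <- seq_len(nrow(tab))
  tab$chain <- "A"
  top <- newTopology(tab[, c("serial", "name", "element", "resname",
                             "resid", "chain")])
  list(topology = top, frame = as.matrix(tab[, c("x", "y", "z")]),
       siteCenters = list(Na1 = nac, Na2 = na2c, Cl = clc))
}
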