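#' Signed torsion angle of four points
#'
#' IUPAC-signed dihedral in degrees on the half-open interval (-180, 180]:
#' positive when, viewed down the p2 to p3 axis, the far bond rotates
#' clockwise from the near bond; the anti-planar case returns +180, never
#' -180. Accepts single points (length-3 vectors) or `n x 3` matrices for a
#' vectorised series.
#'
#' @param p1,p2,p3,p4 length-3 vectors or `n x 3` matrices (Angstrom).
#' @return numeric angle(s) in degrees, in (-180, 180].
#' @examples
#' dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180
#' dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  asMat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- asMat(p1); p2 <- asMat(p2); p3 <- asMat(p3); p4 <- asMat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (any(rowSums(b1^2) < 1e-20) || any(rowSums(b2^2) < 1e-20) ||
      any(rowSums(b3^2) < 1e-20))
    stop("degenerate geometry: coincident points or zero-length torsion axis",
         call. = FALSE)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180 + 1e-12] <- 180
  ang
}

#' chi dihedral atom quadruple for a residue type
#'
#' Looks up the chi1/chi2 atom-name quadruple in the embedded table for the
#' 20 canonical residues (chi1: N-CA-CB-G atom; chi2: CA-CB-G-D atom, with
#' the G/D atom per residue type).
#'
#' @param resname 3-letter residue code.
#' @param chiIndex 1 or 2.
#' @return character vector of 4 atom names.
#' @export
chiAtoms <- function(resname, chiIndex) {
  resname <- toupper(resname)
  if (!chiIndex %in% c(1L, 2L))
    stop("chiIndex must be 1 or 2", call. = FALSE)
  entry <- .chiTable[[resname]]
  if (is.null(entry))
    stop("no chi definition for residue type '", resname, "'", call. = FALSE)
  q <- entry[[paste0("chi", chiIndex)]]
  if (is.null(q))
    stop("residue type ", resname, " has no chi", chiIndex,
         " dihedral", call. = FALSE)
  q
}

#' Side-chain chi dihedral time series
#'
#' One chi angle per frame, with the atom quadruple resolved from the
#' embedded per-residue-type table.
#'
#' @param trajectory a [Trajectory-class].
#' @param resid residue number.
#' @param chiIndex 1 or 2.
#' @param chain optional chain id.
#' @return data.frame with columns `frame`, `time_ps`, `angle_deg`,
#'   `rotamer`; attribute `resid`/`chiIndex` record the request.
#' @export
chiSeries <- function(trajectory, resid, chiIndex = 1L, chain = NULL) {
  top <- trajectory@topology
  sel <- selectAtoms(top, resid = resid, chain = chain)
  resname <- unique(atoms(top)$resname[sel])
  if (length(resname) != 1)
    stop("residue ", resid, " is ambiguous across chains; give `chain`",
         call. = FALSE)
  quad <- chiAtoms(resname, chiIndex)
  idx <- vapply(quad, function(nm)
    selectAtoms(top, resid = resid, chain = chain, names = nm), integer(1))
  co <- trajectory@coords
  ang <- dihedralAngle(t(co[idx[1], , ]), t(co[idx[2], , ]),
                       t(co[idx[3], , ]), t(co[idx[4], , ]))
  tm <- if (length(trajectory@times)) trajectory@times
        else seq_len(nFrames(trajectory))
  out <- data.frame(frame = seq_len(nFrames(trajectory)), time_ps = tm,
                    angle_deg = ang,
                    rotamer = classifyRotamer(ang))
  attr(out, "resid") <- resid; attr(out, "chiIndex") <- chiIndex
  out
}

#' Rotamer class of a chi angle
#'
#' Standard thirds centred on +60 / 180 / -60 degrees: `gauche_plus` for
#' (0, 120], `gauche_minus` for (-120, 0], `trans` for (120, 180] and
#' (-180, -120].
#'
#' @param angle numeric degrees in (-180, 180].
#' @return character vector of classes.
#' @examples
#' classifyRotamer(c(65, -170, -55))
#' @export
classifyRotamer <- function(angle) {
  if (any(angle <= -180 | angle > 180))
    stop("angle out of domain (-180, 180]", call. = FALSE)
  ifelse(angle > 0 & angle <= 120, "gauche_plus",
         ifelse(angle > -120 & angle <= 0, "gauche_minus", "trans"))
}
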