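# Bondi van der Waals radii (Angstrom); fixed table keeps results deterministic.
.bondi <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.defaultRadius <- 1.70

#' Van der Waals radius lookup
#'
#' Returns the embedded Bondi radius for an element symbol; unknown elements
#' get the default 1.70 Angstrom.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdwRadius(c("C", "N", "O", "Xx"))
#' @export
vdwRadius <- function(element) {
  r <- .bondi[toupper(trimws(element))]
  r[is.na(r)] <- .defaultRadius
  unname(r)
}

# Element inferred from a PDB atom name when the element column is absent:
# strip digits/primes, take first letter, except two-letter ions/metals that
# the toy systems use (NA, CL, MG, ZN, FE, MN, K).
.elementFromName <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("NA", "CL", "MG", "ZN", "FE", "MN", "BR")
  ifelse(nm %in% two, nm, {
    stripped <- gsub("[0-9']", "", nm)
    substr(stripped, 1, 1)
  })
}

# Side-chain chi dihedral atom-name tables for the 20 canonical residues.
# chi1 = N-CA-CB-X; chi2 = CA-CB-G-X. NULL entry = residue lacks that chi.
.chiTable <- list(
  ARG = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD")),
  ASN = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "OD1")),
  ASP = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "OD1")),
  CYS = list(chi1 = c("N", "CA", "CB", "SG"),  chi2 = NULL),
  GLN = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD")),
  GLU = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD")),
  HIS = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "ND1")),
  ILE = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = c("CA", "CB", "CG1", "CD1")),
  LEU = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD1")),
  LYS = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD")),
  MET = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "SD")),
  PHE = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD1")),
  PRO = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD")),
  SER = list(chi1 = c("N", "CA", "CB", "OG"),  chi2 = NULL),
  THR = list(chi1 = c("N", "CA", "CB", "OG1"), chi2 = NULL),
  TRP = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD1")),
  TYR = list(chi1 = c("N", "CA", "CB", "CG"),  chi2 = c("CA", "CB", "CG", "CD1")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1"), chi2 = NULL),
  ALA = list(chi1 = NULL, chi2 = NULL),
  GLY = list(chi1 = NULL, chi2 = NULL))
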