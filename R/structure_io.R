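#' Construct a Topology from an atom table
#'
#' Low-level constructor; radii are filled from the embedded Bondi table when
#' the `radius` column is absent, and elements are inferred from atom names
#' when the `element` column is absent.
#'
#' @param atoms data.frame with at least `serial`, `name`, `resname`,
#'   `resid`, `chain` columns.
#' @return a [Topology-class] object.
#' @export
newTopology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element)) atoms$element <- .elementFromName(atoms$name)
  if (is.null(atoms$radius)) atoms$radius <- vdwRadius(atoms$element)
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms)
}

#' Construct a Trajectory
#'
#' @param topology a [Topology-class].
#' @param coords either an `n_atoms x 3 x n_frames` array or a list of
#'   `n_atoms x 3` frame matrices.
#' @param times optional numeric frame times (ps).
#' @param box optional `n_frames x 3` box-length matrix (Angstrom).
#' @param label replica identifier.
#' @return a [Trajectory-class] object.
#' @export
newTrajectory <- function(topology, coords, times = numeric(0),
                          box = matrix(numeric(0), 0, 3), label = "traj") {
  if (is.list(coords)) {
    arr <- array(0, c(nrow(coords[[1]]), 3L, length(coords)))
    for (i in seq_along(coords)) arr[, , i] <- coords[[i]]
    coords <- arr
  }
  new("Trajectory", topology = topology, coords = coords,
      times = as.numeric(times), box = box, label = label)
}

#' Read a PDB structure
#'
#' Reads ATOM/HETATM records in file order via \pkg{bio3d}. For alternate
#' locations only the highest-occupancy altloc is kept, ties broken toward
#' label "A". Van der Waals radii are assigned from the embedded Bondi table;
#' unknown elements receive the 1.70 Angstrom default.
#'
#' @param path PDB file path.
#' @return list with elements `topology` ([Topology-class]) and `frame`
#'   (`n_atoms x 3` coordinate matrix, Angstrom).
#' @examples
#' toy <- makeToyTransporter()
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(toy$topology, toy$frame, f)
#' rt <- readStructure(f)
#' nAtoms(rt$topology)
#' @export
readStructure <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("parse error reading PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("parse error: no ATOM/HETATM records in '", path, "'", call. = FALSE)
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad))
    stop("parse error: malformed coordinate fields at atom serial ",
         a$eleno[bad[1]], " in '", path, "'", call. = FALSE)
  a <- .filterAltloc(a)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  miss <- is.na(elem) | trimws(elem) == ""
  elem[miss] <- .elementFromName(a$elety[miss])
  top <- newTopology(data.frame(
    serial = as.integer(a$eleno), name = trimws(a$elety),
    element = trimws(elem), resname = trimws(a$resid),
    resid = as.integer(a$resno), chain = chain,
    stringsAsFactors = FALSE))
  list(topology = top, frame = cbind(a$x, a$y, a$z))
}

# Keep highest-occupancy altloc per (chain, resno, atom name); ties -> "A".
.filterAltloc <- function(a) {
  alt <- a$alt
  if (is.null(alt)) return(a)
  alt[is.na(alt)] <- ""
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  if (!anyDuplicated(key[alt != ""])) {
    dupk <- unique(key[duplicated(key)])
    if (!length(dupk)) return(a)
  }
  occ <- a$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    best <- idx[order(-occ[idx], alt[idx] != "A", alt[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  a[keep, , drop = FALSE]
}

#' Read a trajectory (DCD or multi-model PDB)
#'
#' DCD files are read via \pkg{bio3d}; any other extension is treated as a
#' multi-model PDB. The frame atom count must match the supplied topology.
#'
#' @param path trajectory file.
#' @param topology the ensemble's shared [Topology-class].
#' @param label replica identifier stored on the result.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, label = basename(path)) {
  nat <- nAtoms(topology)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    found <- ncol(xyz) / 3
    if (found != nat)
      stop("structural error: trajectory has ", found,
           " atoms per frame, topology expects ", nat, call. = FALSE)
    nf <- nrow(xyz)
    coords <- array(0, c(nat, 3L, nf))
    for (i in seq_len(nf)) coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  } else {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("parse error reading trajectory '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    found <- ncol(xyz) / 3
    if (found != nat)
      stop("structural error: trajectory has ", found,
           " atoms per frame, topology expects ", nat, call. = FALSE)
    nf <- nrow(xyz)
    coords <- array(0, c(nat, 3L, nf))
    for (i in seq_len(nf)) coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  message(sprintf("readTrajectory: %d frames of %d atoms from '%s'",
                  dim(coords)[3], nat, path))
  newTrajectory(topology, coords, label = label)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (no unit-cell records), compatible
#' with standard readers including `bio3d::read.dcd`.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDCD <- function(trajectory, path) {
  coords <- trajectory@coords
  nat <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran sequential record: payload length markers fore and aft
    raw0 <- rawConnection(raw(0), "wb")
    writer(raw0)
    payload <- rawConnectionValue(raw0)
    close(raw0)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf       # number of frames
  icntrl[2] <- 1L       # first step
  icntrl[3] <- 1L       # save interval
  icntrl[4] <- nf
  icntrl[20] <- 24L     # CHARMM version flag (single-precision coords)
  rec(function(c0) {
    writeChar("CORD", c0, nchars = 4, eos = NULL)
    writeBin(icntrl, c0, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "gatescope trajectory")
  rec(function(c0) {
    writeBin(1L, c0, size = 4, endian = "little")
    writeChar(title, c0, nchars = 80, eos = NULL)
  })
  rec(function(c0) writeBin(as.integer(nat), c0, size = 4, endian = "little"))
  for (i in seq_len(nf)) {
    for (ax in 1:3) {
      v <- coords[, ax, i]
      rec(function(c0) writeBin(as.numeric(v), c0, size = 4, endian = "little"))
    }
  }
  invisible(path)
}

#' Write a structure or multi-model trajectory as PDB
#'
#' Fixed-width ATOM records; when several frames are given they are wrapped
#' in MODEL/ENDMDL blocks.
#'
#' @param topology a [Topology-class].
#' @param frames one `n_atoms x 3` matrix, or a list of them, or a
#'   [Trajectory-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructure <- function(topology, frames, path) {
  if (is(frames, "Trajectory"))
    frames <- lapply(seq_len(nFrames(frames)), function(i) frameCoords(frames, i))
  if (is.matrix(frames)) frames <- list(frames)
  a <- atoms(topology)
  lines <- character(0)
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    xyz <- frames[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                 sprintf("%-4s", a$name))
    lines <- c(lines, sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, nm, a$resname, a$chain, a$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00,
      substr(a$element, 1, 2)))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms from a topology
#'
#' Deterministic selection by residue number, chain and/or atom names;
#' indices are returned in topology (file) order. Omitting `names` (or
#' passing `"*"`) selects every atom of the matching residues. An empty
#' result is an error, so analyses never silently run on nothing.
#'
#' @param topology a [Topology-class].
#' @param resid optional integer residue number(s).
#' @param chain optional chain id(s).
#' @param names optional character atom names, or `"*"` for all.
#' @param resname optional residue name(s).
#' @return integer vector of atom indices (1-based, topology order).
#' @examples
#' toy <- makeToyTransporter()
#' selectAtoms(toy$topology, resid = 104, names = c("NE", "NH1", "NH2"))
#' @export
selectAtoms <- function(topology, resid = NULL, chain = NULL, names = NULL,
                        resname = NULL) {
  a <- atoms(topology)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(names) && !identical(names, "*")) keep <- keep & a$name %in% names
  idx <- which(keep)
  if (!length(idx))
    stop("empty selection: no atoms match (resid=",
         paste(resid, collapse = ","), ", chain=", paste(chain, collapse = ","),
         ", names=", paste(names, collapse = ","), ")", call. = FALSE)
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` by the optimal proper rotation and
#' translation over the selected atoms; the whole mobile frame is
#' transformed and the RMSD over the selection is returned.
#'
#' @param mobile `n x 3` coordinate matrix.
#' @param reference `n x 3` coordinate matrix (same atom count).
#' @param selection integer atom indices used for the fit (>= 3,
#'   non-collinear).
#' @return list with `coords` (transformed mobile, `n x 3`), `rmsd`
#'   (Angstrom, over the selection), `rotation` (3 x 3) and
#'   `translation` (length 3).
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3)
    stop("degenerate geometry: superposition needs >= 3 selected atoms",
         call. = FALSE)
  X <- mobile[selection, , drop = FALSE]
  Y <- reference[selection, , drop = FALSE]
  k <- .kabsch(X, Y)
  moved <- sweep(mobile, 2, k$xc) %*% t(k$R)
  moved <- sweep(moved, 2, k$yc, FUN = "+")
  rmsd <- sqrt(mean(rowSums((moved[selection, , drop = FALSE] - Y)^2)))
  list(coords = moved, rmsd = rmsd, rotation = k$R,
       translation = as.numeric(k$yc - k$xc %*% t(k$R)))
}

# Kabsch core: optimal proper rotation R and centroids mapping X onto Y.
.kabsch <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  for (M in list(Xc, Yc)) {
    s <- svd(M)$d
    if (s[2] <= 1e-8 * max(s[1], 1e-12))
      stop("degenerate geometry: selected atoms are collinear", call. = FALSE)
  }
  A <- crossprod(Xc, Yc)              # 3x3 covariance
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, xc = xc, yc = yc)
}

#' Write an occupancy grid in OpenDX scalar-field dialect
#'
#' Header encodes origin, diagonal deltas and counts; data values are laid
#' out in the grid array's own (x-fastest) linear order, three per line.
#' [readGridDX()] round-trips the file within 1e-6.
#'
#' @param grid an [OccupancyGrid-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGridDX <- function(grid, path) {
  n <- grid@counts
  if (prod(n) == 0) stop("cannot write an empty grid (0 voxels)", call. = FALSE)
  v <- as.vector(grid@values)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# gatescope occupancy map",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.9g %.9g %.9g", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %.9g 0 0", grid@spacing),
    sprintf("delta 0 %.9g 0", grid@spacing),
    sprintf("delta 0 0 %.9g", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  pad <- c(v, rep(NA_real_, (3 - length(v) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.7e", r[!is.na(r)]), collapse = " ")), con)
  invisible(path)
}

#' Read an occupancy grid written by [writeGridDX()]
#'
#' @param path DX file path.
#' @return an [OccupancyGrid-class] (the `inSphere` flags are restored as
#'   all-`TRUE`; they are presentation metadata, not data).
#' @export
readGridDX <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  cnt <- as.integer(strsplit(sub(".*counts ", "", lines[grep("gridpositions", lines)[1]]),
                             "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "", lines[grep("^origin", lines)[1]]),
                             "\\s+")[[1]])
  deltas <- unname(lines[grep("^delta", lines)])
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta ", "", l), "\\s+")[[1]]), numeric(3),
    USE.NAMES = FALSE))
  spacing <- unname(dmat[1, 1])
  start <- grep("data follows", lines)[1] + 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:length(lines)]), "\\s+")))
  vals <- vals[!is.na(vals)][seq_len(prod(cnt))]
  new("OccupancyGrid", origin = org, spacing = spacing, counts = cnt,
      values = array(vals, cnt), inSphere = array(TRUE, cnt),
      nFramesTotal = 0L)
}
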