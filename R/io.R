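# File formats: extended-XYZ trajectories (with lattice and molecule ids),
# PDB snapshots (through bio3d), Gaussian-cube-style volumetric maps, and the
# delimited tables for predictions, distributions and selections.

#' Write snapshots as an extended-XYZ trajectory
#'
#' One frame per snapshot: the atom-count line, a comment line carrying
#' \code{Lattice="..."} (row-major lattice vectors, Angstrom),
#' \code{Properties=species:S:1:pos:R:3:site:S:1:mol_id:I:1:atom_id:I:1} and
#' \code{Frame=trajectory,frame}, then one row per atom.
#'
#' @param snapshots list of \linkS4class{Snapshot}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectoryXYZ <- function(snapshots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in snapshots) {
    a <- s@atoms
    lat <- paste(sprintf("%.8f", t(s@cell@lattice)), collapse = " ")
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:site:S:1:mol_id:I:1:atom_id:I:1 Frame=%d,%d',
      lat, s@snapshotId[1L], s@snapshotId[2L]), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f %-6s %6d %6d",
                       a$element, a$x, a$y, a$z, a$siteLabel,
                       a$moleculeId, a$atomId), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Parses frames written by \code{\link{writeTrajectoryXYZ}} (or any
#' extended-XYZ dialect with a \code{Lattice} entry and per-atom
#' species/position columns). Molecule ids are taken from the \code{mol_id}
#' column when present; otherwise molecules are perceived by connected
#' components of the covalent-radius bond criterion (1.2 x sum of covalent
#' radii), which is logged via a message.
#'
#' @param path file path.
#' @param topology a \linkS4class{MolecularTopology} for the snapshots; when
#'   NULL a permissive per-frame topology is derived from the first molecule.
#' @return list of \linkS4class{Snapshot} in frame order.
#' @export
readTrajectoryXYZ <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  snaps <- list()
  i <- 1L
  frameNo <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed atom-count line at line ", i)
    frameNo <- frameNo + 1L
    header <- lines[i + 1L]
    latMatch <- regmatches(header,
                           regexpr('Lattice="[^"]+"', header))
    if (!length(latMatch))
      stop("frame ", frameNo, " is missing the Lattice entry")
    latVals <- as.numeric(strsplit(
      sub('Lattice="([^"]+)"', "\\1", latMatch), "\\s+")[[1L]])
    if (length(latVals) != 9L || any(is.na(latVals)))
      stop("frame ", frameNo, " has a malformed Lattice entry")
    lat <- matrix(latVals, 3L, 3L, byrow = TRUE)
    idMatch <- regmatches(header, regexpr("Frame=\\d+,\\d+", header))
    snapId <- if (length(idMatch))
      as.integer(strsplit(sub("Frame=", "", idMatch), ",")[[1L]])
    else c(1L, frameNo)
    if (i + 1L + n > length(lines))
      stop("frame ", frameNo, " is truncated (inconsistent atom count)")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    ncol. <- lengths(rows)
    if (any(ncol. < 4L)) stop("frame ", frameNo, " has malformed atom rows")
    el <- vapply(rows, `[`, character(1L), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
    if (any(is.na(xyz))) stop("frame ", frameNo, " has non-numeric coordinates")
    a <- data.frame(element = el, x = xyz[, 1L], y = xyz[, 2L],
                    z = xyz[, 3L])
    if (all(ncol. >= 7L)) {
      a$siteLabel <- vapply(rows, `[`, character(1L), 5L)
      a$moleculeId <- as.integer(vapply(rows, `[`, character(1L), 6L))
      a$atomId <- as.integer(vapply(rows, `[`, character(1L), 7L))
    } else {
      message("frame ", frameNo,
              ": no mol_id column; perceiving molecules from covalent radii")
      a$moleculeId <- .perceiveMolecules(lat, a)
      a$siteLabel <- paste0(a$element, stats::ave(
        seq_len(nrow(a)), a$moleculeId, FUN = seq_along))
      a$atomId <- seq_len(nrow(a))
    }
    topo <- topology
    if (is.null(topo)) {
      one <- a[a$moleculeId == a$moleculeId[1L], , drop = FALSE]
      topo <- molecularTopology(one$siteLabel,
                                stats::setNames(one$element, one$siteLabel))
    }
    snaps[[frameNo]] <- snapshot(periodicCell(lat), a, topo, snapId)
    i <- i + 2L + n
  }
  snaps
}

.covalentRadii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02)

## connected components of the 1.2 x (r_i + r_j) covalent bond criterion
.perceiveMolecules <- function(lattice, a) {
  unknown <- setdiff(unique(a$element), names(.covalentRadii))
  if (length(unknown))
    stop("unknown element(s) for bond perception: ",
         paste(unknown, collapse = ", "))
  n <- nrow(a)
  frac <- .cartToFrac(lattice, cbind(a$x, a$y, a$z))
  D <- .pairDistances(lattice, frac, frac)
  rad <- .covalentRadii[a$element]
  thresh <- 1.2 * outer(rad, rad, "+")
  adj <- D <= thresh & D > 1e-8
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Read a PDB file as a snapshot
#'
#' Uses \pkg{bio3d} to parse the PDB; the periodic cell is taken from the
#' CRYST1 record, molecule ids from the residue number, and site labels from
#' the atom names.
#'
#' @param path PDB file path.
#' @param topology optional \linkS4class{MolecularTopology}; derived from
#'   the first residue when NULL.
#' @return a \linkS4class{Snapshot}.
#' @export
readSnapshotPDB <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cr)) stop("PDB file has no CRYST1 record (missing lattice)")
  p <- as.numeric(c(substr(cr[1L], 7, 15), substr(cr[1L], 16, 24),
                    substr(cr[1L], 25, 33), substr(cr[1L], 34, 40),
                    substr(cr[1L], 41, 47), substr(cr[1L], 48, 54)))
  lat <- .cellParamsToLattice(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L])
  at <- pdb$atom
  el <- trimws(at$elesy)
  el[!nzchar(el)] <- substr(trimws(at$elety[!nzchar(el)]), 1L, 1L)
  a <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                  siteLabel = trimws(at$elety),
                  moleculeId = as.integer(at$resno),
                  atomId = seq_len(nrow(at)))
  if (is.null(topology)) {
    one <- a[a$moleculeId == a$moleculeId[1L], , drop = FALSE]
    topology <- molecularTopology(one$siteLabel,
                                  stats::setNames(one$element, one$siteLabel))
  }
  snapshot(periodicCell(lat), a, topology, c(1L, 1L))
}

## standard crystallographic cell-parameter to lattice-vector conversion
.cellParamsToLattice <- function(a, b, c., alpha, beta, gamma) {
  al <- .rad(alpha)
  be <- .rad(beta)
  ga <- .rad(gamma)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c. * cos(be)
  cy <- c. * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(c.^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

#' Write a density map in Gaussian-cube-style format
#'
#' Header: two comment lines (the second flags Angstrom units), the atom
#' count (0 unless reference atoms are passed) with the grid origin, three
#' axis lines with node counts and spacing vectors, optional atom records,
#' then the values in x-major order, six per line. Axis counts are written
#' negative, the cube convention flagging Angstrom rather than Bohr units.
#'
#' @param map array from \code{\link{densityMap}}.
#' @param path output path.
#' @param referenceAtoms optional data.frame (element, x, y, z) written as
#'   cube atom records for visualization.
#' @return the path, invisibly.
#' @export
writeCube <- function(map, path, referenceAtoms = NULL) {
  ax <- attr(map, "axes")
  if (is.null(ax)) stop("map carries no grid axes; use densityMap()")
  d <- dim(map)
  spacing <- c(ax$x[2L] - ax$x[1L], ax$y[2L] - ax$y[1L],
               ax$z[2L] - ax$z[1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("Atomic density map, element %s",
                     attr(map, "element")), con)
  writeLines("Units: Angstrom (negative axis counts)", con)
  natoms <- if (is.null(referenceAtoms)) 0L else nrow(referenceAtoms)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", natoms,
                     ax$x[1L], ax$y[1L], ax$z[1L]), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", -d[1L], spacing[1L], 0, 0),
             con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", -d[2L], 0, spacing[2L], 0),
             con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", -d[3L], 0, 0, spacing[3L]),
             con)
  if (natoms) {
    z <- .atomicNumbers[referenceAtoms$element]
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, 0,
                       referenceAtoms$x, referenceAtoms$y,
                       referenceAtoms$z), con)
  }
  vals <- as.vector(aperm(map, c(3L, 2L, 1L)))  # x slowest, z fastest
  full <- length(vals) %/% 6L * 6L
  if (full)
    writeLines(sprintf("%13.5e %13.5e %13.5e %13.5e %13.5e %13.5e",
                       vals[seq(1, full, by = 6)], vals[seq(2, full, by = 6)],
                       vals[seq(3, full, by = 6)], vals[seq(4, full, by = 6)],
                       vals[seq(5, full, by = 6)], vals[seq(6, full, by = 6)]),
               con)
  if (full < length(vals))
    writeLines(paste(sprintf("%13.5e", vals[(full + 1L):length(vals)]),
                     collapse = " "), con)
  invisible(path)
}

#' Read and write the delimited tables used by the pipeline
#'
#' Predictions, experimental distributions, selection tables and two-column
#' curves are plain tab-separated text with a header; these helpers validate
#' the schema on read.
#'
#' @param path file path.
#' @param x data.frame (for writers) in the matching schema.
#' @return data.frame (readers) or the path, invisibly (writers).
#' @name shiftTables
NULL

#' @rdname shiftTables
#' @export
readPredictionTable <- function(path) {
  .checkPredictions(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' @rdname shiftTables
#' @export
writePredictionTable <- function(x, path) {
  .checkPredictions(x)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname shiftTables
#' @export
readDistributionTable <- function(path) {
  .checkDistributions(utils::read.table(path, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
}

#' @rdname shiftTables
#' @export
writeDistributionTable <- function(x, path) {
  .checkDistributions(x)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname shiftTables
#' @export
readCurve <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("r", "value"))
  if (!nrow(tab)) stop("empty curve file: ", path)
  tab
}
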