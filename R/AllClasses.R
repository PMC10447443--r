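#' @import methods
NULL

# ---------------------------------------------------------------------------
# PeriodicCell

#' Periodic simulation cell
#'
#' A right-handed, non-degenerate periodic cell described by a 3x3 matrix of
#' lattice vectors (rows) in Angstrom.
#'
#' @slot lattice 3x3 numeric matrix; rows are the lattice vectors a, b, c.
#' @export
setClass("PeriodicCell", representation(lattice = "matrix"))

setValidity("PeriodicCell", function(object) {
  L <- object@lattice
  if (!is.numeric(L) || !identical(dim(L), c(3L, 3L)))
    return("lattice must be a numeric 3x3 matrix")
  if (any(!is.finite(L)))
    return("lattice entries must be finite")
  if (det(L) <= 0)
    return("lattice determinant must be strictly positive (right-handed cell)")
  TRUE
})

#' Construct a periodic cell
#'
#' @param lattice 3x3 matrix of lattice vectors (rows) in Angstrom, or a
#'   single number for a cubic cell of that side.
#' @return A \linkS4class{PeriodicCell}.
#' @examples
#' periodicCell(20)
#' @export
periodicCell <- function(lattice) {
  if (length(lattice) == 1L && is.numeric(lattice))
    lattice <- diag(rep(as.numeric(lattice), 3L))
  new("PeriodicCell", lattice = lattice)
}

#' @describeIn periodicCell lattice-matrix accessor
#' @param cell A \code{PeriodicCell}.
#' @export
cellLattice <- function(cell) cell@lattice

#' @describeIn periodicCell cell volume in cubic Angstrom
#' @export
cellVolume <- function(cell) det(cell@lattice)

setMethod("show", "PeriodicCell", function(object) {
  v <- round(cellVolume(object), 2)
  cat("PeriodicCell, volume", v, "A^3\n")
  print(round(object@lattice, 4))
})

# ---------------------------------------------------------------------------
# MolecularTopology

#' Molecular topology shared by all molecules of a compound
#'
#' Site labels, bonds, named dihedral definitions, and the hydrogen-bond
#' donor/acceptor roles for one molecular species. All molecules in a
#' \linkS4class{Snapshot} realize this topology exactly once.
#'
#' @slot siteLabels ordered character vector of unique site labels.
#' @slot elements named character vector: element symbol per site label.
#' @slot bonds two-column character matrix of bonded label pairs.
#' @slot dihedralDefs named list of character(4) site-label quadruples.
#' @slot hbondDonor character(2): the donor oxygen and hydroxyl proton labels
#'   (length 0 if the molecule has no donor).
#' @slot hbondAcceptors data.frame with columns \code{siteLabel},
#'   \code{element} (O or N).
#' @export
setClass("MolecularTopology", representation(
  siteLabels = "character",
  elements = "character",
  bonds = "matrix",
  dihedralDefs = "list",
  hbondDonor = "character",
  hbondAcceptors = "data.frame"
))

setValidity("MolecularTopology", function(object) {
  sl <- object@siteLabels
  if (anyDuplicated(sl)) return("site labels must be unique")
  if (!all(sl %in% names(object@elements)))
    return("every site label needs an element entry")
  b <- object@bonds
  if (length(b) && (!is.character(b) || ncol(b) != 2L))
    return("bonds must be a two-column character matrix")
  if (length(b) && !all(b %in% sl))
    return("bond endpoints must be declared site labels")
  for (nm in names(object@dihedralDefs)) {
    q <- object@dihedralDefs[[nm]]
    if (length(q) != 4L || !all(q %in% sl))
      return(sprintf("dihedral '%s' must be four declared site labels", nm))
  }
  if (length(object@hbondDonor) && length(object@hbondDonor) != 2L)
    return("hbondDonor must be empty or length 2 (O label, H label)")
  if (length(object@hbondDonor) && !all(object@hbondDonor %in% sl))
    return("hbondDonor labels must be declared site labels")
  ha <- object@hbondAcceptors
  if (nrow(ha)) {
    if (!all(c("siteLabel", "element") %in% names(ha)))
      return("hbondAcceptors needs siteLabel and element columns")
    if (!all(ha$siteLabel %in% sl))
      return("acceptor labels must be declared site labels")
  }
  TRUE
})

#' Construct a molecular topology
#'
#' @param siteLabels character vector of unique site labels.
#' @param elements named character vector mapping site label to element symbol.
#' @param bonds two-column character matrix (or NULL).
#' @param dihedralDefs named list of character(4) label quadruples.
#' @param hbondDonor character(2) c(O label, H label), or character(0).
#' @param hbondAcceptors data.frame(siteLabel, element).
#' @return A \linkS4class{MolecularTopology}.
#' @export
molecularTopology <- function(siteLabels, elements, bonds = NULL,
                              dihedralDefs = list(),
                              hbondDonor = character(0),
                              hbondAcceptors = NULL) {
  if (is.null(bonds))
    bonds <- matrix(character(0), ncol = 2L)
  if (is.null(hbondAcceptors))
    hbondAcceptors <- data.frame(siteLabel = character(0),
                                 element = character(0))
  new("MolecularTopology", siteLabels = siteLabels, elements = elements,
      bonds = bonds, dihedralDefs = dihedralDefs, hbondDonor = hbondDonor,
      hbondAcceptors = hbondAcceptors)
}

#' @describeIn molecularTopology site-label accessor
#' @param topology A \code{MolecularTopology}.
#' @export
siteLabels <- function(topology) topology@siteLabels

#' @describeIn molecularTopology named dihedral definitions
#' @export
dihedralDefs <- function(topology) topology@dihedralDefs

setMethod("show", "MolecularTopology", function(object) {
  cat("MolecularTopology:", length(object@siteLabels), "sites,",
      nrow(object@bonds), "bonds,", length(object@dihedralDefs),
      "named dihedrals\n")
  if (length(object@hbondDonor))
    cat("  H-bond donor:", paste(object@hbondDonor, collapse = "-"),
        " acceptors:", paste(object@hbondAcceptors$siteLabel, collapse = ", "),
        "\n")
})

# ---------------------------------------------------------------------------
# Snapshot

#' One periodic MD snapshot
#'
#' Atoms partitioned into molecules that all realize a shared
#' \linkS4class{MolecularTopology}, inside a \linkS4class{PeriodicCell}.
#' The atom table has columns \code{element}, \code{x}, \code{y}, \code{z}
#' (Cartesian Angstrom), \code{siteLabel}, \code{moleculeId}, \code{atomId}.
#'
#' @slot cell a \linkS4class{PeriodicCell}.
#' @slot atoms data.frame of atoms (see description).
#' @slot topology the shared \linkS4class{MolecularTopology}.
#' @slot snapshotId integer(2): (trajectory index, frame index).
#' @export
setClass("Snapshot", representation(
  cell = "PeriodicCell",
  atoms = "data.frame",
  topology = "MolecularTopology",
  snapshotId = "integer"
))

setValidity("Snapshot", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "siteLabel", "moleculeId", "atomId")
  if (!all(need %in% names(a)))
    return(paste("atom table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$atomId))
    return("atomId must be unique within a snapshot")
  if (length(object@snapshotId) != 2L)
    return("snapshotId must be integer(2): (trajectory, frame)")
  sl <- sort(object@topology@siteLabels)
  bad <- vapply(split(a$siteLabel, a$moleculeId),
                function(s) !identical(sort(s), sl), logical(1L))
  if (any(bad))
    return(sprintf("molecule(s) %s do not realize the topology site set",
                   paste(names(bad)[bad], collapse = ", ")))
  TRUE
})

#' Construct a snapshot
#'
#' @param cell \linkS4class{PeriodicCell}.
#' @param atoms atom data.frame (element, x, y, z, siteLabel, moleculeId,
#'   atomId).
#' @param topology \linkS4class{MolecularTopology}.
#' @param snapshotId integer(2) (trajectory, frame).
#' @return A \linkS4class{Snapshot}.
#' @export
snapshot <- function(cell, atoms, topology, snapshotId = c(1L, 1L)) {
  if (!"atomId" %in% names(atoms)) atoms$atomId <- seq_len(nrow(atoms))
  new("Snapshot", cell = cell, atoms = atoms, topology = topology,
      snapshotId = as.integer(snapshotId))
}

#' @describeIn snapshot atom-table accessor
#' @param x A \code{Snapshot} or \code{LocalEnvironment}.
#' @export
atoms <- function(x) x@atoms

#' @describeIn snapshot number of molecules
#' @export
nMolecules <- function(x) length(unique(x@atoms$moleculeId))

setMethod("show", "Snapshot", function(object) {
  cat(sprintf("Snapshot (trajectory %d, frame %d): %d atoms in %d molecules\n",
              object@snapshotId[1L], object@snapshotId[2L],
              nrow(object@atoms), nMolecules(object)))
})

# ---------------------------------------------------------------------------
# LocalEnvironment

#' Local molecular environment
#'
#' A central molecule plus all molecules having at least one atom within the
#' cutoff of any central atom, with coordinates unwrapped so every member is
#' contiguous and sits at its nearest image relative to the central molecule.
#'
#' @slot atoms data.frame (element, x, y, z, siteLabel, moleculeId, atomId)
#'   with unwrapped Cartesian coordinates.
#' @slot centralMoleculeId integer.
#' @slot memberMoleculeIds integer vector (central included).
#' @slot cutoff numeric, Angstrom.
#' @slot sourceId integer(2): (trajectory, frame) of the source snapshot.
#' @export
setClass("LocalEnvironment", representation(
  atoms = "data.frame",
  centralMoleculeId = "integer",
  memberMoleculeIds = "integer",
  cutoff = "numeric",
  sourceId = "integer"
))

setValidity("LocalEnvironment", function(object) {
  if (!(object@centralMoleculeId %in% object@memberMoleculeIds))
    return("central molecule must be a member")
  if (anyDuplicated(object@memberMoleculeIds))
    return("no member molecule may appear twice")
  if (!all(object@atoms$moleculeId %in% object@memberMoleculeIds))
    return("atom table contains non-member molecules")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' @describeIn extractEnvironment central-molecule atom subset
#' @param env A \code{LocalEnvironment}.
#' @export
centralAtoms <- function(env) {
  env@atoms[env@atoms$moleculeId == env@centralMoleculeId, , drop = FALSE]
}

#' @describeIn extractEnvironment member molecule ids
#' @export
memberMolecules <- function(env) env@memberMoleculeIds

setMethod("show", "LocalEnvironment", function(object) {
  cat(sprintf(
    "LocalEnvironment: central molecule %d + %d neighbours (cutoff %.1f A)\n",
    object@centralMoleculeId, length(object@memberMoleculeIds) - 1L,
    object@cutoff))
})

# ---------------------------------------------------------------------------
# ShiftReferencing

#' Shielding-to-shift referencing offsets
#'
#' Per-element offsets converting computed magnetic shieldings to chemical
#' shifts via delta = offset - shielding. Defaults are 30.78 ppm for 1H and
#' 170.04 ppm for 13C.
#'
#' @slot offsets named numeric vector of per-element offsets in ppm.
#' @export
setClass("ShiftReferencing", representation(offsets = "numeric"))

setValidity("ShiftReferencing", function(object) {
  if (is.null(names(object@offsets)) || any(!nzchar(names(object@offsets))))
    return("offsets must be named by element symbol")
  if (any(!is.finite(object@offsets))) return("offsets must be finite")
  TRUE
})

#' @describeIn shieldingToShift construct a referencing object
#' @param offsets named numeric vector of per-element offsets (ppm).
#' @export
shiftReferencing <- function(offsets = c(H = 30.78, C = 170.04)) {
  new("ShiftReferencing", offsets = offsets)
}

setMethod("show", "ShiftReferencing", function(object) {
  cat("ShiftReferencing (delta = offset - shielding):\n")
  print(object@offsets)
})

# ---------------------------------------------------------------------------
# EnsembleSelection

#' Result of chemical-shift-probability ensemble selection
#'
#' Per-environment probabilities together with the selection rule (probability
#' threshold, or best top fraction) and the selected index set.
#'
#' @slot table data.frame with one row per environment: \code{trajectory},
#'   \code{frame}, \code{moleculeId}, \code{probability}, \code{selected}.
#' @slot threshold numeric probability cutoff (NA in top-fraction mode).
#' @slot topFraction numeric fraction (NA in threshold mode).
#' @slot mode "threshold" or "topFraction".
#' @export
setClass("EnsembleSelection", representation(
  table = "data.frame",
  threshold = "numeric",
  topFraction = "numeric",
  mode = "character"
))

setValidity("EnsembleSelection", function(object) {
  t <- object@table
  need <- c("trajectory", "frame", "moleculeId", "probability", "selected")
  if (!all(need %in% names(t)))
    return(paste("selection table needs columns:", paste(need, collapse = ", ")))
  if (any(t$probability < 0 | t$probability > 1, na.rm = TRUE))
    return("probabilities must lie in [0, 1]")
  if (object@mode == "threshold" &&
      !isTRUE(all.equal(t$selected, t$probability > object@threshold)))
    return("selected must equal probability > threshold")
  TRUE
})

#' @describeIn scoreEnvironments per-environment probability table
#' @param selection An \code{EnsembleSelection}.
#' @export
selectionTable <- function(selection) selection@table

#' @describeIn scoreEnvironments environment probabilities
#' @export
probabilities <- function(selection) selection@table$probability

#' @describeIn scoreEnvironments rows of the selected (NMR) ensemble
#' @export
selectedEnvironments <- function(selection) {
  selection@table[selection@table$selected, , drop = FALSE]
}

#' @describeIn scoreEnvironments fraction of environments selected
#' @export
selectedFraction <- function(selection) mean(selection@table$selected)

setMethod("show", "EnsembleSelection", function(object) {
  n <- nrow(object@table)
  k <- sum(object@table$selected)
  rule <- if (object@mode == "threshold")
    sprintf("p > %.3g", object@threshold)
  else sprintf("top %.3g%%", 100 * object@topFraction)
  cat(sprintf("EnsembleSelection: %d / %d environments selected (%.2f%%, %s)\n",
              k, n, 100 * k / max(n, 1L), rule))
})

# ---------------------------------------------------------------------------
# HBondCriteria / DensityMapSpec

#' Hydrogen-bond geometric criteria
#'
#' O-H...X motifs (X = O or N) count as hydrogen bonds when the H...X distance
#' is below \code{maxDistance} and the O-H-X angle exceeds \code{minAngle}.
#'
#' @slot maxDistance numeric, Angstrom (default 2.5).
#' @slot minAngle numeric, degrees (default 130).
#' @slot acceptorElements character (default c("O", "N")).
#' @export
setClass("HBondCriteria", representation(
  maxDistance = "numeric", minAngle = "numeric",
  acceptorElements = "character"
))

setValidity("HBondCriteria", function(object) {
  if (object@maxDistance <= 0) return("maxDistance must be positive")
  if (object@minAngle <= 0 || object@minAngle > 180)
    return("minAngle must lie in (0, 180]")
  TRUE
})

#' @describeIn detectHBond construct hydrogen-bond criteria
#' @param maxDistance maximal H...X distance in Angstrom.
#' @param minAngle minimal O-H-X angle in degrees.
#' @param acceptorElements acceptor element symbols.
#' @export
hbondCriteria <- function(maxDistance = 2.5, minAngle = 130,
                          acceptorElements = c("O", "N")) {
  new("HBondCriteria", maxDistance = maxDistance, minAngle = minAngle,
      acceptorElements = acceptorElements)
}

setMethod("show", "HBondCriteria", function(object) {
  cat(sprintf("HBondCriteria: H...X < %.2f A, O-H-X > %.0f deg, X in {%s}\n",
              object@maxDistance, object@minAngle,
              paste(object@acceptorElements, collapse = ", ")))
})

#' 3D atomic density map specification
#'
#' Cubic grid on which per-element atomic density maps are evaluated: by
#' default 31 points per side spanning a 12 Angstrom cube (0.4 Angstrom
#' spacing), unnormalized Gaussians of width 0.5 Angstrom at each atom.
#'
#' @slot gridPoints integer points per side (default 31).
#' @slot cubeSide numeric, Angstrom (default 12).
#' @slot sigma numeric Gaussian width, Angstrom (default 0.5).
#' @export
setClass("DensityMapSpec", representation(
  gridPoints = "integer", cubeSide = "numeric", sigma = "numeric"
))

setValidity("DensityMapSpec", function(object) {
  if (object@gridPoints < 2L) return("gridPoints must be at least 2")
  if (object@cubeSide <= 0) return("cubeSide must be positive")
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' @describeIn densityMap construct a density-map grid specification
#' @param gridPoints grid points per side.
#' @param cubeSide cube side length in Angstrom.
#' @param sigma Gaussian width in Angstrom.
#' @export
densityMapSpec <- function(gridPoints = 31L, cubeSide = 12, sigma = 0.5) {
  new("DensityMapSpec", gridPoints = as.integer(gridPoints),
      cubeSide = cubeSide, sigma = sigma)
}

#' @describeIn densityMap grid spacing in Angstrom implied by a spec
#' @param spec A \code{DensityMapSpec}.
#' @export
gridSpacing <- function(spec) spec@cubeSide / (spec@gridPoints - 1L)

setMethod("show", "DensityMapSpec", function(object) {
  cat(sprintf(
    "DensityMapSpec: %d^3 grid, %.1f A sides (spacing %.3g A), sigma %.2f A\n",
    object@gridPoints, object@cubeSide, gridSpacing(object), object@sigma))
})
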