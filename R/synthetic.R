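# Self-contained synthetic data: periodic amorphous packings of a toy
# flexible molecule with planted conformer and hydrogen-bond subpopulations,
# plus per-site "predicted" shifts with heteroscedastic uncertainties and
# matching "experimental" distributions. Ground truth travels alongside in a
# manifest so every downstream analysis can be validated against it.

#' Toy flexible molecule template
#'
#' A 13-atom molecule with one rotatable backbone bond (dihedral
#' O1-C1-C2-C3), a hydroxyl O1-H1 hydrogen-bond donor, a carbonyl oxygen O2
#' and an amine nitrogen N1 as acceptors: the minimal species realizing every
#' analysis in the package (conformer dihedrals, H-bond categories, density
#' maps, shift matching).
#'
#' @param backboneDihedral backbone torsion in degrees (conformer A: +60,
#'   conformer B: -60).
#' @param hydroxylDihedral hydroxyl torsion in degrees (default 180, pointing
#'   the proton away from the molecular body).
#' @return list with \code{atoms} (data.frame siteLabel, element, x, y, z)
#'   and \code{topology} (\linkS4class{MolecularTopology}).
#' @export
toyMoleculeTemplate <- function(backboneDihedral = 60,
                                hydroxylDihedral = 180) {
  C1 <- c(0, 0, 0)
  C2 <- c(1.52, 0, 0)
  O1 <- C1 + 1.43 * c(cos(.rad(109.5)), sin(.rad(109.5)), 0)
  C3 <- .placeAtom(O1, C1, C2, 1.50, 111.0, backboneDihedral)
  N1 <- .placeAtom(O1, C1, C2, 1.47, 109.5, backboneDihedral + 120)
  H4 <- .placeAtom(O1, C1, C2, 1.09, 109.5, backboneDihedral - 120)
  O2 <- .placeAtom(C1, C2, C3, 1.22, 122.0, 0)
  H5 <- .placeAtom(C1, C2, C3, 1.09, 118.0, 180)
  H1 <- .placeAtom(C2, C1, O1, 0.97, 107.0, hydroxylDihedral)
  H2 <- .placeAtom(C3, C2, C1, 1.09, 109.5, backboneDihedral + 120)
  H3 <- .placeAtom(C3, C2, C1, 1.09, 109.5, backboneDihedral - 120)
  H6 <- .placeAtom(C1, C2, N1, 1.01, 107.0, 60)
  H7 <- .placeAtom(C1, C2, N1, 1.01, 107.0, -60)
  coords <- rbind(O1 = O1, H1 = H1, C1 = C1, H2 = H2, H3 = H3, C2 = C2,
                  H4 = H4, N1 = N1, H6 = H6, H7 = H7, C3 = C3, H5 = H5,
                  O2 = O2)
  labels <- rownames(coords)
  elements <- stats::setNames(substr(labels, 1L, 1L), labels)
  atoms <- data.frame(siteLabel = labels, element = unname(elements),
                      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                      row.names = NULL)
  bonds <- rbind(c("O1", "H1"), c("O1", "C1"), c("C1", "H2"), c("C1", "H3"),
                 c("C1", "C2"), c("C2", "H4"), c("C2", "N1"), c("N1", "H6"),
                 c("N1", "H7"), c("C2", "C3"), c("C3", "H5"), c("C3", "O2"))
  topo <- molecularTopology(
    siteLabels = labels, elements = elements, bonds = bonds,
    dihedralDefs = list(hydroxyl = c("H1", "O1", "C1", "C2"),
                        backbone = c("O1", "C1", "C2", "C3")),
    hbondDonor = c("O1", "H1"),
    hbondAcceptors = data.frame(siteLabel = c("O2", "N1"),
                                element = c("O", "N")))
  list(atoms = atoms, topology = topo)
}

#' @describeIn toyMoleculeTemplate the two planted conformer classes
#'   (backbone torsion +60 / -60 degrees).
#' @export
toyConformers <- function() {
  list(A = toyMoleculeTemplate(60), B = toyMoleculeTemplate(-60))
}

#' Rigid bent triatomic template
#'
#' A water-like 3-atom rigid molecule, used for large-scale environment
#' bookkeeping where only molecule positions matter.
#'
#' @return template list as in \code{\link{toyMoleculeTemplate}}.
#' @export
triatomicTemplate <- function() {
  atoms <- data.frame(
    siteLabel = c("O1", "H1", "H2"), element = c("O", "H", "H"),
    x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0))
  topo <- molecularTopology(
    siteLabels = atoms$siteLabel,
    elements = stats::setNames(atoms$element, atoms$siteLabel),
    bonds = rbind(c("O1", "H1"), c("O1", "H2")))
  list(atoms = atoms, topology = topo)
}

## C2-symmetric hydrogen-bonded dimer of one molecule: a 180-degree rotation
## about an axis through the midpoint of the acceptor and the ideal acceptor
## position X = H + dHb * (H - O)/|H - O|, perpendicular to their connecting
## line. By the involution symmetry, A-donor->B-acceptor and
## B-donor->A-acceptor geometries are identical, so both molecules are
## hydrogen-bonded. The free axis angle is chosen to maximize the smallest
## non-planted interatomic contact.
.buildHBondDimer <- function(template, acceptorLabel, dHb = 1.9,
                             nCandidates = 24L) {
  a <- template$atoms
  P <- as.matrix(a[, c("x", "y", "z")])
  donor <- template$topology@hbondDonor
  o <- P[match(donor[1L], a$siteLabel), ]
  h <- P[match(donor[2L], a$siteLabel), ]
  iAcc <- match(acceptorLabel, a$siteLabel)
  iH <- match(donor[2L], a$siteLabel)
  xAcc <- P[iAcc, ]
  u0 <- (h - o) / .norm3(h - o)
  t1 <- .cross3(u0, c(1, 0, 0))
  if (.norm3(t1) < 1e-6) t1 <- .cross3(u0, c(0, 1, 0))
  t1 <- t1 / .norm3(t1)
  t2 <- .cross3(u0, t1)
  best <- NULL
  bestScore <- -Inf
  ## the acceptor target X may tilt off the O-H axis (O-H-X angle stays
  ## >= 140 degrees, inside the 130-degree criterion with margin); the
  ## remaining freedom is the C2 axis angle in the bisecting plane
  for (tilt in .rad(c(0, 20, 40))) {
    for (az in seq(0, 2 * pi, length.out = 9L)[-9L]) {
      dirX <- cos(tilt) * u0 + sin(tilt) * (cos(az) * t1 + sin(az) * t2)
      X <- h + dHb * dirX
      mid <- (xAcc + X) / 2
      w <- xAcc - mid
      if (.norm3(w) < 1e-8) next
      wn <- w / .norm3(w)
      e1 <- .cross3(wn, c(1, 0, 0))
      if (.norm3(e1) < 1e-6) e1 <- .cross3(wn, c(0, 1, 0))
      e1 <- e1 / .norm3(e1)
      e2 <- .cross3(wn, e1)
      for (th in seq(0, 2 * pi, length.out = nCandidates + 1L)[-1L]) {
        u <- cos(th) * e1 + sin(th) * e2
        V <- sweep(P, 2L, mid)
        B <- sweep(2 * (V %*% u) %*% t(u) - V, 2L, mid, "+")
        d <- .crossDist(P, B)
        d[iH, iAcc] <- Inf   # the two planted contacts
        d[iAcc, iH] <- Inf
        score <- min(d)
        if (score > bestScore) {
          bestScore <- score
          best <- B
        }
      }
      if (bestScore >= 1.8) break
    }
    if (bestScore >= 1.8) break
  }
  if (bestScore < 1.4)
    stop("could not build a clash-free hydrogen-bonded dimer")
  bAtoms <- a
  bAtoms$x <- best[, 1L]
  bAtoms$y <- best[, 2L]
  bAtoms$z <- best[, 3L]
  bAtoms
}

#' Random amorphous periodic packing with planted subpopulations
#'
#' Inserts molecules at random positions and orientations into a cubic
#' periodic cell, rejecting insertions with any minimum-image interatomic
#' contact below \code{minDist}. Each molecule carries a planted conformer
#' class (sampled from \code{conformerFractions}). Hydrogen bonds are
#' planted with margin inside the detection criteria (H...X ~\code{dHb}
#' Angstrom on the O-H axis): carbonyl (O2) bonds as C2-symmetric dimers in
#' which both members donate and accept simultaneously, nitrogen (N1) bonds
#' by inserting a partner molecule whose nitrogen sits at the donor's ideal
#' acceptor position (the partner itself stays unbonded, so a planted
#' fraction of 1 requires an all-O2 acceptor split). Planted pairs are
#' exempt from the \code{minDist} rejection down to a 1.55 Angstrom floor.
#' Ground-truth labels are returned in a manifest.
#'
#' @param nMolecules number of molecules.
#' @param cellSide cubic cell side in Angstrom.
#' @param molecule a template (list(atoms, topology)) or a named list of
#'   conformer templates sharing one topology; default
#'   \code{\link{toyConformers}()}.
#' @param conformerFractions named sampling fractions over conformer classes.
#' @param hbondFraction fraction of molecules planted as hydrogen-bond
#'   donors (rounded to an even count; each dimer binds two molecules).
#' @param acceptorSplit named fractions over acceptor site labels for the
#'   planted dimers.
#' @param dHb planted H...X distance in Angstrom (default 1.9).
#' @param minDist insertion overlap rejection distance in Angstrom
#'   (default 2.0).
#' @param maxTries insertion retry budget per unit.
#' @param trajectoryId trajectory index recorded in the snapshot id.
#' @param seed optional RNG seed.
#' @return list with \code{snapshot} (\linkS4class{Snapshot}) and
#'   \code{manifest} (data.frame: moleculeId, conformerClass, hbondClass,
#'   partnerMoleculeId).
#' @export
generatePacking <- function(nMolecules = 32L, cellSide = 24,
                            molecule = toyConformers(),
                            conformerFractions = c(A = 0.5, B = 0.5),
                            hbondFraction = 0, acceptorSplit = c(O2 = 0.5,
                                                                N1 = 0.5),
                            dHb = 1.9, minDist = 2.0, maxTries = 2000L,
                            trajectoryId = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(molecule$atoms)) {
    molecule <- list(A = molecule)
    conformerFractions <- c(A = 1)
  }
  topo <- molecule[[1L]]$topology
  classes <- names(molecule)
  conformerFractions <- conformerFractions[classes]
  cell <- periodicCell(cellSide)
  L <- cell@lattice

  nBonded <- round(hbondFraction * nMolecules)
  splitO2 <- if ("O2" %in% names(acceptorSplit))
    acceptorSplit[["O2"]] / sum(acceptorSplit) else 0
  nDimers <- round(nBonded * splitO2 / 2)
  nN1 <- nBonded - 2L * nDimers
  ## each N1 planting consumes a donor plus an unbonded partner
  while (2L * nDimers + 2L * nN1 > nMolecules) {
    if (nN1 > 0L) nN1 <- nN1 - 1L else nDimers <- nDimers - 1L
  }
  nSingles <- nMolecules - 2L * nDimers - 2L * nN1

  hasDonor <- length(topo@hbondDonor) == 2L
  if ((nDimers > 0L || nN1 > 0L) && !hasDonor)
    stop("molecule template declares no hydrogen-bond donor")

  nUnits <- nDimers + nN1 + nSingles
  unitClasses <- sample(classes, nUnits + nN1, replace = TRUE,
                        prob = conformerFractions)

  placedFrac <- NULL
  pairFloor <- 1.55  # floor for contacts within a planted pair
  atomRows <- list()
  manifest <- list()
  molId <- 0L

  insertUnit <- function(baseCoords) {
    ## returns rotated+translated coordinates or NULL on failure
    for (try in seq_len(maxTries)) {
      R <- .randomRotation()
      t <- drop(stats::runif(3L) %*% L)
      cand <- t(R %*% t(baseCoords)) +
        matrix(t, nrow(baseCoords), 3L, byrow = TRUE)
      if (is.null(placedFrac)) return(cand)
      fr <- .cartToFrac(L, cand)
      d <- .pairDistances(L, fr, placedFrac)
      if (min(d) >= minDist) return(cand)
    }
    NULL
  }

  ## place `partnerTmpl` with its acceptor atom at the donor's ideal
  ## acceptor position of the already-placed molecule `aCoords`
  insertPartner <- function(aCoords, aLabels, partnerTmpl, acceptorLabel) {
    o <- aCoords[match(topo@hbondDonor[1L], aLabels), ]
    h <- aCoords[match(topo@hbondDonor[2L], aLabels), ]
    u0 <- (h - o) / .norm3(h - o)
    t1 <- .cross3(u0, c(1, 0, 0))
    if (.norm3(t1) < 1e-6) t1 <- .cross3(u0, c(0, 1, 0))
    t1 <- t1 / .norm3(t1)
    t2 <- .cross3(u0, t1)
    P <- as.matrix(partnerTmpl$atoms[, c("x", "y", "z")])
    iAcc <- match(acceptorLabel, partnerTmpl$atoms$siteLabel)
    placedFrac <- rbind(placedFrac, .cartToFrac(L, aCoords))
    aIdxInPlaced <- nrow(placedFrac) - nrow(aCoords) + seq_len(nrow(aCoords))
    for (try in seq_len(max(maxTries %/% 10L, 50L))) {
      tilt <- .rad(stats::runif(1L, 0, 30))
      az <- stats::runif(1L, 0, 2 * pi)
      dirX <- cos(tilt) * u0 + sin(tilt) * (cos(az) * t1 + sin(az) * t2)
      X <- h + dHb * dirX
      R <- .randomRotation()
      cand <- t(R %*% t(sweep(P, 2L, P[iAcc, ]))) +
        matrix(X, nrow(P), 3L, byrow = TRUE)
      fr <- .cartToFrac(L, cand)
      d <- .pairDistances(L, fr, placedFrac)
      dPair <- d[, aIdxInPlaced, drop = FALSE]
      dOther <- d[, -aIdxInPlaced, drop = FALSE]
      hCol <- match(topo@hbondDonor[2L], aLabels)
      ## the planted acceptor must stay the donor's nearest candidate
      okNearest <- min(dPair[-iAcc, hCol]) >= minDist
      dPair[iAcc, hCol] <- Inf  # planted contact
      okOther <- !ncol(dOther) || min(dOther) >= minDist
      if (min(dPair) >= pairFloor && okOther && okNearest) return(cand)
    }
    NULL
  }

  addAtoms <- function(atomsDf, coords, ids) {
    k <- length(unique(atomsDf$siteLabel))
    for (j in seq_along(ids)) {
      rows <- ((j - 1L) * k + 1L):(j * k)
      atomRows[[length(atomRows) + 1L]] <<- data.frame(
        element = atomsDf$element[rows], x = coords[rows, 1L],
        y = coords[rows, 2L], z = coords[rows, 3L],
        siteLabel = atomsDf$siteLabel[rows], moleculeId = ids[j])
    }
    placedFrac <<- rbind(placedFrac, .cartToFrac(L, coords))
  }

  fail <- function() stop("insertion failed after ", maxTries,
                          " tries: packing density too high")
  uIdx <- 0L
  for (di in seq_len(nDimers)) {
    uIdx <- uIdx + 1L
    cls <- unitClasses[uIdx]
    tmplA <- molecule[[cls]]
    atomsB <- .buildHBondDimer(tmplA, "O2", dHb = dHb)
    base <- rbind(as.matrix(tmplA$atoms[, c("x", "y", "z")]),
                  as.matrix(atomsB[, c("x", "y", "z")]))
    coords <- insertUnit(base)
    if (is.null(coords)) fail()
    ids <- c(molId + 1L, molId + 2L)
    molId <- molId + 2L
    addAtoms(rbind(tmplA$atoms, atomsB), coords, ids)
    manifest[[length(manifest) + 1L]] <- data.frame(
      moleculeId = ids, conformerClass = cls, hbondClass = "O2",
      partnerMoleculeId = rev(ids))
  }
  for (ni in seq_len(nN1)) {
    uIdx <- uIdx + 1L
    cls <- unitClasses[uIdx]
    tmplA <- molecule[[cls]]
    clsB <- unitClasses[nUnits + ni]
    tmplB <- molecule[[clsB]]
    ## donor + partner placed atomically: a donor whose O-H axis points
    ## into an occupied region is rolled back and re-inserted elsewhere
    aCoords <- bCoords <- NULL
    for (pairTry in seq_len(50L)) {
      aCoords <- insertUnit(as.matrix(tmplA$atoms[, c("x", "y", "z")]))
      if (is.null(aCoords)) fail()
      bCoords <- insertPartner(aCoords, tmplA$atoms$siteLabel, tmplB, "N1")
      if (!is.null(bCoords)) break
    }
    if (is.null(bCoords)) fail()
    idA <- molId + 1L
    molId <- molId + 1L
    addAtoms(tmplA$atoms, aCoords, idA)
    idB <- molId + 1L
    molId <- molId + 1L
    addAtoms(tmplB$atoms, bCoords, idB)
    manifest[[length(manifest) + 1L]] <- data.frame(
      moleculeId = c(idA, idB), conformerClass = c(cls, clsB),
      hbondClass = c("N1", "none"),
      partnerMoleculeId = c(idB, NA_integer_))
  }
  for (si in seq_len(nSingles)) {
    uIdx <- uIdx + 1L
    cls <- unitClasses[uIdx]
    tmpl <- molecule[[cls]]
    coords <- insertUnit(as.matrix(tmpl$atoms[, c("x", "y", "z")]))
    if (is.null(coords)) fail()
    molId <- molId + 1L
    addAtoms(tmpl$atoms, coords, molId)
    manifest[[length(manifest) + 1L]] <- data.frame(
      moleculeId = molId, conformerClass = cls, hbondClass = "none",
      partnerMoleculeId = NA_integer_)
  }

  atomsAll <- do.call(rbind, atomRows)
  atomsAll$atomId <- seq_len(nrow(atomsAll))
  man <- do.call(rbind, manifest)
  man <- man[order(man$moleculeId), ]
  rownames(man) <- NULL
  list(snapshot = snapshot(cell, atomsAll, topo,
                           c(as.integer(trajectoryId), 1L)),
       manifest = man)
}

#' Jittered trajectory frames from a base packing
#'
#' Emulates MD snapshot cadence by adding independent Gaussian displacements
#' (sd \code{jitterSd}) to the base packing's coordinates in every frame; the
#' planted conformers and hydrogen bonds persist (the jitter is far smaller
#' than the detection tolerances).
#'
#' @param packing output of \code{\link{generatePacking}}.
#' @param nFrames number of frames.
#' @param jitterSd per-coordinate displacement sd in Angstrom (default 0.05).
#' @param seed optional RNG seed.
#' @return list with \code{snapshots} (list of \linkS4class{Snapshot}) and
#'   \code{manifest} (one row per frame and molecule: trajectory, frame,
#'   moleculeId, conformerClass, hbondClass, partnerMoleculeId).
#' @export
generateTrajectory <- function(packing, nFrames, jitterSd = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- packing$snapshot
  n <- nrow(base@atoms)
  snaps <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    a <- base@atoms
    a$x <- a$x + stats::rnorm(n, sd = jitterSd)
    a$y <- a$y + stats::rnorm(n, sd = jitterSd)
    a$z <- a$z + stats::rnorm(n, sd = jitterSd)
    snaps[[f]] <- snapshot(base@cell, a, base@topology,
                           c(base@snapshotId[1L], f))
  }
  perFrame <- do.call(rbind, lapply(seq_len(nFrames), function(f) {
    m <- packing$manifest
    m$trajectory <- base@snapshotId[1L]
    m$frame <- f
    m
  }))
  cols <- c("trajectory", "frame", "moleculeId", "conformerClass",
            "hbondClass", "partnerMoleculeId")
  list(snapshots = snaps, manifest = perFrame[, cols])
}

#' Full synthetic ensemble: several jittered trajectories
#'
#' Default study conditions: 2 trajectories x 25 frames x 32 molecules
#' (1600 environments) in a 24 Angstrom cubic cell.
#'
#' @inheritParams generatePacking
#' @param nTrajectories number of independent packings.
#' @param nFramesPerTrajectory frames per trajectory.
#' @param jitterSd frame jitter sd in Angstrom.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list with \code{snapshots}, \code{manifest}, \code{topology}.
#' @export
generateEnsemble <- function(nTrajectories = 2L, nFramesPerTrajectory = 25L,
                             nMolecules = 32L, cellSide = 24,
                             molecule = toyConformers(),
                             conformerFractions = c(A = 0.5, B = 0.5),
                             hbondFraction = 0.3,
                             acceptorSplit = c(O2 = 0.5, N1 = 0.5),
                             jitterSd = 0.05, seed = 1L) {
  snaps <- list()
  mans <- list()
  for (tr in seq_len(nTrajectories)) {
    pk <- generatePacking(nMolecules, cellSide, molecule,
                          conformerFractions, hbondFraction, acceptorSplit,
                          trajectoryId = tr,
                          seed = .deriveSeed(seed, 2L * tr))
    trj <- generateTrajectory(pk, nFramesPerTrajectory, jitterSd,
                              seed = .deriveSeed(seed, 2L * tr + 1L))
    snaps <- c(snaps, trj$snapshots)
    mans[[tr]] <- trj$manifest
  }
  topo <- if (!is.null(molecule$atoms)) molecule$topology
  else molecule[[1L]]$topology
  list(snapshots = snaps, manifest = do.call(rbind, mans), topology = topo)
}

# ---------------------------------------------------------------------------
# Synthetic shift predictions and experimental distributions

#' Toy structure-dependent chemical-shift model
#'
#' Per-site base means with experimental widths in the ranges typical of
#' amorphous organic solids (13C: 2-6 ppm, C-H protons: 0.6-1 ppm, the OH
#' proton: 1.8 ppm). Conformer class B displaces a subset of sites by
#' \code{separation} joint standard deviations (joint sd = sqrt(expWidth^2 +
#' typical prediction uncertainty^2)); hydrogen bonding deshields the OH
#' proton, more strongly for the nitrogen acceptor. Prediction noise is
#' Gaussian with sd \code{noiseFactor} x expWidth; prediction uncertainties
#' are log-normal with median \code{uncFactor} x expWidth (sdlog 0.4), so
#' the first-quartile uncertainty cap is genuinely exercised.
#'
#' @param separation class separation in joint-sigma units (default 3.5).
#' @param noiseFactor prediction-noise scale relative to the experimental
#'   width (default 0.3).
#' @param uncFactor median prediction uncertainty relative to the
#'   experimental width (default 0.5).
#' @return a shift-model list consumed by \code{\link{generateShifts}}.
#' @export
toyShiftModel <- function(separation = 3.5, noiseFactor = 0.3,
                          uncFactor = 0.5) {
  sites <- data.frame(
    siteLabel = c("H1", "H2", "H3", "H4", "H5", "H6", "H7",
                  "C1", "C2", "C3"),
    element = c(rep("H", 7L), rep("C", 3L)),
    centerPpm = c(5.0, 3.6, 3.7, 2.1, 6.5, 1.5, 1.6, 62, 55, 198),
    widthPpm = c(1.8, 0.8, 0.9, 0.7, 1.0, 0.6, 0.6, 2, 4, 6))
  joint <- sites$widthPpm * sqrt(1 + uncFactor^2)
  shifted <- c("H1", "H4", "H5", "C1", "C2", "C3")
  offB <- stats::setNames(rep(0, nrow(sites)), sites$siteLabel)
  offB[shifted] <- separation * joint[match(shifted, sites$siteLabel)]
  list(sites = sites,
       conformerOffsets = list(A = offB * 0, B = offB),
       hbondOffsets = list(none = offB * 0,
                           O2 = stats::setNames(
                             c(2, rep(0, 9L)), sites$siteLabel),
                           N1 = stats::setNames(
                             c(3, rep(0, 9L)), sites$siteLabel)),
       noiseSd = stats::setNames(noiseFactor * sites$widthPpm,
                                 sites$siteLabel),
       uncMedian = stats::setNames(uncFactor * sites$widthPpm,
                                   sites$siteLabel),
       uncSdLog = 0.4)
}

#' Synthetic per-site shift predictions and experimental distributions
#'
#' For every environment in the manifest and every site of the shift model,
#' draws predicted shift = class mean + Gaussian noise and a log-normal
#' prediction uncertainty. The "experimental" distributions are the class-A,
#' non-hydrogen-bonded means with the model's experimental widths, so
#' class-A environments are the planted ground truth the selection should
#' recover.
#'
#' @param manifest data.frame with columns \code{trajectory}, \code{frame},
#'   \code{moleculeId}, \code{conformerClass}, \code{hbondClass} (from the
#'   generators, or constructed directly).
#' @param model a shift model from \code{\link{toyShiftModel}}.
#' @param noiseScale multiplier on the model's prediction-noise sd (0 gives
#'   noise-free class means).
#' @param seed optional RNG seed.
#' @return list with \code{predictions} and \code{distributions} data.frames
#'   in the \code{\link{scoreEnvironments}} schema.
#' @export
generateShifts <- function(manifest, model = toyShiftModel(),
                           noiseScale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("trajectory", "frame", "moleculeId", "conformerClass",
            "hbondClass")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  badC <- setdiff(unique(manifest$conformerClass),
                  names(model$conformerOffsets))
  badH <- setdiff(unique(manifest$hbondClass), names(model$hbondOffsets))
  if (length(badC) || length(badH))
    stop("class label(s) unknown to the shift model: ",
         paste(c(badC, badH), collapse = ", "))
  sites <- model$sites
  nEnv <- nrow(manifest)
  nSite <- nrow(sites)
  idx <- rep(seq_len(nEnv), each = nSite)
  sidx <- rep(seq_len(nSite), times = nEnv)
  lbl <- sites$siteLabel[sidx]
  confMat <- do.call(cbind, model$conformerOffsets)
  hbMat <- do.call(cbind, model$hbondOffsets)
  confOff <- confMat[cbind(match(lbl, rownames(confMat)),
                           match(manifest$conformerClass[idx],
                                 colnames(confMat)))]
  hbOff <- hbMat[cbind(match(lbl, rownames(hbMat)),
                       match(manifest$hbondClass[idx], colnames(hbMat)))]
  mean. <- sites$centerPpm[sidx] + confOff + hbOff
  noise <- stats::rnorm(length(mean.),
                        sd = noiseScale * model$noiseSd[lbl])
  unc <- stats::rlnorm(length(mean.),
                       meanlog = log(model$uncMedian[lbl]),
                       sdlog = model$uncSdLog)
  predictions <- data.frame(
    trajectory = manifest$trajectory[idx], frame = manifest$frame[idx],
    moleculeId = manifest$moleculeId[idx], siteLabel = lbl,
    shiftPpm = mean. + noise, uncertaintyPpm = unc)
  distributions <- sites
  list(predictions = predictions, distributions = distributions)
}

#' Geometry-free planted manifest for scoring studies
#'
#' Convenience constructor of a manifest with a planted fraction of class-A
#' (ground truth) environments among class-B decoys, without generating
#' geometry; useful for large parameter-recovery studies of the scoring
#' machinery alone.
#'
#' @param nEnvironments number of environments.
#' @param plantedFraction fraction of class-A environments (default 0.2).
#' @param seed optional RNG seed.
#' @return manifest data.frame for \code{\link{generateShifts}}.
#' @export
plantedManifest <- function(nEnvironments, plantedFraction = 0.2,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nA <- round(plantedFraction * nEnvironments)
  cls <- sample(c(rep("A", nA), rep("B", nEnvironments - nA)))
  data.frame(trajectory = 1L, frame = seq_len(nEnvironments),
             moleculeId = 1L, conformerClass = cls, hbondClass = "none",
             partnerMoleculeId = NA_integer_)
}
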