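# Extraction of local molecular environments from periodic snapshots.

## Molecule-level contact adjacency of one snapshot: molecules i and j are
## adjacent when any atom pair is within `cutoff` under the minimum image.
## Returns a logical matrix indexed by sorted unique molecule id.
.moleculeContacts <- function(snap, cutoff) {
  a <- snap@atoms
  L <- snap@cell@lattice
  frac <- .cartToFrac(L, cbind(a$x, a$y, a$z))
  D <- .pairDistances(L, frac, frac)
  mols <- sort(unique(a$moleculeId))
  M <- matrix(0, nrow(a), length(mols))
  M[cbind(seq_len(nrow(a)), match(a$moleculeId, mols))] <- 1
  B <- (D <= cutoff + 1e-9) * 1  # closed inclusion, guarded against wrap round-off
  adj <- t(M) %*% B %*% M > 0
  dimnames(adj) <- list(mols, mols)
  adj
}

## Make one molecule contiguous: place every atom at its nearest image
## relative to the molecule's first atom.
.unwrapMolecule <- function(cell, coords) {
  anchor <- coords[1L, ]
  out <- coords
  for (i in seq_len(nrow(coords)))
    out[i, ] <- anchor + minimumImageVector(cell, anchor, coords[i, ])
  out
}

#' Extract the local molecular environment of one molecule
#'
#' The environment comprises the central molecule and every molecule having
#' at least one atom within \code{cutoff} (inclusive) of any central atom
#' under the minimum-image convention. Member coordinates are unwrapped: each
#' molecule is made contiguous and rigidly shifted to the periodic image
#' minimizing its closest contact with the central molecule.
#'
#' @param snap a \linkS4class{Snapshot}.
#' @param centralMoleculeId molecule id present in the snapshot.
#' @param cutoff contact cutoff in Angstrom (default 7).
#' @return A \linkS4class{LocalEnvironment}.
#' @export
extractEnvironment <- function(snap, centralMoleculeId, cutoff = 7.0) {
  a <- snap@atoms
  centralMoleculeId <- as.integer(centralMoleculeId)
  if (!centralMoleculeId %in% a$moleculeId)
    stop("unknown molecule id: ", centralMoleculeId)
  L <- snap@cell@lattice
  frac <- .cartToFrac(L, cbind(a$x, a$y, a$z))
  cIdx <- which(a$moleculeId == centralMoleculeId)
  D <- .pairDistances(L, frac[cIdx, , drop = FALSE], frac)
  contact <- apply(D <= cutoff + 1e-9, 2L, any)  # closed inclusion, guarded
  members <- sort(unique(a$moleculeId[contact]))
  members <- union(centralMoleculeId, members)

  keep <- a$moleculeId %in% members
  env <- a[keep, , drop = FALSE]
  coords <- cbind(env$x, env$y, env$z)

  ## unwrap the central molecule about its first atom
  ec <- which(env$moleculeId == centralMoleculeId)
  coords[ec, ] <- .unwrapMolecule(snap@cell, coords[ec, , drop = FALSE])
  centralCoords <- coords[ec, , drop = FALSE]

  ## place each member at the image minimizing its closest central contact
  for (m in setdiff(members, centralMoleculeId)) {
    em <- which(env$moleculeId == m)
    cm <- .unwrapMolecule(snap@cell, coords[em, , drop = FALSE])
    best <- NULL
    bestD <- Inf
    for (k in seq_len(nrow(.shifts27))) {
      shift <- drop(.shifts27[k, ] %*% L)
      cand <- sweep(cm, 2L, -shift)
      d <- min(.crossDist(cand, centralCoords))
      if (d < bestD) {
        bestD <- d
        best <- cand
      }
    }
    coords[em, ] <- best
  }

  env$x <- coords[, 1L]
  env$y <- coords[, 2L]
  env$z <- coords[, 3L]
  new("LocalEnvironment", atoms = env,
      centralMoleculeId = centralMoleculeId,
      memberMoleculeIds = as.integer(members),
      cutoff = cutoff, sourceId = snap@snapshotId)
}

## Plain Cartesian cross-distances (no periodicity), nA x nB
.crossDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Extract all local environments of a snapshot list
#'
#' Produces exactly one environment per molecule per snapshot, in
#' deterministic (trajectory, frame, molecule id) order. With
#' \code{detail = "membership"} only the membership bookkeeping is returned
#' (one row per environment with its member count), which scales to millions
#' of environments; \code{detail = "full"} returns the unwrapped
#' \linkS4class{LocalEnvironment} objects.
#'
#' @param snapshots list of \linkS4class{Snapshot} sharing one topology.
#' @param cutoff contact cutoff in Angstrom (default 7).
#' @param detail "full" or "membership".
#' @return list of \code{LocalEnvironment}, or a data.frame with columns
#'   \code{trajectory}, \code{frame}, \code{moleculeId}, \code{nMembers}.
#' @export
extractAllEnvironments <- function(snapshots, cutoff = 7.0,
                                   detail = c("full", "membership")) {
  detail <- match.arg(detail)
  if (!length(snapshots)) stop("no snapshots given")
  labs <- lapply(snapshots, function(s) sort(s@topology@siteLabels))
  if (!all(vapply(labs, identical, logical(1L), labs[[1L]])))
    stop("snapshots do not share a common topology")
  ord <- order(vapply(snapshots, function(s) s@snapshotId[1L], integer(1L)),
               vapply(snapshots, function(s) s@snapshotId[2L], integer(1L)))
  snapshots <- snapshots[ord]
  if (detail == "membership") {
    res <- lapply(snapshots, function(s) {
      adj <- .moleculeContacts(s, cutoff)
      mols <- sort(unique(s@atoms$moleculeId))
      data.frame(trajectory = s@snapshotId[1L], frame = s@snapshotId[2L],
                 moleculeId = mols, nMembers = colSums(adj))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    return(out)
  }
  envs <- list()
  for (s in snapshots) {
    mols <- sort(unique(s@atoms$moleculeId))
    for (m in mols)
      envs[[length(envs) + 1L]] <- extractEnvironment(s, m, cutoff)
  }
  envs
}
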