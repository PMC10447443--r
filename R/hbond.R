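# Hydrogen-bond detection and census over local molecular environments.

#' Detect the hydrogen bond of the central molecule's hydroxyl donor
#'
#' Scans all acceptor-element atoms of the environment (excluding the donor
#' oxygen itself) for O-H...X motifs satisfying the distance and angle
#' criteria; returns the qualifying acceptor with the shortest H...X distance
#' (ties broken by distance), or NULL when none qualifies.
#'
#' @param env a \linkS4class{LocalEnvironment} (unwrapped coordinates).
#' @param criteria a \linkS4class{HBondCriteria}.
#' @param topology the \linkS4class{MolecularTopology} naming the donor O-H
#'   pair.
#' @return list(siteLabel, moleculeId, distance, angle) or NULL.
#' @export
detectHBond <- function(env, topology, criteria = hbondCriteria()) {
  if (length(topology@hbondDonor) != 2L)
    stop("topology declares no hydrogen-bond donor")
  ca <- centralAtoms(env)
  oRow <- ca[ca$siteLabel == topology@hbondDonor[1L], , drop = FALSE]
  hRow <- ca[ca$siteLabel == topology@hbondDonor[2L], , drop = FALSE]
  if (nrow(oRow) != 1L || nrow(hRow) != 1L)
    stop("central molecule is missing the donor O-H pair")
  o <- c(oRow$x, oRow$y, oRow$z)
  h <- c(hRow$x, hRow$y, hRow$z)

  a <- env@atoms
  cand <- a[a$element %in% criteria@acceptorElements &
              a$atomId != oRow$atomId, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  X <- cbind(cand$x, cand$y, cand$z)
  dHX <- sqrt(rowSums(sweep(X, 2L, h)^2))
  ho <- o - h
  hx <- sweep(X, 2L, h, "-")
  cosA <- (hx %*% ho) / (dHX * .norm3(ho))
  angle <- .deg(acos(pmin(pmax(cosA, -1), 1)))

  ok <- dHX < criteria@maxDistance & angle > criteria@minAngle
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(dHX[ok])]
  list(siteLabel = cand$siteLabel[i], moleculeId = cand$moleculeId[i],
       distance = dHX[i], angle = as.numeric(angle[i]))
}

#' Hydrogen-bond acceptor census over an environment set
#'
#' Fraction of environments whose central hydroxyl donor is bonded to each
#' acceptor site label, plus a "none" category; the proportions sum to 1.
#' Categories cover every acceptor-element site of the topology (any O or N
#' of a neighbouring molecule can accept, including its hydroxyl oxygen).
#'
#' @param envs list of \linkS4class{LocalEnvironment}.
#' @param topology shared \linkS4class{MolecularTopology}.
#' @param criteria a \linkS4class{HBondCriteria}.
#' @return named numeric vector of proportions over the acceptor-element
#'   site labels plus "none".
#' @export
hbondCensus <- function(envs, topology, criteria = hbondCriteria()) {
  if (!length(envs)) stop("empty environment set")
  el <- topology@elements[topology@siteLabels]
  cats <- c(topology@siteLabels[el %in% criteria@acceptorElements], "none")
  hits <- vapply(envs, function(e) {
    hb <- detectHBond(e, topology, criteria)
    if (is.null(hb)) "none" else hb$siteLabel
  }, character(1L))
  counts <- table(factor(hits, levels = cats))
  counts / length(envs)
}
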