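# Radial distribution functions of periodic snapshots: element-pair partials
# by minimum-image histogramming, X-ray-like Z-weighted total G(r), and the
# Keen-style differential correlation function D(r) = 4 pi rho r (G(r) - 1).

.atomicNumbers <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                    O = 8, F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13,
                    Si = 14, P = 15, S = 16, Cl = 17, Ar = 18, K = 19,
                    Ca = 20, Br = 35, I = 53)

#' Radial distribution functions of periodic snapshots
#'
#' Histograms all minimum-image atom-pair distances per element pair and
#' normalizes to partial pair-distribution functions g_ij(r) (which tend to 1
#' at large r in a homogeneous system). The total G(r) combines the partials
#' with weights proportional to c_i c_j Z_i Z_j (an X-ray-like weighting,
#' normalized to sum 1 so G(r) -> 1), and D(r) = 4 pi rho r (G(r) - 1) with
#' rho the atomic number density.
#'
#' @param snapshots list of \linkS4class{Snapshot}.
#' @param rMax maximal distance in Angstrom; must not exceed half the
#'   shortest cell width.
#' @param dr bin width in Angstrom (default 0.05).
#' @param weighting "xray" (Z-weighted, default) or "uniform".
#' @return list with \code{r} (bin centers), \code{partials} (matrix, one
#'   column per element pair), \code{pairs}, \code{weights}, \code{G},
#'   \code{D}, \code{rho}.
#' @export
radialDistribution <- function(snapshots, rMax, dr = 0.05,
                               weighting = c("xray", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(snapshots)) stop("no snapshots given")
  L1 <- snapshots[[1L]]@cell@lattice
  ## perpendicular cell widths bound the exact minimum-image range
  widths <- vapply(1:3, function(k) {
    others <- setdiff(1:3, k)
    nvec <- .cross3(L1[others[1L], ], L1[others[2L], ])
    abs(sum(L1[k, ] * nvec)) / .norm3(nvec)
  }, numeric(1L))
  if (rMax > min(widths) / 2)
    stop(sprintf("rMax (%.2f A) exceeds half the shortest cell width (%.2f A)",
                 rMax, min(widths) / 2))

  breaks <- seq(0, rMax, by = dr)
  nb <- length(breaks) - 1L
  elems <- sort(unique(unlist(lapply(snapshots,
                                     function(s) unique(s@atoms$element)))))
  pairs <- expand.grid(i = elems, j = elems, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  pairNames <- paste(pairs$i, pairs$j, sep = "-")
  counts <- matrix(0, nb, nrow(pairs), dimnames = list(NULL, pairNames))

  nAtoms <- 0
  vol <- 0
  nElem <- stats::setNames(numeric(length(elems)), elems)
  for (s in snapshots) {
    a <- s@atoms
    L <- s@cell@lattice
    frac <- .cartToFrac(L, cbind(a$x, a$y, a$z))
    D <- .pairDistances(L, frac, frac)
    nAtoms <- nAtoms + nrow(a)
    vol <- vol + det(L)
    te <- table(a$element)
    nElem[names(te)] <- nElem[names(te)] + as.numeric(te)
    for (k in seq_len(nrow(pairs))) {
      ii <- which(a$element == pairs$i[k])
      jj <- which(a$element == pairs$j[k])
      d <- D[ii, jj, drop = FALSE]
      if (pairs$i[k] == pairs$j[k]) {
        d <- d[upper.tri(d)]
      } else {
        d <- as.vector(d)
      }
      d <- d[d > 1e-8 & d <= rMax]
      if (length(d))
        counts[, k] <- counts[, k] +
          tabulate(pmin(findInterval(d, breaks, left.open = TRUE), nb), nb)
    }
  }

  nSnap <- length(snapshots)
  vol <- vol / nSnap
  nElemSnap <- nElem / nSnap
  rMid <- (utils::head(breaks, -1L) + breaks[-1L]) / 2
  shell <- 4 * pi * rMid^2 * dr
  partials <- counts
  for (k in seq_len(nrow(pairs))) {
    ni <- nElemSnap[pairs$i[k]]
    nj <- nElemSnap[pairs$j[k]]
    nPairs <- if (pairs$i[k] == pairs$j[k]) ni * (ni - 1) / 2 else ni * nj
    ## ideal-gas expectation of pair counts in each shell, per snapshot
    ideal <- nPairs * shell / vol
    partials[, k] <- counts[, k] / (nSnap * ideal)
  }

  conc <- nElemSnap / sum(nElemSnap)
  zz <- if (weighting == "xray") {
    unknown <- setdiff(elems, names(.atomicNumbers))
    if (length(unknown))
      stop("no atomic number for element(s): ", paste(unknown, collapse = ", "))
    .atomicNumbers[elems]
  } else stats::setNames(rep(1, length(elems)), elems)
  w <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ci <- conc[pairs$i[k]]
    cj <- conc[pairs$j[k]]
    mult <- if (pairs$i[k] == pairs$j[k]) 1 else 2  # i-j and j-i
    w[k] <- mult * ci * cj * zz[pairs$i[k]] * zz[pairs$j[k]]
  }
  w <- w / sum(w)
  G <- drop(partials %*% w)
  rho <- sum(nElemSnap) / vol
  D. <- 4 * pi * rho * rMid * (G - 1)

  list(r = rMid, partials = partials, pairs = pairNames,
       weights = stats::setNames(w, pairNames), G = G, D = D., rho = rho)
}

#' Residual and RMSE between a simulated and a reference curve
#'
#' Linearly interpolates the simulated curve onto the reference grid and
#' reports the pointwise residual together with its root-mean-square over the
#' full overlapping range and over a sub-range (default 3-10 Angstrom).
#'
#' @param simulated,reference lists or data.frames with components \code{r}
#'   and \code{value} (for \code{\link{radialDistribution}} output pass e.g.
#'   \code{list(r = rdf$r, value = rdf$G)}).
#' @param subRange numeric(2) sub-range in Angstrom (default c(3, 10)).
#' @return list with \code{r}, \code{residual}, \code{rmse},
#'   \code{rmseSubRange}, \code{subRange}.
#' @export
curveResidual <- function(simulated, reference, subRange = c(3, 10)) {
  rs <- range(simulated$r)
  keep <- reference$r >= rs[1L] & reference$r <= rs[2L]
  if (!any(keep)) stop("curves have disjoint r supports")
  r <- reference$r[keep]
  simInterp <- stats::approx(simulated$r, simulated$value, xout = r)$y
  resid <- simInterp - reference$value[keep]
  inSub <- r >= subRange[1L] & r <= subRange[2L]
  list(r = r, residual = resid,
       rmse = sqrt(mean(resid^2)),
       rmseSubRange = if (any(inSub)) sqrt(mean(resid[inSub]^2)) else NA_real_,
       subRange = subRange)
}
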