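# Least-RMSD rigid superposition of environments on chosen central-molecule
# atoms (Kabsch algorithm), preparing them for 3D atomic density maps.

## Kabsch: proper rotation R and translation t minimizing RMSD of R P + t
## onto Q (rows are points). Returns list(R, t, rmsd).
.kabsch <- function(P, Q) {
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  P0 <- sweep(P, 2L, cP)
  Q0 <- sweep(Q, 2L, cQ)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cQ - drop(R %*% cP)
  fitted <- t(R %*% t(P)) + matrix(t, nrow(P), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Align environments by least-RMSD superposition of chosen atoms
#'
#' Rigidly superposes every environment onto the first (the reference) using
#' only the named alignment atoms of the central molecule; the proper
#' rotation and translation minimize the RMSD over those atoms (Kabsch), and
#' the transformation is applied to all atoms of the environment.
#'
#' @param envs list of \linkS4class{LocalEnvironment}.
#' @param alignmentSiteLabels at least three site labels of non-collinear
#'   central-molecule atoms present in every environment.
#' @return list with \code{envs} (aligned copies), \code{rmsd} (per
#'   environment, 0 for the reference), and \code{center} (centroid of the
#'   reference alignment atoms, the natural density-map center).
#' @export
alignEnvironments <- function(envs, alignmentSiteLabels) {
  if (!length(envs)) stop("empty environment set")
  if (length(alignmentSiteLabels) < 3L)
    stop("need at least three alignment atoms (superposition is ",
         "under-determined otherwise)")
  alignCoords <- function(env) {
    ca <- centralAtoms(env)
    m <- match(alignmentSiteLabels, ca$siteLabel)
    if (any(is.na(m)))
      stop("environment lacks alignment site(s): ",
           paste(alignmentSiteLabels[is.na(m)], collapse = ", "))
    cbind(ca$x[m], ca$y[m], ca$z[m])
  }
  ref <- alignCoords(envs[[1L]])
  ref0 <- sweep(ref, 2L, colMeans(ref))
  if (svd(ref0)$d[2L] < 1e-8)
    stop("alignment atoms are collinear or degenerate")
  rmsd <- numeric(length(envs))
  out <- envs
  for (i in seq_along(envs)) {
    P <- alignCoords(envs[[i]])
    fit <- .kabsch(P, ref)
    rmsd[i] <- fit$rmsd
    a <- envs[[i]]@atoms
    xyz <- t(fit$R %*% t(cbind(a$x, a$y, a$z))) +
      matrix(fit$t, nrow(a), 3L, byrow = TRUE)
    a$x <- xyz[, 1L]
    a$y <- xyz[, 2L]
    a$z <- xyz[, 3L]
    e <- envs[[i]]
    e@atoms <- a
    out[[i]] <- e
  }
  list(envs = out, rmsd = rmsd, center = colMeans(ref))
}
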