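# Dihedral conformer populations of environment sets.

#' Dihedral angle of a named topology dihedral in one environment
#'
#' @param env a \linkS4class{LocalEnvironment}.
#' @param topology the shared \linkS4class{MolecularTopology}.
#' @param name a name in \code{dihedralDefs(topology)}.
#' @return signed angle in degrees in (-180, 180], measured on the central
#'   molecule.
#' @export
environmentDihedral <- function(env, topology, name) {
  defs <- topology@dihedralDefs
  if (!name %in% names(defs))
    stop("undefined dihedral: ", name)
  ca <- centralAtoms(env)
  pts <- lapply(defs[[name]], function(lbl) {
    r <- ca[ca$siteLabel == lbl, , drop = FALSE]
    if (nrow(r) != 1L) stop("site ", lbl, " not unique in central molecule")
    c(r$x, r$y, r$z)
  })
  dihedralAngle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}

#' Histogram of a named dihedral over an environment set
#'
#' Counts over a fixed binning of (-180, 180]; angles are wrapped so the
#' periodic boundary at +/-180 degrees is handled consistently (an angle of
#' exactly -180 is reported as +180).
#'
#' @param envs list of \linkS4class{LocalEnvironment}.
#' @param topology shared \linkS4class{MolecularTopology}.
#' @param name dihedral name declared in the topology.
#' @param binWidth bin width in degrees (must divide 360; default 10).
#' @return data.frame with columns \code{lower}, \code{upper}, \code{mid},
#'   \code{count}, \code{density}, plus attribute \code{angles} carrying the
#'   raw per-environment angles.
#' @export
dihedralHistogram <- function(envs, topology, name, binWidth = 10) {
  if (!length(envs)) stop("empty environment set")
  if (360 %% binWidth != 0) stop("binWidth must divide 360")
  ang <- vapply(envs, environmentDihedral, numeric(1L),
                topology = topology, name = name)
  ang <- ifelse(ang <= -180, ang + 360, ang)
  breaks <- seq(-180, 180, by = binWidth)
  ## right-closed bins match the (-180, 180] convention
  counts <- table(cut(ang, breaks = breaks, right = TRUE,
                      include.lowest = FALSE))
  out <- data.frame(lower = utils::head(breaks, -1L),
                    upper = breaks[-1L])
  out$mid <- (out$lower + out$upper) / 2
  out$count <- as.integer(counts)
  out$density <- out$count / (sum(out$count) * binWidth)
  attr(out, "angles") <- ang
  out
}
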