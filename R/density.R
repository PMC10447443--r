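# Per-element 3D atomic density maps of aligned environment sets: the mean
# over environments of unnormalized Gaussians placed at atom positions, so a
# value of 1 at a grid node means an atom of the element sits there in every
# environment.

#' Per-element 3D atomic density map
#'
#' Evaluates, at every node of a cubic grid centered on \code{center},
#' (1/N_env) * sum over environments of sum over atoms of the element of
#' exp(-|r - r_a|^2 / (2 sigma^2)). Gaussians are unnormalized. The default
#' grid is 31 points per side over a 12 Angstrom cube (0.4 Angstrom spacing)
#' with sigma = 0.5 Angstrom.
#'
#' @param envs non-empty list of aligned \linkS4class{LocalEnvironment}
#'   (see \code{\link{alignEnvironments}}).
#' @param element element symbol to map.
#' @param center numeric(3) grid center, typically the alignment centroid.
#' @param spec a \linkS4class{DensityMapSpec}.
#' @return 3D numeric array (x, y, z) with attributes \code{axes} (node
#'   coordinates per axis), \code{center}, \code{element} and \code{spec}.
#' @export
densityMap <- function(envs, element, center = c(0, 0, 0),
                       spec = densityMapSpec()) {
  if (!length(envs)) stop("empty environment set")
  n <- spec@gridPoints
  half <- spec@cubeSide / 2
  ax <- seq(-half, half, length.out = n)
  gx <- center[1L] + ax
  gy <- center[2L] + ax
  gz <- center[3L] + ax
  s2 <- 2 * spec@sigma^2
  acc <- array(0, dim = c(n, n, n))
  for (env in envs) {
    a <- env@atoms
    a <- a[a$element == element, , drop = FALSE]
    if (!nrow(a)) next
    for (i in seq_len(nrow(a))) {
      ## separable Gaussian: outer product of per-axis factors
      fx <- exp(-(gx - a$x[i])^2 / s2)
      fy <- exp(-(gy - a$y[i])^2 / s2)
      fz <- exp(-(gz - a$z[i])^2 / s2)
      acc <- acc + outer(outer(fx, fy), fz)
    }
  }
  acc <- acc / length(envs)
  attr(acc, "axes") <- list(x = gx, y = gy, z = gz)
  attr(acc, "center") <- center
  attr(acc, "element") <- element
  attr(acc, "spec") <- spec
  acc
}

#' Difference between two atomic density maps
#'
#' Pointwise selected-minus-reference difference of two maps evaluated on
#' identical grids; positive values mark density promoted by the selection.
#'
#' @param mapSelected,mapReference arrays from \code{\link{densityMap}} with
#'   identical grids.
#' @return 3D numeric array with the same grid attributes.
#' @export
densityDifferenceMap <- function(mapSelected, mapReference) {
  axS <- attr(mapSelected, "axes")
  axR <- attr(mapReference, "axes")
  if (!identical(dim(mapSelected), dim(mapReference)) ||
      !isTRUE(all.equal(axS, axR)))
    stop("density maps are on mismatched grids")
  out <- mapSelected - mapReference
  attributes(out) <- attributes(mapSelected)
  out
}
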