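# Formation-energy bookkeeping over environment sets with a pluggable
# single-point energy backend. The backend contract: deterministic total
# energy in kJ/mol for a given atom table; no hidden state.

#' Single-point energy of an atom configuration
#'
#' Generic implemented by energy backends. The atom table carries columns
#' \code{element}, \code{x}, \code{y}, \code{z}, \code{moleculeId};
#' coordinates are unwrapped Cartesian Angstrom and the configuration is
#' treated as a finite cluster.
#'
#' @param backend an \linkS4class{EnergyBackend}.
#' @param atoms atom data.frame.
#' @return total energy in kJ/mol.
#' @export
setGeneric("singlePointEnergy",
           function(backend, atoms) standardGeneric("singlePointEnergy"))

#' Energy backend interface
#'
#' Virtual parent of single-point energy backends; implementations provide a
#' \code{\link{singlePointEnergy}} method that is deterministic for fixed
#' input and returns kJ/mol.
#'
#' @export
setClass("EnergyBackend", representation("VIRTUAL"))

# ---------------------------------------------------------------------------
# Built-in toy pairwise backend (documented closed form)

#' Toy pairwise (Lennard-Jones-like) energy backend
#'
#' Total energy = sum over all atom pairs (intra- and intermolecular) of
#' epsilon * ((r0 / r)^12 - 2 (r0 / r)^6), a 12-6 well of depth epsilon at
#' distance r0. Additive over pairs by construction, so formation energies
#' have a closed form: the sum of pair terms involving central atoms.
#'
#' @slot epsilon well depth, kJ/mol.
#' @slot r0 minimum-energy distance, Angstrom.
#' @export
setClass("ToyPairwiseBackend", contains = "EnergyBackend",
         representation(epsilon = "numeric", r0 = "numeric"))

#' @describeIn ToyPairwiseBackend-class constructor
#' @param epsilon well depth in kJ/mol.
#' @param r0 minimum-energy distance in Angstrom.
#' @export
toyPairwiseBackend <- function(epsilon = 1, r0 = 3.4) {
  new("ToyPairwiseBackend", epsilon = epsilon, r0 = r0)
}

#' @describeIn ToyPairwiseBackend-class pair energy at distance r (kJ/mol)
#' @param backend a \code{ToyPairwiseBackend}.
#' @param r distances in Angstrom.
#' @export
pairEnergy <- function(backend, r) {
  s <- (backend@r0 / r)^6
  backend@epsilon * (s^2 - 2 * s)
}

setMethod("singlePointEnergy", "ToyPairwiseBackend", function(backend, atoms) {
  n <- nrow(atoms)
  if (n < 2L) return(0)
  d <- .crossDist(cbind(atoms$x, atoms$y, atoms$z),
                  cbind(atoms$x, atoms$y, atoms$z))
  d <- d[upper.tri(d)]
  sum(pairEnergy(backend, d))
})

setMethod("show", "ToyPairwiseBackend", function(object) {
  cat(sprintf("ToyPairwiseBackend: 12-6 well, epsilon %.3g kJ/mol, r0 %.2f A\n",
              object@epsilon, object@r0))
})

# ---------------------------------------------------------------------------
# External-command adapter

#' External-program energy backend
#'
#' Adapter handing structures to an external single-point program: the atom
#' table is written as extended XYZ to a temporary file, the command is run
#' with that path as its final argument, and the last line of standard output
#' is parsed as the energy in kJ/mol.
#'
#' @slot command path to the executable.
#' @slot args character vector of fixed arguments preceding the file path.
#' @export
setClass("ExternalCommandBackend", contains = "EnergyBackend",
         representation(command = "character", args = "character"))

#' @describeIn ExternalCommandBackend-class constructor
#' @param command executable to run.
#' @param args fixed arguments placed before the structure-file path.
#' @export
externalCommandBackend <- function(command, args = character(0)) {
  new("ExternalCommandBackend", command = command, args = args)
}

setMethod("singlePointEnergy", "ExternalCommandBackend",
          function(backend, atoms) {
  tmp <- tempfile(fileext = ".xyz")
  on.exit(unlink(tmp))
  if (is.null(atoms$siteLabel))
    atoms$siteLabel <- paste0(atoms$element, seq_len(nrow(atoms)))
  if (is.null(atoms$moleculeId)) atoms$moleculeId <- 1L
  if (is.null(atoms$atomId)) atoms$atomId <- seq_len(nrow(atoms))
  ## hand-off frame written directly: a finite cluster in a huge nominal cell
  lat <- paste(sprintf("%.1f", t(diag(rep(1e6, 3L)))), collapse = " ")
  writeLines(c(
    as.character(nrow(atoms)),
    sprintf('Lattice="%s" Properties=species:S:1:pos:R:3:site:S:1:mol_id:I:1:atom_id:I:1',
            lat),
    sprintf("%-2s %14.8f %14.8f %14.8f %-6s %6d %6d", atoms$element,
            atoms$x, atoms$y, atoms$z, atoms$siteLabel, atoms$moleculeId,
            atoms$atomId)), tmp)
  out <- system2(backend@command, c(backend@args, tmp), stdout = TRUE)
  val <- suppressWarnings(as.numeric(utils::tail(out, 1L)))
  if (is.na(val))
    stop("external backend produced no numeric energy (last line: '",
         utils::tail(out, 1L), "')")
  val
})

# ---------------------------------------------------------------------------
# Formation-energy bookkeeping

#' Formation energy of a local molecular environment
#'
#' Energy difference between the environment with and without its central
#' molecule, E(all members) - E(members minus central): the stabilization of
#' the central molecule by its surroundings, including both intermolecular
#' interaction and the central molecule's conformational (self) energy.
#'
#' @param env a \linkS4class{LocalEnvironment} (unwrapped coordinates).
#' @param backend an \linkS4class{EnergyBackend}.
#' @return formation energy in kJ/mol.
#' @export
formationEnergy <- function(env, backend) {
  a <- env@atoms
  rest <- a[a$moleculeId != env@centralMoleculeId, , drop = FALSE]
  eAll <- singlePointEnergy(backend, a)
  eRest <- if (nrow(rest)) singlePointEnergy(backend, rest) else 0
  eAll - eRest
}

#' Formation energies of an environment set, with optional file cache
#'
#' @param envs list of \linkS4class{LocalEnvironment}.
#' @param backend an \linkS4class{EnergyBackend}.
#' @param cacheFile optional path to a tab-separated cache keyed by
#'   "trajectory:frame:moleculeId"; existing entries are reused, new ones
#'   appended.
#' @return numeric vector of formation energies (kJ/mol), named by
#'   environment key.
#' @export
formationEnergies <- function(envs, backend, cacheFile = NULL) {
  keys <- vapply(envs, function(e)
    .envKey(e@sourceId[1L], e@sourceId[2L], e@centralMoleculeId),
    character(1L))
  cache <- if (!is.null(cacheFile) && file.exists(cacheFile)) {
    tab <- utils::read.table(cacheFile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stats::setNames(tab$energy, tab$key)
  } else stats::setNames(numeric(0), character(0))
  out <- stats::setNames(rep(NA_real_, length(envs)), keys)
  hit <- keys %in% names(cache)
  out[hit] <- cache[keys[hit]]
  for (i in which(!hit)) {
    out[i] <- tryCatch(formationEnergy(envs[[i]], backend),
                       error = function(e)
                         stop("energy backend failed for environment ",
                              keys[i], ": ", conditionMessage(e)))
  }
  if (!is.null(cacheFile) && any(!hit)) {
    tab <- data.frame(key = keys[!hit], energy = out[!hit])
    utils::write.table(tab, cacheFile, sep = "\t", row.names = FALSE,
                       col.names = !file.exists(cacheFile), append =
                         file.exists(cacheFile), quote = FALSE)
  }
  out
}

#' Relative formation energies and per-group statistics
#'
#' Centers the energies on the mean of a reference set (default: all) and
#' reports per-group means with standard errors (sample standard deviation /
#' sqrt(n)). The reference set has relative mean exactly 0 by construction.
#'
#' @param energies numeric vector of formation energies (kJ/mol).
#' @param groups optional factor/character of group labels per energy.
#' @param reference logical or integer index of the reference set (default:
#'   all energies).
#' @return list with \code{relative} (centered energies),
#'   \code{referenceMean}, and \code{groupStats} (data.frame: group, n, mean,
#'   se).
#' @export
relativeFormationEnergies <- function(energies, groups = NULL,
                                      reference = NULL) {
  if (!length(energies)) stop("no energies given")
  if (is.null(reference)) reference <- seq_along(energies)
  refE <- energies[reference]
  if (!length(refE)) stop("empty reference set")
  mu <- mean(refE)
  rel <- energies - mu
  stats <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (any(table(groups) == 0L)) stop("empty group")
    stats <- do.call(rbind, lapply(levels(groups), function(g) {
      v <- rel[groups == g]
      data.frame(group = g, n = length(v), mean = mean(v),
                 se = if (length(v) > 1L)
                   stats::sd(v) / sqrt(length(v)) else 0)
    }))
  }
  list(relative = rel, referenceMean = mu, groupStats = stats)
}
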