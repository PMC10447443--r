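# Probabilistic matching of predicted chemical shifts against experimental
# shift distributions, and selection of the best-matching "NMR ensemble".
#
# For one atomic site, the experimental distribution is a Gaussian
# (centerPpm, widthPpm) and the prediction a Gaussian (shiftPpm,
# uncertaintyPpm). The site probability is the two-tailed p-value of the
# Z-score between the two Gaussians, divided by the prediction uncertainty in
# units of the site's first-quartile uncertainty (capped below at 1). Site
# probabilities combine into an environment probability as a geometric mean.

#' Z-score between an experimental shift distribution and a prediction
#'
#' @param deltaExp experimental center (ppm).
#' @param sigmaExp experimental width (ppm), > 0.
#' @param deltaPred predicted shift (ppm).
#' @param sigmaPred prediction uncertainty (ppm), > 0.
#' @return non-negative Z, |deltaExp - deltaPred| / sqrt(sigmaExp^2 +
#'   sigmaPred^2). All arguments are vectorized.
#' @export
zScore <- function(deltaExp, sigmaExp, deltaPred, sigmaPred) {
  if (any(sigmaExp <= 0) || any(sigmaPred <= 0))
    stop("distribution widths and prediction uncertainties must be positive")
  abs(deltaExp - deltaPred) / sqrt(sigmaExp^2 + sigmaPred^2)
}

#' Two-tailed p-value of a non-negative Z-score
#'
#' The probability mass of a standard Gaussian beyond |Z| on both sides,
#' sqrt(2/pi) * integral_Z^Inf exp(-x^2/2) dx = erfc(Z / sqrt(2)), evaluated
#' through the closed form. Decreasing in Z; 1 at Z = 0.
#'
#' @param z non-negative numeric vector.
#' @return p-values in [0, 1].
#' @export
twoTailedP <- function(z) {
  if (any(z < 0)) stop("Z must be non-negative (callers pass |Z|)")
  2 * stats::pnorm(z, lower.tail = FALSE)
}

#' Uncertainty-penalized site probability
#'
#' Divides the p-value by the prediction uncertainty expressed in units of
#' the site's reference (first-quartile) uncertainty, with the ratio capped
#' below at 1: predictions no more uncertain than the reference keep their
#' p-value, unreliable ones are strictly penalized.
#'
#' @param pVal p-values from \code{\link{twoTailedP}}.
#' @param sigmaPred prediction uncertainty (ppm).
#' @param sigmaRef per-site reference uncertainty (ppm), > 0.
#' @return penalized probabilities in [0, 1].
#' @export
siteProbability <- function(pVal, sigmaPred, sigmaRef) {
  if (any(sigmaRef <= 0)) stop("sigmaRef must be positive")
  pVal / pmax(1, sigmaPred / sigmaRef)
}

#' Geometric-mean environment probability
#'
#' Combines the site probabilities of one environment as their geometric
#' mean, computed in log space; any zero site probability yields exactly 0.
#'
#' @param siteProbs non-empty numeric vector of probabilities in [0, 1].
#' @return a single probability.
#' @export
environmentProbability <- function(siteProbs) {
  if (!length(siteProbs)) stop("empty site-probability list")
  if (any(siteProbs < 0 | siteProbs > 1))
    stop("site probabilities must lie in [0, 1]")
  if (any(siteProbs == 0)) return(0)
  exp(mean(log(siteProbs)))
}

#' Per-site reference (first-quartile) prediction uncertainties
#'
#' The first quartile (25th percentile, linear interpolation: quantile type
#' 7) of all prediction uncertainties per site, over all molecules of all
#' snapshots. Used as the cap reference in \code{\link{siteProbability}}.
#'
#' @param predictions prediction data.frame (see
#'   \code{\link{scoreEnvironments}}).
#' @param sites optional site labels to restrict to; sites without
#'   predictions raise an error.
#' @return named numeric vector of per-site reference uncertainties.
#' @export
referenceUncertainties <- function(predictions, sites = NULL) {
  predictions <- .checkPredictions(predictions)
  if (is.null(sites)) sites <- unique(predictions$siteLabel)
  missing <- setdiff(sites, predictions$siteLabel)
  if (length(missing))
    stop("no predictions for site(s): ", paste(missing, collapse = ", "))
  keep <- predictions$siteLabel %in% sites
  out <- tapply(predictions$uncertaintyPpm[keep],
                predictions$siteLabel[keep],
                stats::quantile, probs = 0.25, names = FALSE, type = 7)
  out <- unlist(out)
  out[sites]
}

.checkPredictions <- function(predictions) {
  need <- c("trajectory", "frame", "moleculeId", "siteLabel", "shiftPpm",
            "uncertaintyPpm")
  if (!all(need %in% names(predictions)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "))
  if (any(predictions$uncertaintyPpm <= 0))
    stop("prediction uncertainties must be positive")
  predictions
}

.checkDistributions <- function(distributions) {
  need <- c("siteLabel", "element", "centerPpm", "widthPpm")
  if (!all(need %in% names(distributions)))
    stop("distribution table needs columns: ", paste(need, collapse = ", "))
  if (any(distributions$widthPpm <= 0))
    stop("experimental widths must be positive")
  if (anyDuplicated(distributions$siteLabel))
    stop("one distribution per site label")
  distributions
}

#' Score all local environments against experimental shift distributions
#'
#' Applies the full per-site probability machinery (Z-score, two-tailed
#' p-value, first-quartile uncertainty cap, geometric mean) to every
#' environment in a prediction table, then selects the NMR ensemble either by
#' a probability threshold (default 0.33, strict >) or by the best top
#' fraction of environments.
#'
#' @param predictions data.frame with columns \code{trajectory},
#'   \code{frame}, \code{moleculeId}, \code{siteLabel}, \code{shiftPpm},
#'   \code{uncertaintyPpm}; one environment per (trajectory, frame,
#'   moleculeId).
#' @param distributions data.frame with columns \code{siteLabel},
#'   \code{element}, \code{centerPpm}, \code{widthPpm}.
#' @param excludedSites site labels excluded from matching (e.g., sites with
#'   ambiguous assignments).
#' @param refUncertainties optional named per-site reference uncertainties;
#'   computed from \code{predictions} by \code{\link{referenceUncertainties}}
#'   when NULL.
#' @param threshold probability cutoff (strict >) for selection.
#' @param topFraction if non-NULL, select this fraction of highest-probability
#'   environments instead of thresholding (ties broken by environment order).
#' @param equivalentProtons "average" pools predictions sharing a site label
#'   within an environment (mean shift, mean uncertainty) before matching;
#'   "perAtom" matches each prediction separately.
#' @param onMissing "error" aborts when an environment lacks a prediction for
#'   an included site; "skip" drops such environments with a warning.
#' @return An \linkS4class{EnsembleSelection}.
#' @export
scoreEnvironments <- function(predictions, distributions,
                              excludedSites = character(0),
                              refUncertainties = NULL,
                              threshold = 0.33, topFraction = NULL,
                              equivalentProtons = c("average", "perAtom"),
                              onMissing = c("error", "skip")) {
  equivalentProtons <- match.arg(equivalentProtons)
  onMissing <- match.arg(onMissing)
  predictions <- .checkPredictions(predictions)
  distributions <- .checkDistributions(distributions)
  if (!is.null(topFraction) &&
      (topFraction <= 0 || topFraction > 1))
    stop("topFraction must lie in (0, 1]")
  if (is.null(topFraction) && (threshold < 0 || threshold > 1))
    stop("threshold must lie in [0, 1]")

  included <- setdiff(distributions$siteLabel, excludedSites)
  if (!length(included)) stop("no sites left after exclusions")
  distributions <- distributions[distributions$siteLabel %in% included, ,
                                 drop = FALSE]
  p <- predictions[predictions$siteLabel %in% included, , drop = FALSE]

  if (equivalentProtons == "average") {
    key <- paste(p$trajectory, p$frame, p$moleculeId, p$siteLabel, sep = ":")
    if (anyDuplicated(key)) {
      agg <- function(v) tapply(v, key, mean)
      first <- !duplicated(key)
      base <- p[first, c("trajectory", "frame", "moleculeId", "siteLabel")]
      k <- key[first]
      base$shiftPpm <- as.numeric(agg(p$shiftPpm)[k])
      base$uncertaintyPpm <- as.numeric(agg(p$uncertaintyPpm)[k])
      p <- base
    }
  }

  if (is.null(refUncertainties))
    refUncertainties <- referenceUncertainties(p, included)
  if (any(is.na(refUncertainties[included])) ||
      any(refUncertainties[included] <= 0))
    stop("reference uncertainties must be positive for all included sites")

  envKey <- .envKey(p$trajectory, p$frame, p$moleculeId)
  nSites <- tapply(p$siteLabel, envKey,
                   function(s) length(unique(s)))
  incomplete <- names(nSites)[nSites < length(included)]
  if (length(incomplete)) {
    if (onMissing == "error")
      stop("environment(s) missing predictions for included sites: ",
           paste(utils::head(incomplete, 5L), collapse = ", "),
           if (length(incomplete) > 5L) " ...")
    warning(length(incomplete),
            " environment(s) skipped for missing site predictions")
    keep <- !(envKey %in% incomplete)
    p <- p[keep, , drop = FALSE]
    envKey <- envKey[keep]
  }
  if (!nrow(p)) stop("no complete environments to score")

  m <- match(p$siteLabel, distributions$siteLabel)
  z <- zScore(distributions$centerPpm[m], distributions$widthPpm[m],
              p$shiftPpm, p$uncertaintyPpm)
  pv <- twoTailedP(z)
  ps <- siteProbability(pv, p$uncertaintyPpm,
                        unname(refUncertainties[p$siteLabel]))

  ## geometric mean per environment in log space (0 short-circuits)
  ord <- order(p$trajectory, p$frame, p$moleculeId)
  p <- p[ord, , drop = FALSE]
  ps <- ps[ord]
  envKey <- .envKey(p$trajectory, p$frame, p$moleculeId)
  uenv <- !duplicated(envKey)
  tab <- p[uenv, c("trajectory", "frame", "moleculeId")]
  logp <- ifelse(ps > 0, log(pmin(ps, 1)), -Inf)
  meanLog <- tapply(logp, factor(envKey, levels = envKey[uenv]), mean)
  tab$probability <- as.numeric(exp(meanLog))
  rownames(tab) <- NULL

  if (is.null(topFraction)) {
    tab$selected <- tab$probability > threshold
    mode <- "threshold"
    topFraction <- NA_real_
  } else {
    k <- ceiling(topFraction * nrow(tab))
    ranks <- rank(-tab$probability, ties.method = "first")
    tab$selected <- ranks <= k
    mode <- "topFraction"
    threshold <- NA_real_
  }
  new("EnsembleSelection", table = tab, threshold = threshold,
      topFraction = topFraction, mode = mode)
}

#' Per-environment RMSE between predicted shifts and experimental centers
#'
#' Root-mean-square deviation of predicted shifts from the centers of the
#' experimental distributions, per environment, restricted to sites of one
#' element. Unlike the probability score this ignores the widths and
#' prediction uncertainties.
#'
#' @inheritParams scoreEnvironments
#' @param element element symbol to restrict to ("H" or "C" typically).
#' @return data.frame with columns \code{trajectory}, \code{frame},
#'   \code{moleculeId}, \code{rmse}.
#' @export
perMoleculeRmse <- function(predictions, distributions, element,
                            excludedSites = character(0)) {
  predictions <- .checkPredictions(predictions)
  distributions <- .checkDistributions(distributions)
  distributions <- distributions[distributions$element == element &
                                   !(distributions$siteLabel %in%
                                       excludedSites), , drop = FALSE]
  p <- predictions[predictions$siteLabel %in% distributions$siteLabel, ,
                   drop = FALSE]
  if (!nrow(p)) stop("no matching sites for element ", element)
  m <- match(p$siteLabel, distributions$siteLabel)
  err2 <- (p$shiftPpm - distributions$centerPpm[m])^2
  ord <- order(p$trajectory, p$frame, p$moleculeId)
  p <- p[ord, , drop = FALSE]
  err2 <- err2[ord]
  key <- .envKey(p$trajectory, p$frame, p$moleculeId)
  uenv <- !duplicated(key)
  out <- p[uenv, c("trajectory", "frame", "moleculeId")]
  out$rmse <- as.numeric(sqrt(
    tapply(err2, factor(key, levels = key[uenv]), mean)))
  rownames(out) <- NULL
  out
}
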