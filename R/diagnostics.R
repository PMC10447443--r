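# Distribution-level diagnostics comparing selected predicted shifts with the
# experimental Gaussian for a site: overlap coefficient and Jensen-Shannon
# divergence. Used to justify the selection threshold (balance between
# maximal overlap and minimal divergence).

## Freedman-Diaconis bin count on the pooled support, floored at `minBins`.
.fdBreaks <- function(shifts, centerPpm, widthPpm, minBins = 20L) {
  lo <- min(min(shifts), centerPpm - 4 * widthPpm)
  hi <- max(max(shifts), centerPpm + 4 * widthPpm)
  iqr <- stats::IQR(shifts)
  n <- length(shifts)
  h <- if (iqr > 0) 2 * iqr / n^(1 / 3) else 0
  k <- if (h > 0) ceiling((hi - lo) / h) else 0L
  k <- max(k, minBins)
  seq(lo, hi, length.out = k + 1L)
}

#' Overlap and Jensen-Shannon divergence against an experimental distribution
#'
#' Histograms the supplied predicted shifts (density normalization on a
#' Freedman-Diaconis binning of the pooled support, minimum 20 bins) and
#' compares them with the experimental Gaussian discretized on the same bins:
#' the overlap coefficient sum(min(p, q)) * binwidth (on densities; 1 for
#' identical distributions) and the Jensen-Shannon divergence with base-2
#' logarithm (in [0, 1]; 0 for identical, 1 for disjoint supports).
#'
#' @param shifts numeric vector (>= 2 values) of predicted shifts for one
#'   site, typically from the selected ensemble.
#' @param centerPpm,widthPpm experimental Gaussian parameters for the site.
#' @param breaks optional numeric vector of bin edges overriding the default
#'   binning.
#' @return list with elements \code{overlap}, \code{jsDivergence},
#'   \code{breaks}.
#' @export
thresholdDiagnostics <- function(shifts, centerPpm, widthPpm, breaks = NULL) {
  if (length(shifts) < 2L)
    stop("need at least two selected predictions for the site")
  if (widthPpm <= 0) stop("widthPpm must be positive")
  if (is.null(breaks))
    breaks <- .fdBreaks(shifts, centerPpm, widthPpm)
  h <- graphics::hist(shifts, breaks = breaks, plot = FALSE)
  pMass <- h$counts / sum(h$counts)
  qMass <- diff(stats::pnorm(breaks, mean = centerPpm, sd = widthPpm))
  qTot <- sum(qMass)
  if (qTot <= 0) stop("experimental Gaussian has no mass on the binning")
  qMass <- qMass / qTot

  overlap <- sum(pmin(pMass, qMass))

  mMass <- (pMass + qMass) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  js <- 0.5 * kl(pMass, mMass) + 0.5 * kl(qMass, mMass)

  list(overlap = overlap, jsDivergence = js, breaks = breaks)
}
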