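# The probabilistic shift-matching machinery: Z-scores, two-tailed p-values,
# uncertainty capping, geometric-mean combination, reference quartiles,
# scoring/selection, RMSE and distribution diagnostics.

test_that("Z-score combines both Gaussian widths", {
  expect_equal(zScore(5, 0.6, 5, 0.8), 0)
  expect_equal(zScore(5, 0.6, 6, 0.8), 1)  # denominator sqrt(0.36+0.64) = 1
  set.seed(3)
  de <- runif(50, 0, 10); dp <- runif(50, 0, 10)
  se <- runif(50, 0.1, 2); sp <- runif(50, 0.1, 2)
  expect_equal(zScore(de, se, dp, sp), abs(de - dp) / sqrt(se^2 + sp^2))
  expect_error(zScore(1, 0, 1, 1), "positive")
  expect_error(zScore(1, 1, 1, -1), "positive")
})

test_that("two-tailed p-value matches quadrature of the tail integral", {
  expect_equal(twoTailedP(0), 1)
  expect_lt(twoTailedP(30), 1e-100)
  expect_equal(twoTailedP(1.959964), 0.05, tolerance = 1e-6)
  ## adaptive quadrature oracle of the printed integral
  for (z in c(0.3, 1, 2.5, 4)) {
    quad <- integrate(function(x) sqrt(2 / pi) * exp(-x^2 / 2), z, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(twoTailedP(z), quad, tolerance = 1e-10)
  }
  z <- seq(0, 8, by = 0.25)
  expect_true(all(diff(twoTailedP(z)) < 0))
  expect_error(twoTailedP(-0.1), "non-negative")
})

test_that("site probability caps the uncertainty penalty at one", {
  expect_equal(siteProbability(0.8, 1, 1), 0.8)
  expect_equal(siteProbability(0.8, 2, 1), 0.4)
  expect_equal(siteProbability(0.8, 0.5, 1), 0.8)  # ratio floored at 1
  expect_error(siteProbability(0.5, 1, 0), "positive")
})

test_that("environment probability is a bounded geometric mean", {
  expect_equal(environmentProbability(rep(0.5, 10)), 0.5)
  expect_equal(environmentProbability(c(1, 1, 0)), 0)
  expect_equal(environmentProbability(c(0.9, 0.4, 0.1)),
               (0.9 * 0.4 * 0.1)^(1 / 3))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    g <- environmentProbability(p)
    expect_gte(g, min(p))
    expect_lte(g, max(p))
    ## log-space equals direct product
    expect_equal(g, prod(p)^(1 / length(p)), tolerance = 1e-12)
  }
  expect_error(environmentProbability(numeric(0)), "empty")
})

test_that("reference uncertainties are per-site first quartiles", {
  p <- data.frame(trajectory = 1, frame = 1, moleculeId = 1:4,
                  siteLabel = "C1", shiftPpm = 0,
                  uncertaintyPpm = c(1, 2, 3, 4))
  expect_equal(unname(referenceUncertainties(p)["C1"]), 1.75)
  p$uncertaintyPpm <- rep(0.7, 4)
  expect_equal(unname(referenceUncertainties(p)["C1"]), 0.7)
  p1 <- p[1, ]
  expect_equal(unname(referenceUncertainties(p1)["C1"]), 0.7)
  expect_error(referenceUncertainties(p, sites = c("C1", "C9")), "C9")
})

makePredictions <- function(shifts, unc = 0.5, env = 1L) {
  data.frame(trajectory = 1L, frame = env, moleculeId = 1L,
             siteLabel = names(shifts), shiftPpm = unname(shifts),
             uncertaintyPpm = unc)
}

toyDists <- function() {
  data.frame(siteLabel = c("H1", "C1", "C2"), element = c("H", "C", "C"),
             centerPpm = c(5, 60, 120), widthPpm = c(1, 3, 3))
}

test_that("scoring selects perfect environments and rejects distant ones", {
  good <- makePredictions(c(H1 = 5, C1 = 60, C2 = 120), env = 1L)
  joint <- sqrt(3^2 + 0.5^2)
  bad <- makePredictions(c(H1 = 5, C1 = 60 + 10 * joint, C2 = 120), env = 2L)
  sel <- scoreEnvironments(rbind(good, bad), toyDists())
  st <- selectionTable(sel)
  expect_equal(st$probability[1], 1)       # all sites at centers, sigma at ref
  expect_true(st$selected[1])
  expect_lt(st$probability[2], 1e-5)
  expect_false(st$selected[2])
  expect_equal(sum(st$selected), 1L)
})

test_that("scoring is invariant under permutation of the prediction rows", {
  set.seed(17)
  man <- plantedManifest(60, 0.5, seed = 2)
  sh <- generateShifts(man, seed = 3)
  s1 <- scoreEnvironments(sh$predictions, sh$distributions)
  perm <- sample(nrow(sh$predictions))
  s2 <- scoreEnvironments(sh$predictions[perm, ], sh$distributions)
  expect_equal(selectionTable(s1), selectionTable(s2))
})

test_that("raising the threshold never grows the selected set", {
  man <- plantedManifest(200, 0.3, seed = 5)
  sh <- generateShifts(man, seed = 6)
  prev <- Inf
  for (th in c(0.1, 0.33, 0.6, 0.9, 1)) {
    k <- sum(selectionTable(
      scoreEnvironments(sh$predictions, sh$distributions,
                        threshold = th))$selected)
    expect_lte(k, prev)
    prev <- k
  }
  ## threshold 1 empties the selection (probabilities never exceed 1)
  expect_equal(prev, 0L)
})

test_that("top-fraction mode selects the stated count", {
  man <- plantedManifest(500, 0.2, seed = 8)
  sh <- generateShifts(man, seed = 9)
  sel <- scoreEnvironments(sh$predictions, sh$distributions,
                           topFraction = 0.01)
  expect_equal(sum(selectionTable(sel)$selected), 5L)
  expect_equal(selectedFraction(sel), 0.01)
})

test_that("site exclusions and missing predictions are handled explicitly", {
  p <- makePredictions(c(H1 = 5, C1 = 60, C2 = 120))
  ## excluding C2 drops it from the match
  sel <- scoreEnvironments(p, toyDists(), excludedSites = "C2")
  expect_equal(selectionTable(sel)$probability, 1)
  ## an environment missing an included site fails by default, skips on demand
  incomplete <- p[p$siteLabel != "C2", ]
  full <- makePredictions(c(H1 = 5, C1 = 60, C2 = 120), env = 2L)
  expect_error(scoreEnvironments(rbind(incomplete, full), toyDists()),
               "missing")
  expect_warning(
    sel2 <- scoreEnvironments(rbind(incomplete, full), toyDists(),
                              onMissing = "skip"),
    "skipped")
  expect_equal(nrow(selectionTable(sel2)), 1L)
})

test_that("equivalent protons are averaged before matching by default", {
  ## two protons sharing a site label, displaced symmetrically: the average
  ## sits exactly on the experimental center
  p <- data.frame(trajectory = 1L, frame = 1L, moleculeId = 1L,
                  siteLabel = c("H1", "H1", "C1", "C2"),
                  shiftPpm = c(4, 6, 60, 120), uncertaintyPpm = 0.5)
  selAvg <- scoreEnvironments(p, toyDists())
  expect_equal(selectionTable(selAvg)$probability, 1)
  selPer <- scoreEnvironments(p, toyDists(), equivalentProtons = "perAtom")
  expect_lt(selectionTable(selPer)$probability, 1)
})

test_that("per-molecule RMSE matches the direct formula", {
  p <- makePredictions(c(H1 = 5, C1 = 62, C2 = 120))
  rC <- perMoleculeRmse(p, toyDists(), "C")
  expect_equal(rC$rmse, sqrt((2^2 + 0^2) / 2))
  rH <- perMoleculeRmse(p, toyDists(), "H")
  expect_equal(rH$rmse, 0)
  ## single site off by 2 ppm
  single <- makePredictions(c(H1 = 7))
  expect_equal(perMoleculeRmse(single, toyDists(), "H")$rmse, 2)
  set.seed(21)
  man <- plantedManifest(30, 0.5, seed = 22)
  sh <- generateShifts(man, seed = 23)
  r <- perMoleculeRmse(sh$predictions, sh$distributions, "C")
  ## direct oracle for one environment
  d <- sh$distributions[sh$distributions$element == "C", ]
  one <- sh$predictions[sh$predictions$frame == r$frame[1] &
                          sh$predictions$siteLabel %in% d$siteLabel, ]
  expect_equal(r$rmse[1],
               sqrt(mean((one$shiftPpm -
                            d$centerPpm[match(one$siteLabel,
                                              d$siteLabel)])^2)))
  expect_error(perMoleculeRmse(p, toyDists(), "N"), "no matching sites")
})

test_that("overlap and JS diagnostics behave at the distribution extremes", {
  set.seed(33)
  ## histogram drawn from the experimental Gaussian itself: high overlap,
  ## low divergence
  sameDist <- thresholdDiagnostics(rnorm(20000, 5, 1), 5, 1)
  expect_gt(sameDist$overlap, 0.95)
  expect_lt(sameDist$jsDivergence, 0.01)
  ## disjoint supports: no overlap, maximal base-2 divergence
  disjoint <- thresholdDiagnostics(rnorm(2000, 50, 0.5), 5, 1)
  expect_lt(disjoint$overlap, 1e-6)
  expect_equal(disjoint$jsDivergence, 1, tolerance = 1e-6)
  ## half-overlapping uniform vs Gaussian: direct summation oracle
  shifts <- runif(5000, 5, 9)
  res <- thresholdDiagnostics(shifts, 5, 1)
  br <- res$breaks
  pM <- hist(shifts, breaks = br, plot = FALSE)$counts / 5000
  qM <- diff(pnorm(br, 5, 1)); qM <- qM / sum(qM)
  expect_equal(res$overlap, sum(pmin(pM, qM)), tolerance = 1e-12)
  m <- (pM + qM) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  expect_equal(res$jsDivergence, 0.5 * kl(pM, m) + 0.5 * kl(qM, m),
               tolerance = 1e-12)
  ## degenerate all-identical predictions still bin against the Gaussian
  deg <- thresholdDiagnostics(rep(5, 10), 5, 1)
  expect_true(is.finite(deg$jsDivergence))
  expect_error(thresholdDiagnostics(5, 5, 1), "at least two")
})
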