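# Structural characterization: hydrogen bonds, dihedral histograms,
# least-RMSD alignment, density maps, radial distribution functions.

test_that("hydrogen-bond detection applies both geometric criteria", {
  topo <- donorTopology()
  ## (2.4 A, 150 deg) to nitrogen: bonded
  hb <- detectHBond(donorEnvironment(acceptorAt(2.4, 150, "N", "NX")), topo)
  expect_equal(hb$siteLabel, "NX")
  expect_equal(hb$distance, 2.4, tolerance = 1e-9)
  expect_equal(hb$angle, 150, tolerance = 1e-6)
  ## distance fails
  expect_null(detectHBond(donorEnvironment(acceptorAt(2.6, 170)), topo))
  ## angle fails
  expect_null(detectHBond(donorEnvironment(acceptorAt(2.4, 120)), topo))
  ## carbon is not an acceptor element
  expect_null(detectHBond(donorEnvironment(acceptorAt(2.2, 170, "C", "CX")),
                          topo))
})

test_that("the nearest qualifying acceptor wins ties", {
  topo <- donorTopology()
  two <- rbind(acceptorAt(2.4, 160, "O", "far"),
               acceptorAt(2.2, 150, "N", "near"))
  hb <- detectHBond(donorEnvironment(two), topo)
  expect_equal(hb$siteLabel, "near")
  expect_equal(hb$distance, 2.2, tolerance = 1e-9)
})

test_that("hydrogen-bond census sums to one and recovers planted mixtures", {
  pk <- generatePacking(nMolecules = 30, cellSide = 24, hbondFraction = 0.3,
                        acceptorSplit = c(O2 = 0.6, N1 = 0.4), seed = 19)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  topo <- pk$snapshot@topology
  cen <- hbondCensus(envs, topo)
  expect_equal(sum(cen), 1)
  planted <- table(factor(pk$manifest$hbondClass,
                          levels = names(cen))) / nrow(pk$manifest)
  ## detected proportions within binomial error (3 sigma) of planted, with
  ## a small allowance for accidental contacts in the packing
  n <- length(envs)
  for (cat in c("O2", "N1")) {
    se <- sqrt(planted[cat] * (1 - planted[cat]) / n)
    expect_lt(abs(cen[cat] - planted[cat]), 3 * se + 0.07)
  }
})

test_that("dihedral histograms localize planted conformers", {
  ## all conformers planted at +65 degrees: a single occupied bin
  pk <- generatePacking(nMolecules = 20, cellSide = 22,
                        molecule = toyMoleculeTemplate(65), seed = 29)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  topo <- pk$snapshot@topology
  h <- dihedralHistogram(envs, topo, "backbone")
  expect_equal(sum(h$count), 20L)
  expect_equal(h$count[h$lower == 60 & h$upper == 70], 20L)
  expect_equal(sum(h$count > 0), 1L)
  expect_error(dihedralHistogram(envs, topo, "nope"), "undefined")
  expect_error(dihedralHistogram(envs, topo, "backbone", binWidth = 7),
               "divide")
})

test_that("dihedral histograms wrap the periodic boundary", {
  ## synthetic angles hugging +/-180 fall in the outermost bins
  tmpl <- toyMoleculeTemplate(179.5)
  pk <- generatePacking(nMolecules = 5, cellSide = 20, molecule = tmpl,
                        seed = 31)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  h <- dihedralHistogram(envs, pk$snapshot@topology, "backbone")
  expect_equal(sum(h$count[h$lower >= 170 | h$upper <= -170]), 5L)
})

test_that("alignment is exact on rigid copies and beats random rotations", {
  pk <- generatePacking(nMolecules = 6, cellSide = 20, seed = 37)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  env <- envs[[1]]
  ## rotated + translated copy of itself
  set.seed(41)
  qr. <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr.) %*% diag(sign(diag(qr.R(qr.))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  a <- atoms(env)
  xyz <- t(R %*% t(cbind(a$x, a$y, a$z))) +
    matrix(c(3, -2, 7), nrow(a), 3, byrow = TRUE)
  copy <- env
  copy@atoms$x <- xyz[, 1]; copy@atoms$y <- xyz[, 2]; copy@atoms$z <- xyz[, 3]
  al <- alignEnvironments(list(env, copy), c("O1", "C1", "C2", "C3"))
  expect_equal(al$rmsd, c(0, 0), tolerance = 1e-8)
  ## aligned coordinates coincide
  expect_equal(atoms(al$envs[[2]])$x, atoms(al$envs[[1]])$x,
               tolerance = 1e-8)

  ## optimality: no random proper rotation (with optimal translation) beats
  ## the least-RMSD fit of two different environments
  al2 <- alignEnvironments(list(envs[[1]], envs[[2]]), c("O1", "C1", "C2"))
  P <- as.matrix(centralAtoms(envs[[2]])[match(c("O1", "C1", "C2"),
                                               centralAtoms(envs[[2]])$siteLabel),
                                         c("x", "y", "z")])
  Q <- as.matrix(centralAtoms(envs[[1]])[match(c("O1", "C1", "C2"),
                                               centralAtoms(envs[[1]])$siteLabel),
                                         c("x", "y", "z")])
  set.seed(43)
  for (i in 1:200) {
    qr. <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr.) %*% diag(sign(diag(qr.R(qr.))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    Pr <- P %*% t(R)
    Pr <- sweep(Pr, 2, colMeans(Pr) - colMeans(Q))
    rmsdRand <- sqrt(mean(rowSums((Pr - Q)^2)))
    expect_gte(rmsdRand, al2$rmsd[2] - 1e-9)
  }
  expect_error(alignEnvironments(list(env), c("O1", "H1")), "three")
})

test_that("alignment agrees with an independent superposition routine", {
  skip_if_not_installed("bio3d")
  pk <- generatePacking(nMolecules = 4, cellSide = 20, seed = 47)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  labels <- c("O1", "C1", "C2", "C3", "N1")
  al <- alignEnvironments(envs[1:2], labels)
  c1 <- centralAtoms(envs[[1]]); c2 <- centralAtoms(envs[[2]])
  fixed <- as.vector(t(as.matrix(c1[match(labels, c1$siteLabel),
                                    c("x", "y", "z")])))
  mobile <- as.vector(t(as.matrix(c2[match(labels, c2$siteLabel),
                                     c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = 1:15,
                           mobile.inds = 1:15)
  rmsdBio <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) -
       matrix(fixed, ncol = 3, byrow = TRUE))^2)))
  expect_equal(al$rmsd[2], rmsdBio, tolerance = 1e-6)
})

test_that("density maps honour the grid anchor and element partition", {
  spec <- densityMapSpec()
  expect_equal(gridSpacing(spec), 0.4)
  ## one environment, one atom exactly on a grid node -> value exactly 1
  a <- data.frame(element = "O", x = 0.4, y = -0.8, z = 1.2,
                  siteLabel = "O1", moleculeId = 1L, atomId = 1L)
  env <- new("LocalEnvironment", atoms = a, centralMoleculeId = 1L,
             memberMoleculeIds = 1L, cutoff = 7, sourceId = c(1L, 1L))
  m <- densityMap(list(env), "O", center = c(0, 0, 0), spec = spec)
  ax <- attr(m, "axes")
  node <- c(match(0.4, round(ax$x, 10)), match(-0.8, round(ax$y, 10)),
            match(1.2, round(ax$z, 10)))
  expect_equal(m[node[1], node[2], node[3]], 1)
  ## an element absent from the environments gives the zero map
  expect_true(all(densityMap(list(env), "N", spec = spec) == 0))
  ## two environments with the same atom position still give 1 (mean of two
  ## unit Gaussians)
  m2 <- densityMap(list(env, env), "O", center = c(0, 0, 0), spec = spec)
  expect_equal(m2[node[1], node[2], node[3]], 1)
  ## single-atom environments never exceed 1
  expect_lte(max(m), 1 + 1e-12)
})

test_that("density maps are permutation invariant and linear in the set", {
  pk <- generatePacking(nMolecules = 8, cellSide = 22, seed = 53)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  al <- alignEnvironments(envs[1:4], c("O1", "C1", "C2"))
  spec <- densityMapSpec(gridPoints = 13L, cubeSide = 6)
  m1234 <- densityMap(al$envs, "C", al$center, spec)
  mPerm <- densityMap(al$envs[c(3, 1, 4, 2)], "C", al$center, spec)
  expect_equal(m1234, mPerm)
  m12 <- densityMap(al$envs[1:2], "C", al$center, spec)
  m34 <- densityMap(al$envs[3:4], "C", al$center, spec)
  expect_equal(as.vector(m1234), as.vector((m12 + m34) / 2),
               tolerance = 1e-12)
})

test_that("difference maps subtract pointwise and reject mismatched grids", {
  a <- data.frame(element = "O", x = 0, y = 0, z = 0, siteLabel = "O1",
                  moleculeId = 1L, atomId = 1L)
  env <- new("LocalEnvironment", atoms = a, centralMoleculeId = 1L,
             memberMoleculeIds = 1L, cutoff = 7, sourceId = c(1L, 1L))
  spec <- densityMapSpec(gridPoints = 11L, cubeSide = 4)
  m <- densityMap(list(env), "O", spec = spec)
  expect_true(all(densityDifferenceMap(m, m) == 0))
  b <- env
  b@atoms$x <- 0.4
  m2 <- densityMap(list(b), "O", spec = spec)
  d <- densityDifferenceMap(m2, m)
  expect_equal(max(abs(d - (m2 - m))), 0)
  mOther <- densityMap(list(env), "O", center = c(1, 0, 0), spec = spec)
  expect_error(densityDifferenceMap(m, mOther), "mismatched")
})

test_that("partial g(r) approaches one for an ideal gas", {
  set.seed(61)
  side <- 30
  topo <- molecularTopology("P1", c(P1 = "C"))
  n <- 1500
  a <- data.frame(element = "C", x = runif(n, 0, side),
                  y = runif(n, 0, side), z = runif(n, 0, side),
                  siteLabel = "P1", moleculeId = seq_len(n),
                  atomId = seq_len(n))
  snap <- snapshot(periodicCell(side), a, topo)
  rdf <- radialDistribution(list(snap), rMax = 12, dr = 0.3)
  far <- rdf$r > 6
  ## Poisson sampling error per bin: 3 sigma band
  lam <- n * (n - 1) / 2 * 4 * pi * rdf$r^2 * 0.3 / side^3
  expect_true(all(abs(rdf$G[far] - 1) < 3 / sqrt(lam[far]) + 0.02))
  expect_error(radialDistribution(list(snap), rMax = 16), "half the")
})

test_that("lattice RDF peaks sit at the analytic shell distances", {
  aLat <- 4
  grid <- expand.grid(x = 0:4, y = 0:4, z = 0:4) * aLat
  topo <- molecularTopology("P1", c(P1 = "C"))
  at <- data.frame(element = "C", x = grid$x, y = grid$y, z = grid$z,
                   siteLabel = "P1", moleculeId = seq_len(nrow(grid)),
                   atomId = seq_len(nrow(grid)))
  snap <- snapshot(periodicCell(5 * aLat), at, topo)
  rdf <- radialDistribution(list(snap), rMax = 9, dr = 0.1)
  shells <- c(4, 4 * sqrt(2), 4 * sqrt(3), 8)
  occupied <- rdf$r[rdf$G > 0.5]
  for (s in shells)
    expect_true(any(abs(occupied - s) <= 0.1))
  ## nothing between the shells
  between <- rdf$G[rdf$r > 4.2 & rdf$r < 5.4]
  expect_true(all(between < 1e-9))
})

test_that("total G(r) is the weighted sum of its partials", {
  pk <- generatePacking(nMolecules = 12, cellSide = 22, seed = 67)
  rdf <- radialDistribution(list(pk$snapshot), rMax = 10, dr = 0.2)
  expect_equal(rdf$G, drop(rdf$partials %*% rdf$weights))
  expect_equal(sum(rdf$weights), 1)
  ## D(r) from G(r) under the documented convention
  expect_equal(rdf$D, 4 * pi * rdf$rho * rdf$r * (rdf$G - 1))
})

test_that("curve residuals interpolate onto the reference grid", {
  r <- seq(0, 10, by = 0.1)
  sim <- list(r = r, value = sin(r))
  ## identical curves
  res <- curveResidual(sim, sim)
  expect_equal(res$rmse, 0)
  ## constant offset
  off <- list(r = r, value = sin(r) + 0.3)
  res2 <- curveResidual(off, sim)
  expect_equal(res2$rmse, 0.3, tolerance = 1e-12)
  expect_equal(res2$rmseSubRange, 0.3, tolerance = 1e-12)
  ## random curves against the direct formula (same grid, no interpolation
  ## error)
  set.seed(71)
  v1 <- rnorm(length(r)); v2 <- rnorm(length(r))
  res3 <- curveResidual(list(r = r, value = v1), list(r = r, value = v2))
  expect_equal(res3$rmse, sqrt(mean((v1 - v2)^2)), tolerance = 1e-12)
  inSub <- r >= 3 & r <= 10
  expect_equal(res3$rmseSubRange, sqrt(mean((v1 - v2)[inSub]^2)),
               tolerance = 1e-12)
  expect_error(curveResidual(list(r = 0:1, value = 0:1),
                             list(r = 5:6, value = 0:1)), "disjoint")
})
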