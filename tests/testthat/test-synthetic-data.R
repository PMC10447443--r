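# The synthetic generator: determinism, topology invariants, ground-truth
# consistency between manifest labels and geometry, and the statistical
# structure of the generated shifts.

test_that("generation is reproducible from a fixed seed", {
  p1 <- generatePacking(nMolecules = 10, cellSide = 22, hbondFraction = 0.4,
                        seed = 97)
  p2 <- generatePacking(nMolecules = 10, cellSide = 22, hbondFraction = 0.4,
                        seed = 97)
  expect_identical(p1$snapshot@atoms, p2$snapshot@atoms)
  expect_identical(p1$manifest, p2$manifest)
  t1 <- generateTrajectory(p1, 3, seed = 98)
  t2 <- generateTrajectory(p2, 3, seed = 98)
  expect_identical(lapply(t1$snapshots, atoms), lapply(t2$snapshots, atoms))
  s1 <- generateShifts(t1$manifest, seed = 99)
  s2 <- generateShifts(t2$manifest, seed = 99)
  expect_identical(s1, s2)
})

test_that("generated molecules realize the topology and planted conformers", {
  pk <- generatePacking(nMolecules = 12, cellSide = 24,
                        conformerFractions = c(A = 0.5, B = 0.5),
                        hbondFraction = 0.3, seed = 101)
  snap <- pk$snapshot
  expect_true(validObject(snap))  # every molecule realizes the site set
  envs <- extractAllEnvironments(list(snap), 7)
  topo <- snap@topology
  ## planted backbone torsions: +60 for class A, -60 for class B
  for (i in seq_along(envs)) {
    ang <- environmentDihedral(envs[[i]], topo, "backbone")
    cls <- pk$manifest$conformerClass[
      pk$manifest$moleculeId == envs[[i]]@centralMoleculeId]
    expect_equal(ang, if (cls == "A") 60 else -60, tolerance = 1e-6)
  }
})

test_that("manifest hydrogen-bond labels match detected geometry", {
  pk <- generatePacking(nMolecules = 24, cellSide = 26, hbondFraction = 0.5,
                        seed = 103)
  envs <- extractAllEnvironments(list(pk$snapshot), 7)
  topo <- pk$snapshot@topology
  man <- pk$manifest
  for (i in seq_along(envs)) {
    mid <- envs[[i]]@centralMoleculeId
    planted <- man$hbondClass[man$moleculeId == mid]
    hb <- detectHBond(envs[[i]], topo)
    if (planted != "none") {
      ## planted donors always fire, on the planted acceptor and partner
      expect_false(is.null(hb))
      expect_equal(hb$siteLabel, planted)
      expect_equal(hb$moleculeId, man$partnerMoleculeId[man$moleculeId == mid])
    }
  }
  ## full planting through symmetric dimers
  full <- generatePacking(nMolecules = 12, cellSide = 24, hbondFraction = 1,
                          acceptorSplit = c(O2 = 1), seed = 107)
  fenvs <- extractAllEnvironments(list(full$snapshot), 7)
  fired <- vapply(fenvs, function(e)
    !is.null(detectHBond(e, full$snapshot@topology)), logical(1))
  expect_true(all(fired))
})

test_that("trajectory jitter preserves planted structure", {
  pk <- generatePacking(nMolecules = 10, cellSide = 24, hbondFraction = 0.4,
                        seed = 109)
  trj <- generateTrajectory(pk, 5, jitterSd = 0.05, seed = 110)
  expect_length(trj$snapshots, 5L)
  expect_equal(nrow(trj$manifest), 50L)
  topo <- pk$snapshot@topology
  for (f in c(1L, 5L)) {
    envs <- extractAllEnvironments(trj$snapshots[f], 7)
    man <- trj$manifest[trj$manifest$frame == f, ]
    for (i in seq_along(envs)) {
      planted <- man$hbondClass[man$moleculeId ==
                                  envs[[i]]@centralMoleculeId]
      if (planted != "none")
        expect_false(is.null(detectHBond(envs[[i]], topo)))
    }
  }
})

test_that("noise-free class-A shifts give the capped p-value at Z = 0", {
  man <- plantedManifest(40, 1, seed = 113)  # all class A
  sh <- generateShifts(man, noiseScale = 0, seed = 114)
  ## all predictions sit exactly on the experimental centers
  d <- sh$distributions
  m <- match(sh$predictions$siteLabel, d$siteLabel)
  expect_equal(sh$predictions$shiftPpm, d$centerPpm[m])
  ## site probability reduces to 1 / max(1, sigma/sigma0)
  ref <- referenceUncertainties(sh$predictions)
  ps <- siteProbability(twoTailedP(zScore(d$centerPpm[m], d$widthPpm[m],
                                          sh$predictions$shiftPpm,
                                          sh$predictions$uncertaintyPpm)),
                        sh$predictions$uncertaintyPpm,
                        ref[sh$predictions$siteLabel])
  expected <- 1 / pmax(1, sh$predictions$uncertaintyPpm /
                         ref[sh$predictions$siteLabel])
  expect_equal(unname(ps), unname(expected))
  expect_true(all(ps <= 1))
  ## predictions at or below the site's first quartile keep probability 1
  atFloor <- sh$predictions$uncertaintyPpm <=
    ref[sh$predictions$siteLabel]
  expect_true(all(ps[atFloor] == 1))
})

test_that("zero class separation makes selection no better than chance", {
  man <- plantedManifest(2000, 0.2, seed = 115)
  model <- toyShiftModel(separation = 0)
  sh <- generateShifts(man, model = model, seed = 116)
  sel <- scoreEnvironments(sh$predictions, sh$distributions,
                           topFraction = 0.05)
  st <- selectionTable(sel)
  key <- paste(st$trajectory, st$frame, st$moleculeId)
  mkey <- paste(man$trajectory, man$frame, man$moleculeId)
  plantedSel <- mean(man$conformerClass[match(key[st$selected],
                                              mkey)] == "A")
  ## within 3 binomial sigma of the planted fraction
  expect_lt(abs(plantedSel - 0.2), 3 * sqrt(0.2 * 0.8 / sum(st$selected)))
})

test_that("infeasible packing densities raise an explicit error", {
  expect_error(generatePacking(nMolecules = 60, cellSide = 10,
                               maxTries = 30, seed = 117),
               "density")
})
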