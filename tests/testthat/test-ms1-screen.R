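test_that("feature detection recovers injected elution peaks", {
  out <- generateRun(onePeptideConfig(seed = 3))
  tp <- out$truth$peptides
  ft <- detectFeatures(out$run, data.frame(mz = tp$unlabeledMz, z = tp$charge))
  expect_equal(nrow(ft), 1L)
  expect_lt(abs(ft$rtApex - tp$rtUnlabeled), 0.05 + 1e-9)
  expect_true(ft$rtMin <= ft$rtApex && ft$rtApex <= ft$rtMax)
  ## flat/empty run yields no features
  expect_equal(nrow(detectFeatures(MSRun(ms1Rt = 1:5,
    ms1Peaks = replicate(5, cbind(mz = 500, intensity = 1),
                         simplify = FALSE)),
    data.frame(mz = 600, z = 2))), 0L)
})

test_that("baseline-separated peaks at one m/z become two features with disjoint bounds", {
  rts <- seq(0, 20, by = 0.1)
  y <- 1000 * exp(-(rts - 5)^2 / (2 * 0.3^2)) +
       800 * exp(-(rts - 15)^2 / (2 * 0.3^2))
  run <- MSRun(ms1Rt = rts, ms1Peaks = lapply(y, function(v)
    cbind(mz = 700.35, intensity = v)))
  ft <- detectFeatures(run, data.frame(mz = 700.35, z = 2))
  ft <- ft[order(ft$rtApex), ]
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$rtApex, c(5, 15), tolerance = 0.02)
  expect_lte(ft$rtMax[1], ft$rtMin[2])
})

test_that("the delayed-retention screen keeps true labeled peptides and rejects near-coeluters", {
  out <- generateRun(onePeptideConfig(seed = 5, efficiencyPct = 1,
                                      rtShift = 12))
  peps <- data.frame(sequence = "IVFPFTFSLFNLVYWLYYVN", proteinId = "p1",
                     start = 1L, end = 20L)
  hits <- screenLabeled(out$run, peps, defaultAdducts()["KK123"],
                        searchParams(chargeRange = 3L))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rtDelay, 12, tolerance = 0.01)
  expect_equal(hits$reference, "delayed")
  expect_lte(abs(hits$ppmError), 30)
  ## labeled form only 0.1 min later than unlabeled: excluded at 2 min
  outNear <- generateRun(onePeptideConfig(seed = 5, rtShift = 0.1))
  hitsNear <- screenLabeled(outNear$run, peps, defaultAdducts()["KK123"],
                            searchParams(chargeRange = 3L,
                                         minRetentionDelayMin = 2))
  expect_equal(nrow(hitsNear), 0L)
})

test_that("mass errors beyond the precursor tolerance are never reported", {
  ## inject the labeled feature displaced by 50 ppm
  cfg <- onePeptideConfig(seed = 9)
  out <- generateRun(cfg)
  tp <- out$truth$peptides
  rts <- ms1ScanTimes(out$run)
  shifted <- MSRun(ms1Rt = rts, ms1Peaks = lapply(seq_along(rts), function(i) {
    p <- ms1PeakLists(out$run)[[i]]
    if (nrow(p)) {
      lab <- abs(p[, 1] - tp$labeledMz) < 1e-6
      p[lab, 1] <- p[lab, 1] * (1 + 50e-6)
    }
    p
  }))
  peps <- data.frame(sequence = tp$sequence, proteinId = "p1",
                     start = 1L, end = 20L)
  hits <- screenLabeled(shifted, peps, defaultAdducts()["KK123"],
                        searchParams(chargeRange = 3L))
  expect_equal(nrow(hits), 0L)
})

test_that("doublet pairing matches the tag spacing and co-elution rules", {
  ## the worked doublet: (1073.256, z3) / (1076.592, z3), co-eluting
  ft <- data.frame(targetMz = c(1073.256, 1076.592),
                   observedMz = c(1073.256, 1076.592),
                   charge = 3L, rtApex = 80, rtMin = 79, rtMax = 81,
                   area = c(100, 100), apexIntensity = c(10, 10))
  prm <- searchParams()
  pd <- defaultAdducts()$KK123_FLI@pairDelta
  pairs <- findDoublets(ft, pd, prm)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$massDiff, pd, tolerance = 0.01 / pd)
  expect_equal(pairs$intensityRatio, 1)
  ## not co-eluting
  ft2 <- ft; ft2$rtApex <- c(80, 95)
  expect_equal(nrow(findDoublets(ft2, pd, prm)), 0L)
  ## charge mismatch
  ft3 <- ft; ft3$charge <- c(3L, 4L)
  expect_equal(nrow(findDoublets(ft3, pd, prm)), 0L)
})

test_that("doublet detection is deterministic and order-independent", {
  set.seed(21)
  pd <- 10.0078
  ## three genuine pairs plus decoys at random m/z
  light <- c(900.5, 1100.25, 1300.75)
  z <- c(2L, 3L, 4L)
  heavy <- light + pd / z
  decoy <- runif(10, 400, 1600)
  ft <- data.frame(
    observedMz = c(light, heavy, decoy),
    charge = c(z, z, sample(2:4, 10, replace = TRUE)),
    rtApex = c(rep(50, 6), runif(10, 0, 100)),
    area = 100, apexIntensity = 10)
  ft$targetMz <- ft$observedMz; ft$rtMin <- ft$rtApex - 1
  ft$rtMax <- ft$rtApex + 1
  prm <- searchParams()
  ref <- findDoublets(ft, pd, prm)
  expect_equal(nrow(ref), 3L)
  expect_equal(sort(ref$lightMz), sort(light), tolerance = 1e-9)
  ## all reported pairs satisfy the tolerance by construction
  tolMass <- pmax(prm$pairAbsTolDa,
                  massFromMz(ref$heavyMz, ref$charge) * 30e-6)
  expect_true(all(abs(ref$massDiff - pd) <= tolMass))
  for (i in 1:5) {
    perm <- ft[sample(nrow(ft)), ]
    expect_equal(findDoublets(perm, pd, prm), ref)
  }
})

test_that("doublets on paired generator runs reach perfect precision and recall", {
  cfg <- syntheticRunConfig(
    peptides = data.frame(
      sequence = "IVFPFTFSLFNLVYWLYYVN", proteinId = "beta3", start = 426L,
      site = 442L, reagent = "KK123-FLI", efficiencyPct = 2,
      rtUnlabeled = 6, charge = 3L, stringsAsFactors = FALSE),
    pairing = TRUE, rtRange = c(0, 25), noisePeaks = 0, seed = 13)
  out <- generateRun(cfg)
  truthPairs <- out$truth$pairs
  targets <- data.frame(mz = c(truthPairs$lightMz, truthPairs$heavyMz),
                        z = truthPairs$charge)
  ft <- detectFeatures(out$run, targets)
  pairs <- findDoublets(ft, truthPairs$pairDelta[1])
  expect_equal(nrow(pairs), nrow(truthPairs))      # recall = 1
  expect_equal(pairs$lightMz, truthPairs$lightMz, tolerance = 1e-6)
  expect_equal(pairs$heavyMz, truthPairs$heavyMz, tolerance = 1e-6)
})
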