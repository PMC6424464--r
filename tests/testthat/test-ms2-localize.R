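test_that("theoretical b/y ladders match hand-computed fragment masses", {
  tab <- residueMasses()
  lad <- theoreticalLadder("AGK", NULL, charges = 1L)
  b2 <- lad$mz[lad$series == "b" & lad$index == 2]
  y1 <- lad$mz[lad$series == "y" & lad$index == 1]
  expect_equal(b2, 71.03711 + 57.02146 + 1.00728, tolerance = 1e-9)
  expect_equal(y1, 128.09496 + 18.01056 + 1.00728, tolerance = 1e-9)
  ## adduct on residue 3: y1 carries it, b2 does not; neutral loss restores
  ad <- AdductSpec("x", 100)
  lad3 <- theoreticalLadder("AGK", ad, placement = 3, charges = 1L,
                            includeNeutralLoss = TRUE)
  expect_equal(lad3$mz[lad3$series == "y" & lad3$index == 1 &
                       !lad3$neutralLoss], y1 + 100, tolerance = 1e-9)
  expect_equal(lad3$mz[lad3$series == "b" & lad3$index == 2], b2,
               tolerance = 1e-9)
  expect_equal(lad3$mz[lad3$series == "y" & lad3$index == 1 &
                       lad3$neutralLoss], y1, tolerance = 1e-9)
  expect_true(all(lad3$carriesAdduct[lad3$neutralLoss]))
  expect_error(theoreticalLadder("AGK", ad, placement = 9), "placement")
  ## agreement with the substring-summation oracle incl. positioned mods
  set.seed(31)
  for (i in 1:10) {
    s <- randomPeptide(sample(4:12, 1))
    pos <- sample(nchar(s), 1)
    mp <- sample(nchar(s), 1)
    lad <- theoreticalLadder(
      ModifiedPeptide(s, mp, ModificationSpec("fx", 57.02146)),
      ad, pos, charges = 1:2)
    for (j in sample(nrow(lad), 6)) {
      expect_equal(lad$mz[j],
        oracleFragMz(s, lad$series[j], lad$index[j], lad$charge[j],
                     100, pos, mp, 57.02146) -
          if (lad$neutralLoss[j]) 100 / lad$charge[j] else 0,
        tolerance = 1e-9)
    }
  }
})

test_that("fragment matching uses the nearest peak within the absolute tolerance", {
  lad <- theoreticalLadder("AGKW", NULL, charges = 1L)
  spec <- Spectrum2(500, 2L, 10, mz = sort(lad$mz), intensity = rep(1, nrow(lad)))
  m <- matchFragments(spec, lad, 0.1)
  expect_equal(nrow(m), nrow(lad))
  expect_true(all(abs(m$error) < 1e-9))
  specOff <- Spectrum2(500, 2L, 10, mz = sort(lad$mz) + 0.2,
                       intensity = rep(1, nrow(lad)))
  expect_equal(nrow(matchFragments(specOff, lad, 0.1)), 0L)
})

test_that("matched fraction tracks the generator ladder completeness", {
  cfg <- onePeptideConfig(seed = 17, ladderCompleteness = 0.8,
                          noisePeaks = 0, neutralLossFraction = 0)
  out <- generateRun(cfg)
  sp <- ms2Spectra(out$run)[[1]]
  lad <- theoreticalLadder("IVFPFTFSLFNLVYWLYYVN", defaultAdducts()$KK123,
                           17, charges = 1:2)
  m <- matchFragments(sp, lad, 0.1)
  frac <- nrow(m) / nrow(lad)
  ## binomial: 76 trials at p = 0.8, allow 4 sigma
  expect_lt(abs(frac - 0.8), 4 * sqrt(0.8 * 0.2 / nrow(lad)))
})

test_that("localization reproduces the set-intersection logic of site-defining ions", {
  ad <- AdductSpec("x", 100)
  s7 <- "AGKWSTV"
  ## full ladder for placement 3 localizes exactly
  lad <- theoreticalLadder(s7, ad, 3, charges = 1L)
  spec <- Spectrum2(mzFromMass(peptideMass(s7) + 100, 2), 2L, 10,
                    mz = sort(lad$mz), intensity = rep(100, nrow(lad)))
  loc <- localizeSite(spec, s7, ad, charges = 1L)
  expect_equal(localizedInterval(loc), c(3L, 3L))
  ## only neutral-loss ions: no site evidence, interval is the whole peptide
  nl <- theoreticalLadder(s7, ad, 3, charges = 1L, includeNeutralLoss = TRUE)
  nl <- nl[nl$neutralLoss, ]
  specNl <- Spectrum2(mzFromMass(peptideMass(s7) + 100, 2), 2L, 10,
                      mz = sort(unique(nl$mz)),
                      intensity = rep(100, length(unique(nl$mz))))
  locNl <- localizeSite(specNl, s7, ad, charges = 1L)
  expect_equal(localizedInterval(locNl), c(1L, 7L))
  ## adduct-free b2 plus adduct-bearing y5 only: exclude 1-2, constrain 3-7
  b2 <- oracleFragMz(s7, "b", 2, 1)
  y5 <- oracleFragMz(s7, "y", 5, 1, adductMass = 100, placement = 3)
  spec2 <- Spectrum2(mzFromMass(peptideMass(s7) + 100, 2), 2L, 10,
                     mz = sort(c(b2, y5)), intensity = c(100, 100))
  loc2 <- localizeSite(spec2, s7, ad, charges = 1L)
  expect_equal(localizedInterval(loc2), c(3L, 7L))
})

test_that("localization agrees exactly with the brute-force enumeration oracle", {
  set.seed(41)
  ad <- AdductSpec("x", 120.5)
  for (i in 1:60) {
    L <- sample(4:12, 1)
    s <- randomPeptide(L)
    pos <- sample(L, 1)
    lad <- theoreticalLadder(s, ad, pos, charges = 1L,
                             includeNeutralLoss = TRUE)
    keep <- runif(nrow(lad)) < 0.6
    mzs <- lad$mz[keep]
    noise <- runif(sample(0:10, 1), 100, 1500)
    allMz <- sort(unique(c(mzs, noise)))
    if (length(allMz) < 1) next
    spec <- Spectrum2(mzFromMass(peptideMass(s) + 120.5, 2), 2L, 10,
                      mz = allMz, intensity = rep(1, length(allMz)))
    loc <- localizeSite(spec, s, ad, charges = 1L)
    ora <- oracleLocalize(allMz, s, 120.5, 0.1, 1L)
    expect_equal(unname(localizedInterval(loc)), as.integer(ora))
  }
})

test_that("localized intervals shrink monotonically and ignore unmatched noise", {
  ad <- AdductSpec("x", 100)
  s <- "AGKWSTVYE"
  lad <- theoreticalLadder(s, ad, 5, charges = 1L)
  y7 <- lad[lad$series == "y" & lad$index == 7, ]      # spans 3..9, carries
  prec <- mzFromMass(peptideMass(s) + 100, 2)
  spec1 <- Spectrum2(prec, 2L, 10, mz = y7$mz, intensity = 1)
  i1 <- localizedInterval(localizeSite(spec1, s, ad, charges = 1L))
  ## add an adduct-bearing y5 (spans 5..9): interval must not widen
  y5 <- lad[lad$series == "y" & lad$index == 5, ]
  spec2 <- Spectrum2(prec, 2L, 10, mz = sort(c(y7$mz, y5$mz)),
                     intensity = c(1, 1))
  i2 <- localizedInterval(localizeSite(spec2, s, ad, charges = 1L))
  expect_gte(i2[1], i1[1])
  expect_lte(i2[2], i1[2])
  ## noise matching nothing leaves the result unchanged
  spec3 <- Spectrum2(prec, 2L, 10, mz = sort(c(y7$mz, y5$mz, 1800, 1900)),
                     intensity = rep(1, 4))
  expect_equal(localizedInterval(localizeSite(spec3, s, ad, charges = 1L)),
               i2)
  expect_error(localizeSite(spec1, "A", ad), "2 residues")
  expect_warning(localizeSite(Spectrum2(9999, 2L, 10, mz = y7$mz,
                                        intensity = 1), s, ad,
                              charges = 1L),
                 "inconsistent")
})

test_that("complete ladders localize any placement to a single residue", {
  set.seed(51)
  ad <- AdductSpec("x", 250)
  for (i in 1:20) {
    L <- sample(5:15, 1)
    s <- randomPeptide(L)
    pos <- sample(L, 1)
    lad <- theoreticalLadder(s, ad, pos, charges = 1L)
    spec <- Spectrum2(mzFromMass(peptideMass(s) + 250, 2), 2L, 10,
                      mz = sort(unique(lad$mz)),
                      intensity = rep(1, length(unique(lad$mz))))
    loc <- localizeSite(spec, s, ad, charges = 1L)
    expect_equal(localizedInterval(loc), c(pos, pos))
  }
})

test_that("heavy/light fragment overlays verify genuine tag pairs only", {
  ad <- defaultAdducts()$KK123_FLI
  s <- "IVFPFTFSLFNLVYWLYYVN"
  pos <- 17L
  ladL <- theoreticalLadder(s, AdductSpec("l", ad@lightTagMass), pos, 1:2)
  ladH <- theoreticalLadder(s, AdductSpec("h", ad@heavyTagMass), pos, 1:2)
  prm <- searchParams()
  mk <- function(mzs) Spectrum2(1073.256, 3L, 16, mz = sort(unique(mzs)),
                                intensity = rep(1, length(unique(mzs))))
  ovOK <- overlayVerify(mk(ladL$mz), mk(ladH$mz), s, ad, pos, prm)
  expect_equal(ovOK$verdict, "verified")
  expect_true(all(abs(ovOK$pairs$observedDiff - ovOK$pairs$expectedDiff)
                  <= prm$fragmentTolDa))
  ## heavy spectrum shifted on adduct-free ions too: inconsistent
  shifted <- ladH
  shifted$mz <- shifted$mz + ifelse(shifted$carriesAdduct, 0,
                                    ad@pairDelta / shifted$charge)
  expect_equal(overlayVerify(mk(ladL$mz), mk(shifted$mz), s, ad, pos,
                             prm)$verdict, "inconsistent")
  ## identical spectra with a nonzero pair delta: inconsistent
  expect_equal(overlayVerify(mk(ladL$mz), mk(ladL$mz), s, ad, pos,
                             prm)$verdict, "inconsistent")
  ## disjoint spectra: inconsistent with empty pair list
  ovNone <- overlayVerify(mk(c(200.123, 300.456)), mk(c(800.9, 900.1)),
                          s, ad, pos, prm)
  expect_equal(ovNone$verdict, "inconsistent")
  expect_equal(nrow(ovNone$pairs), 0L)
})

test_that("paired generator spectra pass overlay verification", {
  cfg <- syntheticRunConfig(
    peptides = data.frame(
      sequence = "IVFPFTFSLFNLVYWLYYVN", proteinId = "beta3", start = 426L,
      site = 442L, reagent = "KK123-FLI", efficiencyPct = 2,
      rtUnlabeled = 6, charge = 3L, stringsAsFactors = FALSE),
    pairing = TRUE, rtRange = c(0, 25), noisePeaks = 5, seed = 23)
  out <- generateRun(cfg)
  sps <- ms2Spectra(out$run)
  ov <- overlayVerify(sps[[1]], sps[[2]],
                      Peptide("IVFPFTFSLFNLVYWLYYVN", "beta3", 426L),
                      defaultAdducts()$KK123_FLI, 17L)
  expect_equal(ov$verdict, "verified")
})
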