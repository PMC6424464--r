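test_that("residue mass table is complete and anchored", {
  tab <- residueMasses()
  expect_setequal(names(tab$residues), strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]])
  expect_true(all(tab$residues > 0))
  expect_equal(tab$water, 18.01056, tolerance = 1e-4)
  expect_equal(tab$proton, 1.00728, tolerance = 1e-4)
})

test_that("peptide masses match independent summation", {
  expect_equal(peptideMass("IAFPLLFGIFNLVYWATYLNREPQLK"), 3125.711,
               tolerance = 0.01 / 3125)
  expect_equal(peptideMass("G"), 75.032, tolerance = 1e-3 / 75)
  mp <- ModifiedPeptide("IVFPFTFSLFNLVYWLYYVN", 17,
                        AdductSpec("KK123-FLI-light", 672.4322))
  expect_equal(peptideMass(mp), 2544.313 + 672.4322, tolerance = 0.01 / 3216)
  ## cross-check against the naive per-character oracle
  for (s in c("AGK", "MWCNQH", "IAFPLLFGIFNLVYWATYLNREPQLK"))
    expect_equal(peptideMass(s), unname(oraclePeptideMass(s)),
                 tolerance = 1e-9)
})

test_that("mass additivity holds for any modification", {
  set.seed(42)
  for (i in 1:20) {
    s <- randomPeptide(sample(5:25, 1))
    pos <- sample(nchar(s), 1)
    dm <- stats::runif(1, 10, 700)
    mp <- ModifiedPeptide(s, pos, ModificationSpec("m", dm))
    expect_equal(peptideMass(mp) - peptideMass(s), dm, tolerance = 1e-9)
  }
})

test_that("peptide mass rejects unknown residues and bad mod positions", {
  expect_error(peptideMass("AGX"), "position 3")
  expect_error(ModifiedPeptide("AGK", 5, ModificationSpec("m", 1)),
               "out of range")
})

test_that("m/z arithmetic follows the protonation convention", {
  expect_equal(mzFromMass(1000, 2), 501.00728)
  expect_equal(mzFromMass(3587.98, 4), 898.002, tolerance = 0.01 / 898)
  expect_equal(massFromMz(875.503, 4), 3497.98, tolerance = 0.01 / 3497)
  expect_equal(massFromMz(1.00728, 1), 0)
  expect_equal(massFromMz(501.00728, 2), 1000)
  expect_error(mzFromMass(100, 0))
  expect_error(massFromMz(100, -1))
  ## exact round trip across charges
  for (z in 1:8)
    expect_equal(massFromMz(mzFromMass(1234.5678, z), z), 1234.5678,
                 tolerance = 1e-9)
})

test_that("ppm error is signed and invertible", {
  expect_equal(ppmError(500.015, 500), 30)
  expect_equal(ppmError(898.002, 898.002), 0)
  expect_equal(ppmError(898.002 * (1 + 30e-6), 898.002), 30,
               tolerance = 1e-9)
  ## inverting the definition: a -30 ppm shift of the reference gives
  ## +30/(1 - 30e-6) ppm back
  expect_equal(ppmError(898.002, 898.002 * (1 - 30e-6)),
               30 / (1 - 30e-6), tolerance = 1e-9)
  expect_error(ppmError(500, 0))
})

test_that("tryptic digestion applies the cleavage rule with the proline exception", {
  d0 <- digestProtein("AAKRPCCK", maxMissedCleavages = 0)
  expect_equal(d0$sequence, c("AAK", "RPCCK"))
  expect_equal(d0$start, c(1L, 4L))
  expect_equal(d0$end, c(3L, 8L))
  d1 <- digestProtein("AAKRPCCK", maxMissedCleavages = 1)
  expect_true("AAKRPCCK" %in% d1$sequence)
  expect_equal(d1$missedCleavages[d1$sequence == "AAKRPCCK"], 1L)
  expect_equal(digestProtein("GGG")$sequence, "GGG")
  expect_error(digestProtein(""))
})

test_that("digestion conserves the protein and missed-cleavage peptides are concatenations", {
  set.seed(7)
  for (i in 1:10) {
    prot <- randomPeptide(sample(30:80, 1))
    d <- digestProtein(prot, maxMissedCleavages = 3)
    d0 <- d[d$missedCleavages == 0L, ]
    d0 <- d0[order(d0$start), ]
    expect_identical(paste(d0$sequence, collapse = ""), prot)
    for (k in 1:3) {
      dk <- d[d$missedCleavages == k, ]
      for (j in seq_len(nrow(dk))) {
        segs <- d0[d0$start >= dk$start[j] & d0$end <= dk$end[j], ]
        expect_equal(nrow(segs), k + 1L)
        expect_identical(paste(segs$sequence, collapse = ""),
                         dk$sequence[j])
      }
    }
  }
})

test_that("the shipped scaffolds release the receptor TMD peptides on digestion", {
  subs <- exampleSubunits()
  tmd <- tmdPeptides()
  for (i in seq_len(nrow(tmd))) {
    d <- digestProtein(subs[[tmd$proteinId[i]]], maxMissedCleavages = 3,
                       proteinId = tmd$proteinId[i])
    hit <- d[d$sequence == tmd$sequence[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, tmd$start[i])
    expect_equal(hit$end, tmd$end[i])
  }
})

test_that("adduct registry carries the reagent masses and tag pair spacing", {
  ad <- defaultAdducts()
  expect_equal(ad$KK123@adductMass, 372.16)
  expect_equal(ad$KK200@adductMass, 462.27)
  expect_equal(ad$KK202@adductMass, 500.31)
  expect_equal(ad$KK123_FLI@lightTagMass, 672.4322)
  expect_equal(ad$KK123_FLI@pairDelta, 682.44 - 672.4322)
  expect_equal(defaultAdducts(nominalPairDelta = TRUE)$KK123_FLI@pairDelta,
               10.07, ignore_attr = TRUE)
  ## an inconsistent pairDelta without the override is rejected
  expect_error(AdductSpec("x", 100, lightTagMass = 100, heavyTagMass = 110,
                          pairDelta = 9), "disagrees")
})

test_that("FASTA and JSON config round trip through the readers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">alpha1 synthetic scaffold", exampleSubunits()[["alpha1"]],
               ">beta3 synthetic scaffold", exampleSubunits()[["beta3"]]), fa)
  subs <- readSubunits(fa)
  expect_identical(subs, exampleSubunits())
  cfgFile <- tempfile(fileext = ".json")
  writeLines('{
    "chemistry": {
      "adducts": {"KK123": {"adductMass": 372.27}},
      "modifications": {"nem_dtt": {"deltaMass": 280.0, "specificity": "C"}}
    },
    "search": {"precursorTolPpm": 20, "minRetentionDelayMin": 2}
  }', cfgFile)
  cfg <- readConfig(cfgFile)
  expect_equal(cfg$adducts$KK123@adductMass, 372.27)
  expect_equal(cfg$modifications$nem_dtt@deltaMass, 280.0)
  expect_equal(cfg$params$precursorTolPpm, 20)
  expect_equal(cfg$params$minRetentionDelayMin, 2)
  expect_equal(cfg$params$fragmentTolDa, 0.1)
})
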