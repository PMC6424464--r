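#' Transmembrane-domain peptides carrying known photolabeling sites
#'
#' The four tryptic transmembrane-domain peptides of the human alpha1/beta3
#' GABA-A receptor on which the neurosteroid photolabeling reagents insert,
#' with their protein coordinates, labeled residues and cysteine-alkylation
#' state. These drive the worked examples and the synthetic generator's
#' default study conditions.
#'
#' @return A data.frame with columns proteinId, name, sequence, start, end,
#'   reagent, site (protein coordinate of the labeled residue; for the
#'   three-residue interval the first residue), siteEnd, charge (the charge
#'   state at which the labeled form is observed), fixedModMass (cysteine
#'   alkylation mass present on the peptide) and efficiencyPct (labeling
#'   efficiency at 3 uM reagent used as the generator default).
#' @examples
#' tmdPeptides()
#' @export
tmdPeptides <- function() {
  data.frame(
    proteinId = c("alpha1", "beta3", "alpha1", "beta3", "beta3"),
    name = c("alpha1-TM4", "beta3-TM4", "alpha1-TM4", "beta3-TM3",
             "beta3-TM3"),
    sequence = c(
      "IAFPLLFGIFNLVYWATYLNREPQLK",
      "IVFPFTFSLFNLVYWLYYVN",
      "IAFPLLFGIFNLVYWATYLNREPQLK",
      "AIDMYLMGCFVFVFLALLEYAFVNYIFFGRGPQR",
      "VKAIDMYLMGCFVFVFLALLEYAFVNYIFFGRGPQR"),
    start = c(398L, 426L, 398L, 280L, 278L),
    end = c(423L, 445L, 423L, 313L, 313L),
    reagent = c("KK123", "KK123", "KK200", "KK200", "KK202"),
    site = c(415L, 442L, 408L, 308L, 294L),
    siteEnd = c(415L, 442L, 408L, 309L, 294L),
    charge = c(4L, 3L, 4L, 4L, 6L),
    fixedModMass = c(0, 0, 0, 279.05994, 125.04768),
    efficiencyPct = c(0.77, 0.37, 0.19, 0.19, 0.29),
    stringsAsFactors = FALSE)
}

#' Synthetic subunit scaffold sequences
#'
#' Builds scaffold protein sequences that embed the transmembrane-domain
#' tryptic peptides of \code{\link{tmdPeptides}} at their native residue
#' coordinates. The filler regions are synthetic (GAS-repeat linkers with a
#' lysine placed immediately before each peptide so tryptic digestion
#' releases the peptides at the correct coordinates); they are NOT the real
#' subunit sequences, which are not shipped with the package.
#'
#' @return Named character vector with elements \code{alpha1} and
#'   \code{beta3}.
#' @examples
#' substr(exampleSubunits()[["alpha1"]], 398, 423)
#' @export
exampleSubunits <- function() {
  filler <- function(n) {
    if (n <= 0) return("")
    substr(strrep("GAS", ceiling(n / 3)), 1L, n)
  }
  place <- function(segments, totalEnd) {
    ## segments: list of (start, sequence); K before each start
    out <- ""
    at <- 1L
    for (s in segments) {
      stopifnot(s$start >= at + 1L)
      out <- paste0(out, filler(s$start - at - 1L), "K", s$sequence)
      at <- s$start + nchar(s$sequence)
    }
    if (totalEnd > at - 1L) out <- paste0(out, filler(totalEnd - at + 1L))
    out
  }
  tmd <- tmdPeptides()
  a1 <- place(list(list(start = 398L,
                        sequence = tmd$sequence[tmd$name == "alpha1-TM4"][1L])),
              totalEnd = 430L)
  b3 <- place(list(
    list(start = 278L, sequence = tmd$sequence[tmd$name == "beta3-TM3" &
                                               tmd$reagent == "KK202"][1L]),
    list(start = 426L, sequence = tmd$sequence[tmd$name == "beta3-TM4"][1L])),
    totalEnd = 445L)
  c(alpha1 = a1, beta3 = b3)
}

#' Synthetic-run configuration
#'
#' Describes the LC-MS structure the generator emulates: labeled and
#' unlabeled peptide features with Gaussian elution profiles (labeled
#' features retention-shifted later), optional co-eluting heavy/light tag
#' doublets, and MS2 spectra with partially complete b/y ladders,
#' neutral-loss companions and uniform noise peaks.
#'
#' @param peptides data.frame with columns sequence, proteinId, start,
#'   site (protein coordinate of the true labeled residue), reagent,
#'   efficiencyPct, rtUnlabeled (min), charge, and optionally rtShift
#'   (min, default taken from \code{rtShift}), amplitude and fixedModMass.
#'   Default: the receptor TMD peptides of \code{\link{tmdPeptides}} with
#'   their observed efficiencies, spread along the gradient.
#' @param adducts named list of \linkS4class{AdductSpec} resolving the
#'   \code{reagent} column.
#' @param rtShift default retention delay of the labeled form, minutes.
#' @param sigmaMin Gaussian elution peak width (sigma), minutes.
#' @param scanInterval MS1 scan spacing, minutes.
#' @param rtRange run retention window \code{c(min, max)}, minutes.
#' @param ladderCompleteness probability that a b/y ladder ion is present
#'   in an MS2 spectrum.
#' @param neutralLossFraction probability that an emitted adduct-bearing
#'   ion also appears in neutral-loss form.
#' @param noisePeaks uniform-random noise peaks per MS2 spectrum.
#' @param pairing logical; emit the labeled form as a co-eluting
#'   heavy/light tag doublet (requires tag masses on the adduct).
#' @param mixingRatio heavy:light amplitude ratio when pairing.
#' @param fragmentCharges fragment charges emitted in MS2 ladders, or
#'   \code{NULL} for 1..min(precursor charge - 1, 3).
#' @param amplitude default unlabeled apex intensity (arbitrary units).
#' @param seed integer random seed; identical seeds give identical runs.
#' @return A validated list of class \code{"SyntheticRunConfig"}.
#' @export
syntheticRunConfig <- function(peptides = NULL, adducts = defaultAdducts(),
                               rtShift = 10, sigmaMin = 0.25,
                               scanInterval = 0.05, rtRange = c(0, 40),
                               ladderCompleteness = 0.9,
                               neutralLossFraction = 0.3, noisePeaks = 10,
                               pairing = FALSE, mixingRatio = 1,
                               fragmentCharges = NULL, amplitude = 1e6,
                               seed = 1L) {
  if (is.null(peptides)) {
    tmd <- tmdPeptides()
    peptides <- data.frame(
      sequence = tmd$sequence, proteinId = tmd$proteinId,
      start = tmd$start, site = tmd$site, reagent = tmd$reagent,
      efficiencyPct = tmd$efficiencyPct,
      rtUnlabeled = seq(8, by = 4, length.out = nrow(tmd)),
      charge = tmd$charge, fixedModMass = tmd$fixedModMass,
      stringsAsFactors = FALSE)
  }
  need <- c("sequence", "proteinId", "start", "site", "reagent",
            "efficiencyPct", "rtUnlabeled", "charge")
  miss <- setdiff(need, names(peptides))
  if (length(miss))
    stop("peptide table missing column(s): ", paste(miss, collapse = ", "))
  if (!"rtShift" %in% names(peptides)) peptides$rtShift <- rtShift
  if (!"amplitude" %in% names(peptides)) peptides$amplitude <- amplitude
  if (!"fixedModMass" %in% names(peptides)) peptides$fixedModMass <- 0
  stopifnot(all(peptides$efficiencyPct >= 0),
            all(peptides$efficiencyPct <= 100),
            sigmaMin > 0, scanInterval > 0, diff(rtRange) > 0,
            ladderCompleteness >= 0, ladderCompleteness <= 1,
            neutralLossFraction >= 0, neutralLossFraction <= 1,
            noisePeaks >= 0, mixingRatio > 0,
            all(peptides$reagent %in% names(adducts) |
                peptides$reagent %in%
                  vapply(adducts, function(a) a@reagent, character(1))))
  local <- peptides$site - peptides$start + 1L
  if (any(local < 1L) || any(local > nchar(peptides$sequence)))
    stop("'site' must fall within each peptide's coordinates")
  structure(list(peptides = peptides, adducts = adducts,
                 sigmaMin = sigmaMin, scanInterval = scanInterval,
                 rtRange = rtRange, ladderCompleteness = ladderCompleteness,
                 neutralLossFraction = neutralLossFraction,
                 noisePeaks = noisePeaks, pairing = pairing,
                 mixingRatio = mixingRatio,
                 fragmentCharges = fragmentCharges,
                 seed = as.integer(seed)),
            class = "SyntheticRunConfig")
}

.resolveAdduct <- function(adducts, reagent) {
  if (!is.null(adducts[[reagent]])) return(adducts[[reagent]])
  nm <- vapply(adducts, function(a) a@reagent, character(1))
  hit <- which(nm == reagent)
  if (!length(hit)) stop("unknown reagent: ", reagent)
  adducts[[hit[1L]]]
}

#' Generate a synthetic LC-MS run with ground truth
#'
#' Emits MS1 scans carrying Gaussian elution profiles of unlabeled and
#' labeled peptide features (labeled apex shifted later by the configured
#' retention delay; labeled/unlabeled area ratio equal to the configured
#' efficiency), optional heavy/light tag doublets offset by the pair
#' spacing over the charge, and one MS2 spectrum per labeled species at
#' its elution apex containing each b/y ladder ion with the configured
#' completeness probability, neutral-loss companions of adduct-bearing
#' ions, and uniform noise peaks. The same seed always produces the same
#' run.
#'
#' @param cfg a \code{\link{syntheticRunConfig}}.
#' @return A list with elements \code{run} (an \linkS4class{MSRun}) and
#'   \code{truth} (a list with data.frames \code{peptides},
#'   \code{fragments} and \code{pairs}).
#' @examples
#' cfg <- syntheticRunConfig(seed = 7)
#' out <- generateRun(cfg)
#' out$run
#' @export
generateRun <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticRunConfig"))
  set.seed(cfg$seed)
  rts <- seq(cfg$rtRange[1L], cfg$rtRange[2L], by = cfg$scanInterval)
  nscan <- length(rts)
  scanMz <- vector("list", nscan)
  scanInt <- vector("list", nscan)
  addTrace <- function(mz, apex, A) {
    y <- A * exp(-(rts - apex)^2 / (2 * cfg$sigmaMin^2))
    sel <- which(y > A * 1e-4)
    for (i in sel) {
      scanMz[[i]] <<- c(scanMz[[i]], mz)
      scanInt[[i]] <<- c(scanInt[[i]], y[i])
    }
  }
  tab <- residueMasses()
  truthPep <- list()
  truthFrag <- list()
  truthPair <- list()
  ms2 <- list()
  for (r in seq_len(nrow(cfg$peptides))) {
    p <- cfg$peptides[r, ]
    ad <- .resolveAdduct(cfg$adducts, p$reagent)
    z <- as.integer(p$charge)
    base <- peptideMass(p$sequence, tab) + p$fixedModMass
    mzUn <- mzFromMass(base, z, tab)
    rtLab <- p$rtUnlabeled + p$rtShift
    ampLab <- p$amplitude * p$efficiencyPct / 100
    addTrace(mzUn, p$rtUnlabeled, p$amplitude)
    paired <- cfg$pairing && !is.na(ad@lightTagMass) &&
      !is.na(ad@heavyTagMass)
    localSite <- p$site - p$start + 1L
    fragCharges <- if (is.null(cfg$fragmentCharges))
      seq_len(max(1L, min(z - 1L, 3L))) else cfg$fragmentCharges
    buildLadder <- function(adductMass) {
      theoreticalLadder(
        ModifiedPeptide(Peptide(p$sequence, p$proteinId, start = p$start),
                        if (p$fixedModMass > 0) .fixedModPosition(p$sequence)
                        else integer(0),
                        if (p$fixedModMass > 0)
                          list(ModificationSpec("fixed", p$fixedModMass,
                                                class = "fixed"))
                        else list()),
        AdductSpec(p$reagent, adductMass), localSite, fragCharges,
        includeNeutralLoss = FALSE, table = tab)
    }
    ## the kept-ion / neutral-loss pattern is drawn once per labeled
    ## species so light and heavy tag forms fragment identically
    ladderRows <- nrow(buildLadder(1))
    keep <- stats::runif(ladderRows) < cfg$ladderCompleteness
    nlDraw <- stats::runif(ladderRows) < cfg$neutralLossFraction
    intens <- stats::runif(ladderRows, 0.2, 1) * 1000
    emitMs2 <- function(adductMass, precMz, tag) {
      ions <- buildLadder(adductMass)
      kept <- ions[keep, , drop = FALSE]
      kept$intensity <- intens[keep]
      nl <- kept[kept$carriesAdduct & nlDraw[keep], , drop = FALSE]
      if (nrow(nl)) {
        nl$mz <- nl$mz - adductMass / nl$charge
        nl$neutralLoss <- TRUE
      }
      ions <- rbind(kept, nl)
      noiseMz <- stats::runif(cfg$noisePeaks, 100, 2000)
      noiseInt <- 10^stats::runif(cfg$noisePeaks, 0, log10(1000))
      sp <- Spectrum2(precMz, z, rtLab,
                      mz = c(ions$mz, noiseMz),
                      intensity = c(ions$intensity, noiseInt),
                      scanId = sprintf("ms2_%d_%s", r, tag))
      ms2[[length(ms2) + 1L]] <<- sp
      ions$spectrum <- length(ms2)
      truthFrag[[length(truthFrag) + 1L]] <<-
        ions[, c("spectrum", "series", "index", "charge", "carriesAdduct",
                 "neutralLoss", "mz")]
    }
    if (paired) {
      mzLight <- mzFromMass(base + ad@lightTagMass, z, tab)
      mzHeavy <- mzFromMass(base + ad@heavyTagMass, z, tab)
      addTrace(mzLight, rtLab, ampLab)
      addTrace(mzHeavy, rtLab, ampLab * cfg$mixingRatio)
      emitMs2(ad@lightTagMass, mzLight, "light")
      emitMs2(ad@heavyTagMass, mzHeavy, "heavy")
      truthPair[[length(truthPair) + 1L]] <- data.frame(
        lightMz = mzLight, heavyMz = mzHeavy, charge = z,
        pairDelta = ad@heavyTagMass - ad@lightTagMass, rt = rtLab)
      mzLab <- mzLight
    } else {
      mzLab <- mzFromMass(base + ad@adductMass, z, tab)
      if (ampLab > 0) {
        addTrace(mzLab, rtLab, ampLab)
        emitMs2(ad@adductMass, mzLab, "labeled")
      }
    }
    truthPep[[length(truthPep) + 1L]] <- data.frame(
      sequence = p$sequence, proteinId = p$proteinId, start = p$start,
      site = p$site, sitePeptide = localSite, reagent = p$reagent,
      efficiencyPct = p$efficiencyPct, charge = z, unlabeledMz = mzUn,
      labeledMz = mzLab, rtUnlabeled = p$rtUnlabeled, rtLabeled = rtLab,
      paired = paired, stringsAsFactors = FALSE)
  }
  keep <- vapply(scanMz, length, integer(1)) > 0
  run <- MSRun(
    ms1Rt = rts,
    ms1Peaks = lapply(seq_len(nscan), function(i)
      if (keep[i]) .peakMatrix(scanMz[[i]], scanInt[[i]])
      else .emptyPeaks()),
    ms2 = ms2,
    metadata = list(generator = "photolabelMS", seed = cfg$seed))
  truth <- list(
    peptides = do.call(rbind, truthPep),
    fragments = if (length(truthFrag)) do.call(rbind, truthFrag) else NULL,
    pairs = if (length(truthPair)) do.call(rbind, truthPair) else NULL)
  list(run = run, truth = truth)
}

.fixedModPosition <- function(sequence) {
  pos <- which(strsplit(sequence, "")[[1]] == "C")
  if (!length(pos)) 1L else pos[1L]
}

#' Generate a synthetic electrophysiology peak-current table
#'
#' Draws per-cell peak currents consistent with configured population
#' effects: the potentiation response ratio, direct activation (fraction
#' of the saturating GABA + propofol response) and constitutive open
#' probability. Current magnitudes are truncated at zero; the sign
#' convention is that of recordings at a -60 mV holding potential (agonist
#' currents negative/inward, the picrotoxin shift positive).
#'
#' @param n number of cells (>= 1).
#' @param construct construct label carried onto the rows.
#' @param potentiation list(mean, sd) of the potentiation response ratio.
#' @param activation list(mean, sd) of the direct-activation fraction.
#' @param poConst list(mean, sd) of the constitutive open probability
#'   (values are clipped to [0, 0.99]).
#' @param gabaCurrent list(mean, sd) of the GABA-alone peak magnitude, uA.
#' @param satCurrent saturating GABA + propofol peak magnitude, uA.
#' @param seed integer random seed.
#' @return A data.frame with one row per cell: cell, construct, i_gaba,
#'   i_gaba_mod, i_mod, i_picrotoxin, i_gaba_propofol (signed, uA).
#' @examples
#' generateEphysTable(5, potentiation = list(mean = 4.2, sd = 0), seed = 1)
#' @export
generateEphysTable <- function(n, construct = "wt",
                               potentiation = list(mean = 4.2, sd = 3.3),
                               activation = list(mean = 0.063, sd = 0.038),
                               poConst = list(mean = 0.02, sd = 0.01),
                               gabaCurrent = list(mean = 1, sd = 0.2),
                               satCurrent = 10, seed = 1L) {
  if (n < 1L) stop("'n' must be >= 1")
  for (p in list(potentiation, activation, poConst, gabaCurrent))
    if (!is.finite(p$sd) || p$sd < 0) stop("SDs must be finite and >= 0")
  set.seed(as.integer(seed))
  ## draws are normals truncated at zero; the location is solved so the
  ## configured effect is the population mean of the truncated draws
  truncNorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    truncMean <- function(mu)
      mu + sd * stats::dnorm(mu / sd) / stats::pnorm(mu / sd)
    mu <- stats::uniroot(function(m) truncMean(m) - mean,
                         c(mean - 10 * sd, mean), extendInt = "upX",
                         tol = 1e-10)$root
    x <- stats::rnorm(n, mu, sd)
    while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mu, sd)
    x
  }
  ig <- truncNorm(n, gabaCurrent$mean, gabaCurrent$sd)
  ratio <- truncNorm(n, potentiation$mean, potentiation$sd)
  act <- truncNorm(n, activation$mean, activation$sd)
  po <- pmin(truncNorm(n, poConst$mean, poConst$sd), 0.99)
  iSat <- -abs(satCurrent)
  data.frame(cell = seq_len(n), construct = construct,
             i_gaba = -ig, i_gaba_mod = -ig * ratio,
             i_mod = iSat * act,
             i_picrotoxin = po / (1 - po) * (-iSat),
             i_gaba_propofol = iSat, stringsAsFactors = FALSE)
}
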