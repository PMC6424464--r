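#' Search parameters
#'
#' Tolerances and ranges for MS1 screening and MS2 localization.
#'
#' @param precursorTolPpm MS1 precursor mass tolerance in ppm.
#' @param fragmentTolDa MS2 fragment-ion tolerance in Da (absolute).
#' @param coelutionTolMin apex co-elution tolerance for heavy/light doublet
#'   pairing, minutes.
#' @param minRetentionDelayMin minimum retention delay of a labeled peptide
#'   relative to its unlabeled counterpart, minutes. Covalent neurosteroid
#'   addition increases peptide hydrophobicity, so genuine labeled forms
#'   elute later.
#' @param chargeRange integer charge states considered at MS1.
#' @param pairAbsTolDa absolute floor on the doublet neutral-mass-difference
#'   tolerance, Da.
#' @param intensityFloorFactor feature-calling floor, as a multiple of the
#'   median nonzero XIC intensity.
#' @return A list of class \code{"SearchParams"}.
#' @examples
#' searchParams()
#' @export
searchParams <- function(precursorTolPpm = 30, fragmentTolDa = 0.1,
                         coelutionTolMin = 0.2, minRetentionDelayMin = 1.0,
                         chargeRange = 2:6, pairAbsTolDa = 0.01,
                         intensityFloorFactor = 5) {
  stopifnot(precursorTolPpm > 0, fragmentTolDa > 0, coelutionTolMin > 0,
            minRetentionDelayMin >= 0, length(chargeRange) >= 1,
            all(chargeRange >= 1), pairAbsTolDa >= 0,
            intensityFloorFactor >= 0)
  structure(list(precursorTolPpm = precursorTolPpm,
                 fragmentTolDa = fragmentTolDa,
                 coelutionTolMin = coelutionTolMin,
                 minRetentionDelayMin = minRetentionDelayMin,
                 chargeRange = as.integer(chargeRange),
                 pairAbsTolDa = pairAbsTolDa,
                 intensityFloorFactor = intensityFloorFactor),
            class = "SearchParams")
}

.emptyFeatures <- function() {
  data.frame(targetMz = numeric(0), observedMz = numeric(0),
             charge = integer(0), rtApex = numeric(0), rtMin = numeric(0),
             rtMax = numeric(0), area = numeric(0),
             apexIntensity = numeric(0))
}

#' Detect ion features at targeted m/z values
#'
#' For each target, extracts an XIC and calls local maxima above an
#' intensity floor (a multiple of the median nonzero intensity) as
#' features, with bounds at the nearest flanking minima and trapezoidal
#' areas. The observed m/z is the intensity-weighted mean of the matching
#' peaks at the apex scan.
#'
#' @param run an \linkS4class{MSRun}.
#' @param targets data.frame with columns \code{mz} and \code{z}.
#' @param params a \code{\link{searchParams}} list.
#' @param rtWindow optional retention-time window, minutes.
#' @return A data.frame of features (one row per called peak).
#' @export
detectFeatures <- function(run, targets, params = searchParams(),
                           rtWindow = NULL) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1,
            all(c("mz", "z") %in% names(targets)))
  out <- list()
  for (i in seq_len(nrow(targets))) {
    xic <- extractXIC(run, targets$mz[i], params$precursorTolPpm, rtWindow,
                      charge = targets$z[i])
    fts <- .callPeaks(xic, params$intensityFloorFactor)
    if (!nrow(fts)) next
    fts$observedMz <- vapply(fts$rtApex, function(rt)
      .apexMz(run, rt, targets$mz[i], params$precursorTolPpm), numeric(1))
    fts$targetMz <- targets$mz[i]
    fts$charge <- as.integer(targets$z[i])
    out[[length(out) + 1L]] <- fts
  }
  if (!length(out)) return(.emptyFeatures())
  df <- do.call(rbind, out)
  df[, c("targetMz", "observedMz", "charge", "rtApex", "rtMin", "rtMax",
         "area", "apexIntensity")]
}

.callPeaks <- function(xic, floorFactor) {
  empty <- data.frame(rtApex = numeric(0), rtMin = numeric(0),
                      rtMax = numeric(0), area = numeric(0),
                      apexIntensity = numeric(0))
  y <- xic@intensity
  rt <- xic@rt
  n <- length(y)
  nz <- y[y > 0]
  if (n < 3L || !length(nz)) return(empty)
  floor <- floorFactor * stats::median(nz)
  yl <- c(-Inf, y[-n])
  yr <- c(y[-1L], -Inf)
  apex <- which(y > floor & y >= yl & y > yr)
  if (!length(apex)) return(empty)
  rows <- lapply(apex, function(a) {
    lo <- a
    while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
    hi <- a
    while (hi < n && y[hi + 1L] < y[hi]) hi <- hi + 1L
    seg <- lo:hi
    data.frame(rtApex = rt[a], rtMin = rt[lo], rtMax = rt[hi],
               area = if (length(seg) > 1L)
                 pracma::trapz(rt[seg], y[seg]) else 0,
               apexIntensity = y[a])
  })
  do.call(rbind, rows)
}

.apexMz <- function(run, rtApex, targetMz, tolPpm) {
  i <- which.min(abs(run@ms1Rt - rtApex))
  p <- run@ms1Peaks[[i]]
  tol <- targetMz * tolPpm * 1e-6
  sel <- abs(p[, 1L] - targetMz) <= tol
  if (!any(sel)) return(NA_real_)
  sum(p[sel, 1L] * p[sel, 2L]) / sum(p[sel, 2L])
}

#' Screen for photolabeled peptides at MS1
#'
#' Enumerates peptide x adduct x charge theoretical m/z values, detects
#' matching ion features within the precursor tolerance, and applies the
#' delayed-retention criterion: a labeled hit is kept only if its apex
#' elutes at least \code{minRetentionDelayMin} later than the unlabeled
#' peptide's apex. Hits whose unlabeled counterpart is absent from the run
#' are returned flagged \code{"no-reference"} instead of being dropped.
#'
#' @param run an \linkS4class{MSRun}.
#' @param peptides data.frame as returned by \code{\link{digestProtein}}
#'   (columns sequence, proteinId, start, end).
#' @param adducts list of \linkS4class{AdductSpec}.
#' @param params a \code{\link{searchParams}} list.
#' @param fixedModMass extra fixed-modification mass (Da) added to every
#'   peptide (e.g. cysteine alkylation already positioned upstream).
#' @param table residue mass table.
#' @return A data.frame of candidate hits with columns proteinId, sequence,
#'   start, end, reagent, charge, theoreticalMz, observedMz, ppmError,
#'   rtApex, area, rtDelay, reference ("delayed" or "no-reference").
#' @export
screenLabeled <- function(run, peptides, adducts, params = searchParams(),
                          fixedModMass = 0, table = residueMasses()) {
  stopifnot(is.data.frame(peptides), nrow(peptides) >= 1)
  if (is(adducts, "AdductSpec")) adducts <- list(adducts)
  hits <- list()
  for (p in seq_len(nrow(peptides))) {
    base <- peptideMass(peptides$sequence[p], table) + fixedModMass
    for (ad in adducts) {
      for (z in params$chargeRange) {
        mzLab <- mzFromMass(base + ad@adductMass, z, table)
        lab <- detectFeatures(run, data.frame(mz = mzLab, z = z), params)
        lab <- lab[!is.na(lab$observedMz), , drop = FALSE]
        if (!nrow(lab)) next
        lab <- lab[which.max(lab$area), , drop = FALSE]
        err <- ppmError(lab$observedMz, mzLab)
        if (abs(err) > params$precursorTolPpm) next
        mzUn <- mzFromMass(base, z, table)
        un <- detectFeatures(run, data.frame(mz = mzUn, z = z), params)
        if (nrow(un)) {
          un <- un[which.max(un$area), , drop = FALSE]
          delay <- lab$rtApex - un$rtApex
          if (delay < params$minRetentionDelayMin) next
          ref <- "delayed"
        } else {
          delay <- NA_real_
          ref <- "no-reference"
        }
        hits[[length(hits) + 1L]] <- data.frame(
          proteinId = peptides$proteinId[p],
          sequence = peptides$sequence[p], start = peptides$start[p],
          end = peptides$end[p], reagent = ad@reagent, charge = z,
          theoreticalMz = mzLab, observedMz = lab$observedMz,
          ppmError = err, rtApex = lab$rtApex, area = lab$area,
          rtDelay = delay, reference = ref, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(proteinId = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      reagent = character(0), charge = integer(0),
                      theoreticalMz = numeric(0), observedMz = numeric(0),
                      ppmError = numeric(0), rtApex = numeric(0),
                      area = numeric(0), rtDelay = numeric(0),
                      reference = character(0)))
  df <- do.call(rbind, hits)
  rownames(df) <- NULL
  df
}

#' Find heavy/light isotope-tag doublets
#'
#' Pairs ion features of equal charge whose neutral-mass difference matches
#' the tag pair spacing within tolerance and whose apexes co-elute. Each
#' feature joins at most one pair; assignment is greedy by smallest
#' combined mass + retention error with a deterministic tie-break by
#' ascending m/z, so the result does not depend on the input order.
#'
#' @param features data.frame from \code{\link{detectFeatures}}.
#' @param pairDelta expected heavy-light neutral-mass spacing, Da (> 0).
#' @param params a \code{\link{searchParams}} list; the mass tolerance is
#'   the precursor ppm tolerance applied to the neutral mass with an
#'   absolute floor of \code{pairAbsTolDa}.
#' @param table residue mass table (proton mass).
#' @return A data.frame of doublet pairs: lightMz, heavyMz, charge,
#'   massDiff (neutral Da), rtOffset (heavy - light apex, min), lightArea,
#'   heavyArea, intensityRatio (heavy/light area).
#' @export
findDoublets <- function(features, pairDelta, params = searchParams(),
                         table = residueMasses()) {
  stopifnot(pairDelta > 0)
  empty <- data.frame(lightMz = numeric(0), heavyMz = numeric(0),
                      charge = integer(0), massDiff = numeric(0),
                      rtOffset = numeric(0), lightArea = numeric(0),
                      heavyArea = numeric(0), intensityRatio = numeric(0))
  features <- features[!is.na(features$observedMz), , drop = FALSE]
  if (!nrow(features)) return(empty)
  ft <- features[order(features$observedMz, features$rtApex), , drop = FALSE]
  mass <- massFromMz(ft$observedMz, ft$charge, table)
  n <- nrow(ft)
  cand <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (ft$charge[i] != ft$charge[j]) next
    d <- abs(mass[j] - mass[i])
    tol <- max(params$pairAbsTolDa,
               max(mass[i], mass[j]) * params$precursorTolPpm * 1e-6)
    if (abs(d - pairDelta) > tol) next
    dt <- ft$rtApex[j] - ft$rtApex[i]
    if (abs(dt) > params$coelutionTolMin) next
    lo <- if (mass[i] <= mass[j]) i else j
    hi <- if (mass[i] <= mass[j]) j else i
    cand[[length(cand) + 1L]] <- data.frame(
      light = lo, heavy = hi,
      err = abs(d - pairDelta) / tol + abs(dt) / params$coelutionTolMin)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$err, ft$observedMz[cand$light],
                     ft$observedMz[cand$heavy]), , drop = FALSE]
  used <- logical(n)
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$light[k]; j <- cand$heavy[k]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      lightMz = ft$observedMz[i], heavyMz = ft$observedMz[j],
      charge = ft$charge[i], massDiff = mass[j] - mass[i],
      rtOffset = ft$rtApex[j] - ft$rtApex[i], lightArea = ft$area[i],
      heavyArea = ft$area[j],
      intensityRatio = if (ft$area[i] > 0) ft$area[j] / ft$area[i]
                       else NA_real_)
  }
  df <- do.call(rbind, pairs)
  df <- df[order(df$lightMz), , drop = FALSE]
  rownames(df) <- NULL
  df
}
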