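#' Theoretical b/y fragment-ion ladder
#'
#' Builds singly to multiply protonated b and y ions for a peptide with an
#' adduct at a candidate placement. An ion carries the adduct iff the
#' placement falls within its residue span; when requested, each
#' adduct-bearing ion is also emitted in its neutral-loss form (adduct mass
#' subtracted), reflecting the tendency of sterol adducts to detach during
#' fragmentation.
#'
#' @param peptide a \linkS4class{Peptide}, \linkS4class{ModifiedPeptide}
#'   (non-adduct modifications, e.g. cysteine alkylation, are kept on their
#'   residues), or a sequence string.
#' @param adduct an \linkS4class{AdductSpec}, or \code{NULL} for an
#'   unmodified ladder.
#' @param placement 1-based within-peptide index of the candidate labeled
#'   residue (ignored when \code{adduct} is \code{NULL}).
#' @param charges integer vector of fragment charges.
#' @param includeNeutralLoss logical; emit neutral-loss companions of
#'   adduct-bearing ions.
#' @param table residue mass table.
#' @return A data.frame with columns series ("b"/"y"), index, charge,
#'   carriesAdduct, neutralLoss, mz, spanStart, spanEnd (within-peptide
#'   residue span of the ion).
#' @examples
#' theoreticalLadder("AGK", NULL)
#' @export
theoreticalLadder <- function(peptide, adduct = NULL, placement = NA_integer_,
                              charges = 1L, includeNeutralLoss = FALSE,
                              table = residueMasses()) {
  mp <- if (is(peptide, "ModifiedPeptide")) peptide else ModifiedPeptide(peptide)
  seqstr <- mp@peptide@sequence
  L <- nchar(seqstr)
  if (L < 2L) stop("peptide must have at least 2 residues")
  if (!is.null(adduct)) {
    placement <- as.integer(placement)
    if (is.na(placement) || placement < 1L || placement > L)
      stop("'placement' must be a residue index in 1..", L)
  }
  resMass <- .residueVector(seqstr, table)
  for (k in seq_along(mp@mods))            # fixed / positioned mods
    resMass[mp@modPositions[k]] <- resMass[mp@modPositions[k]] +
      .modDelta(mp@mods[[k]])
  pre <- cumsum(resMass)
  idx <- seq_len(L - 1L)
  rows <- list()
  for (z in as.integer(charges)) {
    bNeutral <- pre[idx]                   # b_i neutral residue sum
    yNeutral <- pre[L] - pre[L - idx] + table$water
    bAdduct <- !is.null(adduct) & placement <= idx
    yAdduct <- !is.null(adduct) & placement > L - idx
    am <- if (is.null(adduct)) 0 else adduct@adductMass
    rows[[length(rows) + 1L]] <- data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = c(idx, idx), charge = z,
      carriesAdduct = c(bAdduct, yAdduct), neutralLoss = FALSE,
      mz = c((bNeutral + am * bAdduct + z * table$proton) / z,
             (yNeutral + am * yAdduct + z * table$proton) / z),
      spanStart = c(rep(1L, L - 1L), L - idx + 1L),
      spanEnd = c(idx, rep(L, L - 1L)), stringsAsFactors = FALSE)
    if (includeNeutralLoss && !is.null(adduct)) {
      nl <- rows[[length(rows)]]
      nl <- nl[nl$carriesAdduct, , drop = FALSE]
      if (nrow(nl)) {
        nl$mz <- nl$mz - am / z
        nl$neutralLoss <- TRUE
        rows[[length(rows) + 1L]] <- nl
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match theoretical fragment ions to a spectrum
#'
#' Each theoretical ion is matched to the nearest peak within an absolute
#' m/z tolerance. A single peak may satisfy several isobaric ions; the peak
#' index is recorded so scoring can avoid double counting.
#'
#' @param spec a \linkS4class{Spectrum2}.
#' @param ions data.frame from \code{\link{theoreticalLadder}}.
#' @param tolDa absolute fragment tolerance in Da (> 0).
#' @return The matched subset of \code{ions} with added columns
#'   \code{observedMz}, \code{error} (observed - theoretical) and
#'   \code{peak} (index into the spectrum's peak matrix).
#' @export
matchFragments <- function(spec, ions, tolDa = 0.1) {
  stopifnot(tolDa > 0)
  pk <- spec@peaks
  if (!nrow(pk) || !nrow(ions)) {
    ions$observedMz <- numeric(0); ions$error <- numeric(0)
    ions$peak <- integer(0)
    return(ions[integer(0), , drop = FALSE])
  }
  near <- findInterval(ions$mz, pk[, 1L])
  best <- integer(nrow(ions))
  for (i in seq_len(nrow(ions))) {
    cand <- c(near[i], near[i] + 1L)
    cand <- cand[cand >= 1L & cand <= nrow(pk)]
    d <- abs(pk[cand, 1L] - ions$mz[i])
    j <- cand[which.min(d)]
    best[i] <- if (length(j) && abs(pk[j, 1L] - ions$mz[i]) <= tolDa) j else NA_integer_
  }
  keep <- !is.na(best)
  out <- ions[keep, , drop = FALSE]
  out$observedMz <- pk[best[keep], 1L]
  out$error <- out$observedMz - out$mz
  out$peak <- best[keep]
  rownames(out) <- NULL
  out
}

#' Localize an adduct within a peptide from one MS2 spectrum
#'
#' Scores every candidate placement 1..L by the number of distinct spectrum
#' peaks explained by that placement's b/y ladder. Adduct-bearing matched
#' ions constrain the site to their residue span and adduct-free matched
#' ions exclude theirs (this falls out of the per-placement ladders:
#' a peak only matches placements for which the ion's adduct status gives
#' the right m/z). Neutral-loss ions support peptide identity but carry
#' weight zero in localization. The reported interval is the minimal
#' within-peptide interval covering all placements that achieve the
#' maximal score; ties are reported as the union interval rather than an
#' arbitrary single residue.
#'
#' @param spec a \linkS4class{Spectrum2}.
#' @param peptide a \linkS4class{Peptide}, \linkS4class{ModifiedPeptide}
#'   (for fixed modifications) or sequence string.
#' @param adduct an \linkS4class{AdductSpec}.
#' @param params a \code{\link{searchParams}} list (fragment tolerance,
#'   precursor tolerance).
#' @param charges fragment charges considered; default 1..min(precursor
#'   charge - 1, 3), at least 1.
#' @param table residue mass table.
#' @return A \linkS4class{LocalizationResult}.
#' @export
localizeSite <- function(spec, peptide, adduct, params = searchParams(),
                         charges = NULL, table = residueMasses()) {
  mp <- if (is(peptide, "ModifiedPeptide")) peptide else ModifiedPeptide(peptide)
  L <- nchar(mp@peptide@sequence)
  if (L < 2L) stop("peptide must have at least 2 residues")
  if (is.null(charges))
    charges <- seq_len(max(1L, min(spec@precursorCharge - 1L, 3L)))
  expMz <- mzFromMass(peptideMass(mp, table) + adduct@adductMass,
                      spec@precursorCharge, table)
  if (abs(ppmError(spec@precursorMz, expMz)) > params$precursorTolPpm)
    warning(sprintf(
      "precursor m/z %.4f is inconsistent with peptide + adduct (expected %.4f)",
      spec@precursorMz, expMz))
  score <- numeric(L)
  bearing <- numeric(L)
  bestMatch <- vector("list", L)
  for (pos in seq_len(L)) {
    ions <- theoreticalLadder(mp, adduct, pos, charges,
                              includeNeutralLoss = TRUE, table = table)
    m <- matchFragments(spec, ions, params$fragmentTolDa)
    ## a peak explainable as a neutral-loss ion of this placement is not
    ## site evidence for it (neutral loss restores the unmodified
    ## fragment mass, so such peaks carry localization weight zero)
    nlPeaks <- unique(m$peak[m$neutralLoss])
    sitePeaks <- setdiff(unique(m$peak[!m$neutralLoss]), nlPeaks)
    score[pos] <- length(sitePeaks)
    bearing[pos] <- length(setdiff(
      unique(m$peak[m$carriesAdduct & !m$neutralLoss]), nlPeaks))
    bestMatch[[pos]] <- m
  }
  if (max(bearing) == 0) {
    ## no adduct-bearing fragment matches under any placement: the
    ## spectrum supports the peptide but carries no site evidence
    best <- seq_len(L)
  } else {
    best <- which(score == max(score))
  }
  a <- min(best); b <- max(best)
  m <- bestMatch[[a]]
  counts <- c(
    adductBearing = length(unique(m$peak[m$carriesAdduct & !m$neutralLoss])),
    adductFree = length(unique(m$peak[!m$carriesAdduct & !m$neutralLoss])),
    neutralLoss = length(unique(m$peak[m$neutralLoss])))
  new("LocalizationResult", peptide = mp@peptide, reagent = adduct@reagent,
      intervalStart = mp@peptide@start + a - 1L,
      intervalEnd = mp@peptide@start + b - 1L,
      matchedIons = m, counts = counts, placementScore = score)
}

#' Verify a localization against a heavy/light spectrum pair
#'
#' For an isotope-tagged adduct, corresponding fragment ions from the light
#' and heavy spectra must differ by the tag spacing divided by the fragment
#' charge when they carry the adduct, and must coincide when they do not.
#' Both conditions are required, and at least one adduct-bearing fragment
#' must be common to the two spectra, for a \code{"verified"} verdict.
#'
#' @param light,heavy \linkS4class{Spectrum2} objects assigned to the same
#'   peptide and placement.
#' @param peptide a \linkS4class{Peptide}, \linkS4class{ModifiedPeptide} or
#'   sequence string.
#' @param adduct an \linkS4class{AdductSpec} with light and heavy tag
#'   masses.
#' @param placement 1-based within-peptide index of the labeled residue.
#' @param params a \code{\link{searchParams}} list.
#' @param charges fragment charges considered (default as in
#'   \code{\link{localizeSite}}, from the light precursor charge).
#' @param table residue mass table.
#' @return A list with elements \code{verdict} ("verified" or
#'   "inconsistent") and \code{pairs}, a data.frame of common matched
#'   fragments with light/heavy observed m/z, observed difference and the
#'   expected difference.
#' @export
overlayVerify <- function(light, heavy, peptide, adduct, placement,
                          params = searchParams(), charges = NULL,
                          table = residueMasses()) {
  if (is.na(adduct@lightTagMass) || is.na(adduct@heavyTagMass))
    stop("'adduct' must carry light and heavy tag masses")
  mp <- if (is(peptide, "ModifiedPeptide")) peptide else ModifiedPeptide(peptide)
  if (is.null(charges))
    charges <- seq_len(max(1L, min(light@precursorCharge - 1L, 3L)))
  adLight <- AdductSpec(adduct@reagent, adduct@lightTagMass)
  adHeavy <- AdductSpec(adduct@reagent, adduct@heavyTagMass)
  ionsL <- theoreticalLadder(mp, adLight, placement, charges,
                             includeNeutralLoss = FALSE, table = table)
  ionsH <- theoreticalLadder(mp, adHeavy, placement, charges,
                             includeNeutralLoss = FALSE, table = table)
  mL <- matchFragments(light, ionsL, params$fragmentTolDa)
  mH <- matchFragments(heavy, ionsH, params$fragmentTolDa)
  key <- function(m) paste(m$series, m$index, m$charge)
  common <- intersect(key(mL), key(mH))
  if (!length(common))
    return(list(verdict = "inconsistent",
                pairs = data.frame(series = character(0), index = integer(0),
                                   charge = integer(0),
                                   carriesAdduct = logical(0),
                                   lightMz = numeric(0), heavyMz = numeric(0),
                                   observedDiff = numeric(0),
                                   expectedDiff = numeric(0))))
  iL <- match(common, key(mL))
  iH <- match(common, key(mH))
  pd <- adduct@heavyTagMass - adduct@lightTagMass
  pairs <- data.frame(
    series = mL$series[iL], index = mL$index[iL], charge = mL$charge[iL],
    carriesAdduct = mL$carriesAdduct[iL],
    lightMz = mL$observedMz[iL], heavyMz = mH$observedMz[iH],
    observedDiff = mH$observedMz[iH] - mL$observedMz[iL],
    expectedDiff = ifelse(mL$carriesAdduct[iL],
                          pd / mL$charge[iL], 0),
    stringsAsFactors = FALSE)
  ok <- abs(pairs$observedDiff - pairs$expectedDiff) <= params$fragmentTolDa
  ## an adduct-free fragment seen in the light spectrum must reappear at
  ## the same m/z in the heavy spectrum; a shifted or missing counterpart
  ## contradicts the tag-only mass difference
  freeLightOnly <- setdiff(key(mL)[!mL$carriesAdduct], key(mH))
  verdict <- if (all(ok) && any(pairs$carriesAdduct) &&
                 !length(freeLightOnly)) "verified" else "inconsistent"
  list(verdict = verdict, pairs = pairs)
}
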