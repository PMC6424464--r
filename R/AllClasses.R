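#' @import methods
NULL

#' Modification specification
#'
#' A fixed or variable covalent modification: a name, a monoisotopic delta
#' mass in Da, and a residue specificity (one-letter codes, or \code{"any"}).
#'
#' @slot name character(1) modification name.
#' @slot deltaMass numeric(1) monoisotopic mass shift in Da.
#' @slot specificity character vector of one-letter residue codes, or
#'   \code{"any"}.
#' @slot modClass character(1), \code{"fixed"} or \code{"variable"}.
#' @export
setClass("ModificationSpec",
  representation(name = "character", deltaMass = "numeric",
                 specificity = "character", modClass = "character"),
  prototype(specificity = "any", modClass = "variable"))

setValidity("ModificationSpec", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@deltaMass) != 1L || !is.finite(object@deltaMass))
    msg <- c(msg, "'deltaMass' must be a single finite number")
  if (length(object@specificity) < 1L)
    msg <- c(msg, "'specificity' must be non-empty")
  if (!object@modClass %in% c("fixed", "variable"))
    msg <- c(msg, "'modClass' must be \"fixed\" or \"variable\"")
  if (is.null(msg)) TRUE else msg
})

#' Photoreagent adduct specification
#'
#' Describes a photoaffinity reagent adduct: the monoisotopic adduct mass
#' added to a labeled residue and, for click-tagged reagents, the light and
#' heavy isotope-tag masses whose difference (\code{pairDelta}) produces
#' co-eluting MS1 doublets.
#'
#' @slot reagent character(1) reagent name.
#' @slot adductMass numeric(1) monoisotopic adduct mass in Da (> 0). For a
#'   tagged reagent this is the light-tag form.
#' @slot lightTagMass,heavyTagMass numeric(1) tagged adduct masses in Da, or
#'   \code{NA} for untagged reagents.
#' @slot pairDelta numeric(1) heavy-light mass spacing in Da, or \code{NA}.
#' @export
setClass("AdductSpec",
  representation(reagent = "character", adductMass = "numeric",
                 lightTagMass = "numeric", heavyTagMass = "numeric",
                 pairDelta = "numeric"),
  prototype(lightTagMass = NA_real_, heavyTagMass = NA_real_,
            pairDelta = NA_real_))

setValidity("AdductSpec", function(object) {
  msg <- NULL
  if (length(object@reagent) != 1L || !nzchar(object@reagent))
    msg <- c(msg, "'reagent' must be a single non-empty string")
  if (length(object@adductMass) != 1L || !is.finite(object@adductMass) ||
      object@adductMass <= 0)
    msg <- c(msg, "'adductMass' must be a single positive number")
  if (!is.na(object@lightTagMass) && !is.na(object@heavyTagMass) &&
      !is.na(object@pairDelta)) {
    implied <- object@heavyTagMass - object@lightTagMass
    if (abs(object@pairDelta - implied) > 1e-6 &&
        !isTRUE(attr(object@pairDelta, "override")))
      msg <- c(msg, sprintf(
        "pairDelta (%.6f) disagrees with heavy - light tag masses (%.6f)",
        object@pairDelta, implied))
  }
  if (is.null(msg)) TRUE else msg
})

#' Tryptic peptide with protein coordinates
#'
#' @slot sequence character(1) residue string (standard one-letter codes).
#' @slot proteinId character(1) identifier of the parent protein.
#' @slot start,end integer(1) 1-based inclusive positions in protein
#'   coordinates.
#' @slot missedCleavages integer(1) internal missed-cleavage count.
#' @export
setClass("Peptide",
  representation(sequence = "character", proteinId = "character",
                 start = "integer", end = "integer",
                 missedCleavages = "integer"),
  prototype(proteinId = NA_character_, start = 1L, missedCleavages = 0L))

setValidity("Peptide", function(object) {
  msg <- NULL
  n <- nchar(object@sequence)
  if (length(object@sequence) != 1L || n < 1L)
    msg <- c(msg, "'sequence' must be a single non-empty string")
  else {
    res <- strsplit(object@sequence, "")[[1]]
    bad <- which(!res %in% names(.AA_MONO))
    if (length(bad))
      msg <- c(msg, sprintf("unknown residue letter '%s' at position %d",
                            res[bad[1L]], bad[1L]))
    if (object@end - object@start + 1L != n)
      msg <- c(msg, "end - start + 1 must equal the sequence length")
  }
  if (object@missedCleavages < 0L)
    msg <- c(msg, "'missedCleavages' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Peptide with positioned modifications
#'
#' A \linkS4class{Peptide} plus a list of positioned modifications
#' (\linkS4class{ModificationSpec} or \linkS4class{AdductSpec}), each at a
#' 1-based within-peptide index. At most one adduct per peptide.
#'
#' @slot peptide a \linkS4class{Peptide}.
#' @slot modPositions integer vector of 1-based within-peptide positions.
#' @slot mods list of \linkS4class{ModificationSpec} / \linkS4class{AdductSpec}
#'   parallel to \code{modPositions}.
#' @export
setClass("ModifiedPeptide",
  representation(peptide = "Peptide", modPositions = "integer",
                 mods = "list"))

setValidity("ModifiedPeptide", function(object) {
  msg <- NULL
  L <- nchar(object@peptide@sequence)
  if (length(object@modPositions) != length(object@mods))
    msg <- c(msg, "'modPositions' and 'mods' lengths differ")
  if (length(object@modPositions) &&
      (any(object@modPositions < 1L) || any(object@modPositions > L)))
    msg <- c(msg, sprintf("modification position out of range 1..%d", L))
  ok <- vapply(object@mods, function(m)
    is(m, "ModificationSpec") || is(m, "AdductSpec"), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "mods must be ModificationSpec or AdductSpec objects")
  nAdduct <- sum(vapply(object@mods, is, logical(1), class2 = "AdductSpec"))
  if (nAdduct > 1L)
    msg <- c(msg, "at most one adduct per peptide is supported")
  if (is.null(msg)) TRUE else msg
})

#' MS2 fragmentation spectrum
#'
#' Centroided product-ion spectrum with precursor annotation. Peaks are
#' stored as a two-column matrix (\code{mz}, \code{intensity}) with strictly
#' increasing m/z.
#'
#' @slot precursorMz numeric(1) precursor m/z (> 0).
#' @slot precursorCharge integer(1) precursor charge (>= 1).
#' @slot rt numeric(1) retention time in minutes.
#' @slot peaks numeric matrix with columns \code{mz}, \code{intensity}.
#' @slot scanId character(1) optional scan identifier.
#' @export
setClass("Spectrum2",
  representation(precursorMz = "numeric", precursorCharge = "integer",
                 rt = "numeric", peaks = "matrix", scanId = "character"),
  prototype(scanId = NA_character_))

setValidity("Spectrum2", function(object) {
  msg <- NULL
  if (object@precursorMz <= 0) msg <- c(msg, "precursor m/z must be > 0")
  if (object@precursorCharge < 1L) msg <- c(msg, "precursor charge must be >= 1")
  msg <- c(msg, .validPeaks(object@peaks))
  if (is.null(msg)) TRUE else msg
})

.validPeaks <- function(pk) {
  msg <- NULL
  if (!is.numeric(pk) || ncol(pk) != 2L)
    return("peaks must be a numeric matrix with columns mz, intensity")
  if (nrow(pk) > 1L && any(diff(pk[, 1L]) <= 0))
    msg <- c(msg, "peak m/z values must be strictly increasing")
  if (nrow(pk) && any(pk[, 2L] < 0))
    msg <- c(msg, "peak intensities must be >= 0")
  msg
}

#' An LC-MS run
#'
#' Ordered MS1 scans (retention time plus centroided peak list) and a
#' collection of \linkS4class{Spectrum2} objects.
#'
#' @slot ms1Rt numeric vector of MS1 retention times in minutes,
#'   non-decreasing.
#' @slot ms1Peaks list of peak matrices (columns \code{mz},
#'   \code{intensity}), parallel to \code{ms1Rt}.
#' @slot ms2 list of \linkS4class{Spectrum2}.
#' @slot metadata list (source path, format, free-form entries).
#' @export
setClass("MSRun",
  representation(ms1Rt = "numeric", ms1Peaks = "list", ms2 = "list",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("MSRun", function(object) {
  msg <- NULL
  if (length(object@ms1Rt) != length(object@ms1Peaks))
    msg <- c(msg, "'ms1Rt' and 'ms1Peaks' lengths differ")
  if (length(object@ms1Rt) > 1L && any(diff(object@ms1Rt) < 0))
    msg <- c(msg, "MS1 retention times must be non-decreasing")
  for (pk in object@ms1Peaks) msg <- c(msg, .validPeaks(pk))
  ok <- vapply(object@ms2, is, logical(1), class2 = "Spectrum2")
  if (length(ok) && !all(ok))
    msg <- c(msg, "'ms2' must contain Spectrum2 objects")
  if (is.null(msg)) TRUE else unique(msg)
})

#' Extracted-ion chromatogram
#'
#' Intensity versus retention time within a narrow m/z window around a
#' target.
#'
#' @slot rt numeric vector of retention times (minutes), non-decreasing.
#' @slot intensity numeric vector parallel to \code{rt}.
#' @slot targetMz numeric(1) target m/z.
#' @slot tolPpm numeric(1) extraction tolerance in ppm.
#' @slot charge integer(1) assumed charge (may be \code{NA}).
#' @export
setClass("Chromatogram",
  representation(rt = "numeric", intensity = "numeric", targetMz = "numeric",
                 tolPpm = "numeric", charge = "integer"),
  prototype(charge = NA_integer_))

setValidity("Chromatogram", function(object) {
  msg <- NULL
  if (length(object@rt) != length(object@intensity))
    msg <- c(msg, "'rt' and 'intensity' lengths differ")
  if (length(object@rt) > 1L && any(diff(object@rt) < 0))
    msg <- c(msg, "'rt' must be non-decreasing")
  if (is.null(msg)) TRUE else msg
})

#' Adduct localization result
#'
#' The minimal residue interval (protein coordinates) consistent with the
#' site-defining fragment ions matched in one MS2 spectrum, plus per-residue
#' placement scores and matched-ion bookkeeping.
#'
#' @slot peptide the \linkS4class{Peptide} the spectrum was assigned to.
#' @slot reagent character(1) adduct reagent name.
#' @slot intervalStart,intervalEnd integer(1) localized interval in protein
#'   coordinates (equal for a unique site).
#' @slot matchedIons data.frame of matched fragment ions for the best
#'   placements (series, index, charge, carriesAdduct, neutralLoss,
#'   theoretical and observed m/z, error).
#' @slot counts named integer vector: matched adduct-bearing, adduct-free
#'   and neutral-loss ions at the best placement.
#' @slot placementScore numeric vector, consistency score per candidate
#'   residue (within-peptide order).
#' @export
setClass("LocalizationResult",
  representation(peptide = "Peptide", reagent = "character",
                 intervalStart = "integer", intervalEnd = "integer",
                 matchedIons = "data.frame", counts = "integer",
                 placementScore = "numeric"))

setValidity("LocalizationResult", function(object) {
  msg <- NULL
  if (object@intervalStart > object@intervalEnd)
    msg <- c(msg, "intervalStart must be <= intervalEnd")
  if (object@intervalStart < object@peptide@start ||
      object@intervalEnd > object@peptide@end)
    msg <- c(msg, "interval must lie within the peptide's coordinates")
  if (is.null(msg)) TRUE else msg
})

## -- show methods ----------------------------------------------------------

setMethod("show", "AdductSpec", function(object) {
  cat("AdductSpec:", object@reagent, sprintf("(+%.4f Da)", object@adductMass))
  if (!is.na(object@pairDelta))
    cat(sprintf(" light/heavy tags %.4f/%.4f, pair delta %.4f Da",
                object@lightTagMass, object@heavyTagMass, object@pairDelta))
  cat("\n")
})

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide %s %d-%d (%d aa, %d missed cleavage%s)\n  %s\n",
              object@proteinId, object@start, object@end,
              nchar(object@sequence), object@missedCleavages,
              if (object@missedCleavages == 1L) "" else "s",
              object@sequence))
})

setMethod("show", "ModifiedPeptide", function(object) {
  show(object@peptide)
  if (length(object@mods)) {
    lab <- vapply(seq_along(object@mods), function(i) {
      m <- object@mods[[i]]
      nm <- if (is(m, "AdductSpec")) m@reagent else m@name
      dm <- if (is(m, "AdductSpec")) m@adductMass else m@deltaMass
      sprintf("%s@%d (+%.4f)", nm, object@modPositions[i], dm)
    }, character(1))
    cat("  mods:", paste(lab, collapse = ", "), "\n")
  } else cat("  no modifications\n")
})

setMethod("show", "Spectrum2", function(object) {
  cat(sprintf(
    "Spectrum2: precursor m/z %.4f (z = %d), rt %.2f min, %d peaks\n",
    object@precursorMz, object@precursorCharge, object@rt,
    nrow(object@peaks)))
})

setMethod("show", "MSRun", function(object) {
  cat(sprintf("MSRun: %d MS1 scans, %d MS2 spectra",
              length(object@ms1Rt), length(object@ms2)))
  if (length(object@ms1Rt))
    cat(sprintf(", rt %.2f-%.2f min", min(object@ms1Rt), max(object@ms1Rt)))
  cat("\n")
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf(
    "Chromatogram: target m/z %.4f (+/- %.1f ppm), %d points, area %.3g\n",
    object@targetMz, object@tolPpm, length(object@rt),
    integrateArea(object)))
})

setMethod("show", "LocalizationResult", function(object) {
  site <- if (object@intervalStart == object@intervalEnd)
    as.character(object@intervalStart)
  else paste0("[", object@intervalStart, ",", object@intervalEnd, "]")
  cat(sprintf(
    "LocalizationResult: %s adduct on %s residue %s (%d adduct-bearing, %d adduct-free, %d neutral-loss ions matched)\n",
    object@reagent, object@peptide@proteinId, site,
    object@counts[["adductBearing"]], object@counts[["adductFree"]],
    object@counts[["neutralLoss"]]))
})

## -- accessors -------------------------------------------------------------

#' Accessors for photolabelMS classes
#'
#' Small accessor functions for the core S4 containers; use these instead
#' of reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases peptideSequence proteinId peptideStart peptideEnd ms1ScanTimes
#'   ms1PeakLists ms2Spectra runMetadata precursorMz precursorCharge
#'   retentionTime peakMatrix chromRt chromIntensity localizedInterval
#'   placementScores matchedIons
NULL

#' @rdname accessors
#' @export
peptideSequence <- function(x) {
  if (is(x, "ModifiedPeptide")) x@peptide@sequence else x@sequence
}

#' @rdname accessors
#' @export
proteinId <- function(x) {
  if (is(x, "ModifiedPeptide")) x@peptide@proteinId else x@proteinId
}

#' @rdname accessors
#' @export
peptideStart <- function(x) {
  if (is(x, "ModifiedPeptide")) x@peptide@start else x@start
}

#' @rdname accessors
#' @export
peptideEnd <- function(x) {
  if (is(x, "ModifiedPeptide")) x@peptide@end else x@end
}

#' @rdname accessors
#' @export
ms1ScanTimes <- function(x) x@ms1Rt

#' @rdname accessors
#' @export
ms1PeakLists <- function(x) x@ms1Peaks

#' @rdname accessors
#' @export
ms2Spectra <- function(x) x@ms2

#' @rdname accessors
#' @export
runMetadata <- function(x) x@metadata

#' @rdname accessors
#' @export
precursorMz <- function(x) x@precursorMz

#' @rdname accessors
#' @export
precursorCharge <- function(x) x@precursorCharge

#' @rdname accessors
#' @export
retentionTime <- function(x) x@rt

#' @rdname accessors
#' @export
peakMatrix <- function(x) x@peaks

#' @rdname accessors
#' @export
chromRt <- function(x) x@rt

#' @rdname accessors
#' @export
chromIntensity <- function(x) x@intensity

#' @rdname accessors
#' @export
localizedInterval <- function(x) c(x@intervalStart, x@intervalEnd)

#' @rdname accessors
#' @export
placementScores <- function(x) x@placementScore

#' @rdname accessors
#' @export
matchedIons <- function(x) x@matchedIons
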