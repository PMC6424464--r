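#' Labeling efficiency from XIC areas
#'
#' XIC area of the photolabeled peptide as a percentage of the unlabeled
#' peptide's XIC area.
#'
#' @param labeledArea XIC area of the labeled form (>= 0).
#' @param unlabeledArea XIC area of the unlabeled form (> 0).
#' @return Efficiency in percent: \code{100 * labeledArea / unlabeledArea}.
#' @examples
#' labelingEfficiency(1, 100)  # 1 percent
#' @export
labelingEfficiency <- function(labeledArea, unlabeledArea) {
  if (any(unlabeledArea <= 0))
    stop("'unlabeledArea' must be > 0 (undefined denominator)")
  100 * labeledArea / unlabeledArea
}

#' Labeling efficiency measured from a run
#'
#' Extracts the labeled and unlabeled XICs of a peptide at the best
#' charge state (the one with the largest unlabeled feature area, so the
#' comparison stays within a single ionization channel), integrates both,
#' and reports the area ratio as percent. When no labeled feature is found
#' the efficiency is 0 with \code{detected = FALSE}; an absent unlabeled
#' reference is an error because the denominator is undefined.
#'
#' @param run an \linkS4class{MSRun}.
#' @param peptide a \linkS4class{Peptide}, sequence string, or one-row
#'   data.frame from \code{\link{digestProtein}}.
#' @param adduct an \linkS4class{AdductSpec}.
#' @param params a \code{\link{searchParams}} list.
#' @param charges charge states to consider (default from \code{params}).
#' @param fixedModMass extra fixed-modification mass in Da.
#' @param condition,replicate labels carried onto the result row.
#' @param table residue mass table.
#' @return One-row data.frame: proteinId, sequence, start, end, reagent,
#'   charge, labeledArea, unlabeledArea, efficiencyPct, detected,
#'   condition, replicate.
#' @export
efficiencyFromRun <- function(run, peptide, adduct, params = searchParams(),
                              charges = params$chargeRange,
                              fixedModMass = 0, condition = NA_character_,
                              replicate = NA_integer_,
                              table = residueMasses()) {
  if (is.data.frame(peptide)) {
    stopifnot(nrow(peptide) == 1L)
    pep <- Peptide(peptide$sequence, peptide$proteinId,
                   start = peptide$start)
  } else if (is.character(peptide)) pep <- Peptide(peptide)
  else pep <- peptide
  base <- peptideMass(pep@sequence, table) + fixedModMass
  ## pick the charge state with the largest unlabeled feature area
  unArea <- rep(NA_real_, length(charges))
  unFeat <- vector("list", length(charges))
  for (k in seq_along(charges)) {
    z <- charges[k]
    un <- detectFeatures(run, data.frame(mz = mzFromMass(base, z, table),
                                         z = z), params)
    if (nrow(un)) {
      un <- un[which.max(un$area), , drop = FALSE]
      unArea[k] <- un$area
      unFeat[[k]] <- un
    }
  }
  if (all(is.na(unArea)))
    stop("unlabeled peptide not found in the run: no reference for the ",
         "efficiency denominator")
  k <- which.max(unArea)
  z <- charges[k]
  un <- unFeat[[k]]
  unXic <- extractXIC(run, mzFromMass(base, z, table),
                      params$precursorTolPpm, charge = z)
  unlabeledArea <- integrateArea(unXic, rtBounds = c(un$rtMin, un$rtMax))
  labMz <- mzFromMass(base + adduct@adductMass, z, table)
  lab <- detectFeatures(run, data.frame(mz = labMz, z = z), params)
  if (nrow(lab)) {
    lab <- lab[which.max(lab$area), , drop = FALSE]
    labXic <- extractXIC(run, labMz, params$precursorTolPpm, charge = z)
    labeledArea <- integrateArea(labXic, rtBounds = c(lab$rtMin, lab$rtMax))
    detected <- TRUE
  } else {
    labeledArea <- 0
    detected <- FALSE
  }
  data.frame(proteinId = pep@proteinId, sequence = pep@sequence,
             start = pep@start, end = pep@end, reagent = adduct@reagent,
             charge = z, labeledArea = labeledArea,
             unlabeledArea = unlabeledArea,
             efficiencyPct = labelingEfficiency(labeledArea, unlabeledArea),
             detected = detected, condition = condition,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Competition (protection) of photolabeling
#'
#' Summarizes labeling efficiency per arm (mean, SD with n - 1
#' denominator, n) and reports the percent reduction of the competitor arm
#' relative to the control arm, computed from the arm means. Per-replicate
#' reductions against the control mean are also returned.
#'
#' @param control,competitor numeric vectors of efficiencies (percent), or
#'   data.frames from \code{\link{efficiencyFromRun}} (the
#'   \code{efficiencyPct} column is used).
#' @return A list with \code{control} and \code{competitor} summaries
#'   (mean, sd, n), \code{percentReduction}
#'   (\code{100 * (control - competitor) / control} on the arm means) and
#'   \code{replicateReduction}.
#' @examples
#' competitionReduction(c(0.77, 0.8), c(0.05, 0.05))$percentReduction
#' @export
competitionReduction <- function(control, competitor) {
  eff <- function(x) if (is.data.frame(x)) x$efficiencyPct else as.numeric(x)
  ctl <- eff(control)
  cmp <- eff(competitor)
  if (!length(ctl)) stop("control arm is empty")
  mc <- mean(ctl)
  if (mc <= 0) stop("control arm mean must be > 0")
  summ <- function(x) list(mean = mean(x),
                           sd = if (length(x) > 1L) stats::sd(x) else 0,
                           n = length(x))
  list(control = summ(ctl), competitor = summ(cmp),
       percentReduction = 100 * (mc - mean(cmp)) / mc,
       replicateReduction = 100 * (mc - cmp) / mc)
}
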