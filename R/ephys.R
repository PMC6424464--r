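#' Potentiation response ratio
#'
#' Ratio of the peak response in the presence of GABA plus modulator to the
#' peak response with GABA alone. Scale-invariant in the recorded currents.
#'
#' @param peakGabaPlusMod peak current with GABA + modulator.
#' @param peakGaba peak current with GABA alone (nonzero).
#' @return The ratio.
#' @examples
#' potentiationRatio(42, 10)  # 4.2
#' @export
potentiationRatio <- function(peakGabaPlusMod, peakGaba) {
  if (any(peakGaba == 0)) stop("'peakGaba' must be nonzero")
  peakGabaPlusMod / peakGaba
}

#' Direct activation
#'
#' Peak response to modulator alone relative to the peak response to
#' saturating GABA + 100 uM propofol (an open-probability scale that
#' includes constitutive activity). Returned as a fraction; multiply by
#' 100 for percent display.
#'
#' @param peakModulatorAlone peak current with modulator alone.
#' @param peakGabaSatPropofol peak current with saturating GABA + propofol
#'   (nonzero).
#' @return Activation fraction.
#' @examples
#' directActivation(6.3, 100)  # 0.063
#' @export
directActivation <- function(peakModulatorAlone, peakGabaSatPropofol) {
  if (any(peakGabaSatPropofol == 0))
    stop("'peakGabaSatPropofol' must be nonzero")
  peakModulatorAlone / peakGabaSatPropofol
}

#' Constitutive open probability
#'
#' Anchored between the picrotoxin response (open probability ~ 0) and the
#' saturating GABA + propofol response (open probability ~ 1):
#' \code{iPicrotoxin / (iPicrotoxin - iGabaSatPropofol)}. Under the signed
#' recording convention (picrotoxin shift >= 0, GABA + propofol current
#' <= 0) the result lies in [0, 1].
#'
#' @param iPicrotoxin holding-current shift under 100 uM picrotoxin.
#' @param iGabaSatPropofol peak current under saturating GABA + 100 uM
#'   propofol.
#' @return Constitutive open probability.
#' @examples
#' poConst(5, -95)  # 0.05
#' @export
poConst <- function(iPicrotoxin, iGabaSatPropofol) {
  den <- iPicrotoxin - iGabaSatPropofol
  if (any(den == 0)) stop("iPicrotoxin - iGabaSatPropofol must be nonzero")
  iPicrotoxin / den
}

#' Summarize per-cell electrophysiology measurements
#'
#' Computes the selected derived quantity per cell and returns mean, SD
#' (n - 1 denominator; reported as 0 with a flag when n = 1) and n per
#' construct.
#'
#' @param cells data.frame with one row per cell and columns
#'   \code{construct}, \code{i_gaba}, \code{i_gaba_mod}, \code{i_mod},
#'   \code{i_picrotoxin}, \code{i_gaba_propofol} (signed currents, common
#'   units), as produced by \code{\link{generateEphysTable}}.
#' @param quantity \code{"potentiation"}, \code{"activation"} or
#'   \code{"poconst"}.
#' @param activationDenominator for \code{"activation"}: normalize to the
#'   saturating GABA + propofol response (\code{"gaba_propofol"}, the
#'   open-probability convention, default) or to a saturating-GABA column
#'   \code{i_gaba_sat} (\code{"gaba_sat"}, the percent-of-GABA display
#'   convention).
#' @return A data.frame with columns construct, quantity, mean, sd, n,
#'   singleCell (TRUE when SD is undefined because n = 1).
#' @export
summarizeEphys <- function(cells,
                           quantity = c("potentiation", "activation",
                                        "poconst"),
                           activationDenominator = c("gaba_propofol",
                                                     "gaba_sat")) {
  quantity <- match.arg(quantity)
  activationDenominator <- match.arg(activationDenominator)
  need <- switch(quantity,
    potentiation = c("i_gaba", "i_gaba_mod"),
    activation = c("i_mod", if (activationDenominator == "gaba_propofol")
      "i_gaba_propofol" else "i_gaba_sat"),
    poconst = c("i_picrotoxin", "i_gaba_propofol"))
  miss <- setdiff(c("construct", need), names(cells))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  cells <- cells[stats::complete.cases(cells[, need, drop = FALSE]), ,
                 drop = FALSE]
  if (!nrow(cells)) stop("no cells with the required fields")
  val <- switch(quantity,
    potentiation = potentiationRatio(cells$i_gaba_mod, cells$i_gaba),
    activation = directActivation(cells$i_mod,
      if (activationDenominator == "gaba_propofol") cells$i_gaba_propofol
      else cells$i_gaba_sat),
    poconst = poConst(cells$i_picrotoxin, cells$i_gaba_propofol))
  groups <- split(val, cells$construct)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(construct = g, quantity = quantity, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v), singleCell = length(v) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
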