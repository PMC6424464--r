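## Independent oracles used by the unit and acceptance tests. These are
## deliberately naive (substring summation, double loops) and share no code
## with the package internals they check.

.tab <- residueMasses()

## peptide neutral mass by direct per-character summation
oraclePeptideMass <- function(seq, extra = 0) {
  chars <- strsplit(seq, "")[[1]]
  s <- 0
  for (ch in chars) s <- s + .tab$residues[[ch]]
  s + .tab$water + extra
}

## fragment m/z by substring summation; mods = named list pos -> mass
oracleFragMz <- function(seq, series, index, z, adductMass = 0,
                         placement = NA, modPos = integer(0),
                         modMass = numeric(0)) {
  L <- nchar(seq)
  span <- if (series == "b") seq_len(index) else (L - index + 1):L
  chars <- strsplit(seq, "")[[1]]
  m <- sum(vapply(chars[span], function(ch) .tab$residues[[ch]],
                  numeric(1)))
  for (k in seq_along(modPos))
    if (modPos[k] %in% span) m <- m + modMass[k]
  if (!is.na(placement) && placement %in% span) m <- m + adductMass
  if (series == "y") m <- m + .tab$water
  (m + z * .tab$proton) / z
}

## brute-force placement-enumeration localization: for every candidate
## placement, count the distinct spectrum peaks explained by its b/y
## ladder (nearest-peak rule, absolute tolerance); return the min..max of
## the placements achieving the maximal count, in within-peptide
## coordinates.
oracleLocalize <- function(peakMz, seq, adductMass, tolDa = 0.1,
                           charges = 1L, modPos = integer(0),
                           modMass = numeric(0)) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  resMass <- vapply(chars, function(ch) .tab$residues[[ch]], numeric(1))
  for (k in seq_along(modPos))
    resMass[modPos[k]] <- resMass[modPos[k]] + modMass[k]
  score <- integer(L)
  bearing <- integer(L)
  for (pos in seq_len(L)) {
    hit <- integer(0)
    hitBearing <- integer(0)
    hitNl <- integer(0)
    for (z in charges) for (series in c("b", "y")) for (idx in seq_len(L - 1)) {
      if (!length(peakMz)) next
      span <- if (series == "b") seq_len(idx) else (L - idx + 1):L
      carries <- pos %in% span
      neutral <- sum(resMass[span]) + if (series == "y") .tab$water else 0
      mz <- (neutral + carries * adductMass + z * .tab$proton) / z
      j <- which.min(abs(peakMz - mz))
      if (abs(peakMz[j] - mz) <= tolDa) {
        hit <- c(hit, j)
        if (carries) hitBearing <- c(hitBearing, j)
      }
      if (carries) {
        ## neutral-loss companion: unmodified fragment mass; any peak it
        ## explains carries no localization weight for this placement
        jn <- which.min(abs(peakMz - (mz - adductMass / z)))
        if (abs(peakMz[jn] - (mz - adductMass / z)) <= tolDa)
          hitNl <- c(hitNl, jn)
      }
    }
    score[pos] <- length(setdiff(unique(hit), unique(hitNl)))
    bearing[pos] <- length(setdiff(unique(hitBearing), unique(hitNl)))
  }
  if (max(bearing) == 0) return(c(1L, L))
  best <- which(score == max(score))
  c(min(best), max(best))
}

## random peptide without ambiguity-free constraints; all 20 residues
randomPeptide <- function(len) {
  paste(sample(names(residueMasses()$residues), len, replace = TRUE),
        collapse = "")
}

## a minimal single-peptide generator configuration used across tests
onePeptideConfig <- function(sequence = "IVFPFTFSLFNLVYWLYYVN",
                             site = 17L, reagent = "KK123",
                             efficiencyPct = 1, charge = 3L,
                             rtUnlabeled = 6, rtShift = 10,
                             start = 1L, proteinId = "p1", seed = 1L, ...) {
  syntheticRunConfig(
    peptides = data.frame(
      sequence = sequence, proteinId = proteinId, start = start,
      site = start + site - 1L, reagent = reagent,
      efficiencyPct = efficiencyPct, rtUnlabeled = rtUnlabeled,
      charge = charge, rtShift = rtShift, stringsAsFactors = FALSE),
    rtRange = c(0, rtUnlabeled + rtShift + 5), seed = seed, ...)
}
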