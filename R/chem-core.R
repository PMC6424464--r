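## Monoisotopic residue masses (Da), fixed to 5 decimals. Shared by all
## mass arithmetic in the package; override via residue table arguments.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

.WATER_MONO <- 18.01056
.PROTON_MONO <- 1.00728

#' Monoisotopic residue mass table
#'
#' Returns the residue, water and proton monoisotopic masses used throughout
#' the package (positive-mode \eqn{[M + zH]^{z+}} convention).
#'
#' @return A list with elements \code{residues} (named numeric vector, 20
#'   standard amino acids), \code{water} and \code{proton} (Da).
#' @examples
#' residueMasses()$residues[["G"]]
#' @export
residueMasses <- function() {
  list(residues = .AA_MONO, water = .WATER_MONO, proton = .PROTON_MONO)
}

#' Construct a ModificationSpec
#'
#' @param name modification name.
#' @param deltaMass monoisotopic mass shift in Da.
#' @param specificity character vector of one-letter residue codes, or
#'   \code{"any"}.
#' @param class \code{"fixed"} or \code{"variable"}.
#' @return A \linkS4class{ModificationSpec}.
#' @examples
#' ModificationSpec("oxidation", 15.99491, "M")
#' @export
ModificationSpec <- function(name, deltaMass, specificity = "any",
                             class = c("variable", "fixed")) {
  new("ModificationSpec", name = name, deltaMass = as.numeric(deltaMass),
      specificity = specificity, modClass = match.arg(class))
}

#' Construct an AdductSpec
#'
#' @param reagent reagent name.
#' @param adductMass monoisotopic adduct mass in Da (for a click-tagged
#'   reagent, the light-tag form).
#' @param lightTagMass,heavyTagMass tagged adduct masses in Da (optional).
#' @param pairDelta heavy-light spacing in Da; defaults to
#'   \code{heavyTagMass - lightTagMass} when both tag masses are given.
#'   Supplying a value that disagrees with the tag masses requires
#'   \code{overridePairDelta = TRUE}.
#' @param overridePairDelta logical; allow an explicit \code{pairDelta} that
#'   is not the tag-mass difference (e.g. a nominal rounded spacing).
#' @return An \linkS4class{AdductSpec}.
#' @examples
#' AdductSpec("KK123", 372.16)
#' @export
AdductSpec <- function(reagent, adductMass, lightTagMass = NA_real_,
                       heavyTagMass = NA_real_, pairDelta = NA_real_,
                       overridePairDelta = FALSE) {
  if (is.na(pairDelta) && !is.na(lightTagMass) && !is.na(heavyTagMass))
    pairDelta <- heavyTagMass - lightTagMass
  if (overridePairDelta) attr(pairDelta, "override") <- TRUE
  new("AdductSpec", reagent = reagent, adductMass = as.numeric(adductMass),
      lightTagMass = as.numeric(lightTagMass),
      heavyTagMass = as.numeric(heavyTagMass), pairDelta = pairDelta)
}

#' Construct a Peptide
#'
#' @param sequence residue string (standard one-letter codes).
#' @param proteinId parent protein identifier.
#' @param start 1-based start position in protein coordinates.
#' @param missedCleavages internal missed-cleavage count.
#' @return A \linkS4class{Peptide}.
#' @examples
#' Peptide("IAFPLLFGIFNLVYWATYLNREPQLK", "alpha1", start = 398)
#' @export
Peptide <- function(sequence, proteinId = NA_character_, start = 1L,
                    missedCleavages = 0L) {
  start <- as.integer(start)
  new("Peptide", sequence = sequence, proteinId = proteinId, start = start,
      end = start + nchar(sequence) - 1L,
      missedCleavages = as.integer(missedCleavages))
}

#' Construct a ModifiedPeptide
#'
#' @param peptide a \linkS4class{Peptide} (or a sequence string).
#' @param modPositions integer vector of 1-based within-peptide positions.
#' @param mods list of \linkS4class{ModificationSpec} /
#'   \linkS4class{AdductSpec}, parallel to \code{modPositions}. A single
#'   spec may be given unwrapped.
#' @param ... passed to \code{\link{Peptide}} when \code{peptide} is a
#'   string.
#' @return A \linkS4class{ModifiedPeptide}.
#' @examples
#' ModifiedPeptide("IVFPFTFSLFNLVYWLYYVN", 17,
#'                 AdductSpec("KK123-FLI-light", 672.4322))
#' @export
ModifiedPeptide <- function(peptide, modPositions = integer(0),
                            mods = list(), ...) {
  if (is.character(peptide)) peptide <- Peptide(peptide, ...)
  if (is(mods, "ModificationSpec") || is(mods, "AdductSpec"))
    mods <- list(mods)
  new("ModifiedPeptide", peptide = peptide,
      modPositions = as.integer(modPositions), mods = mods)
}

#' Default variable-modification registry
#'
#' Methionine oxidation and cysteine alkylation adducts (NEM, and NEM
#' followed by DTT addition across the maleimide ring). The NEM+DTT mass is
#' a package convention (sum of the NEM and DTT monoisotopic additions);
#' override it through the \code{chemistry} config section if needed.
#'
#' @return Named list of \linkS4class{ModificationSpec}.
#' @export
defaultModifications <- function() {
  list(
    oxidation = ModificationSpec("oxidation", 15.99491, "M"),
    nem       = ModificationSpec("nem", 125.04768, "C"),
    nem_dtt   = ModificationSpec("nem_dtt", 279.05994, "C"))
}

#' Default photoreagent adduct registry
#'
#' Adduct masses for the allopregnanolone-analogue photolabeling reagents
#' KK123, KK200 and KK202, plus the click-tagged KK123-FLI forms whose
#' light/heavy isotope tags create MS1 doublets. The doublet spacing
#' defaults to the difference of the tag masses (682.44 - 672.4322 =
#' 10.0078 Da); pass \code{nominalPairDelta = TRUE} to use the rounded
#' nominal spacing of 10.07 Da instead.
#'
#' @param nominalPairDelta logical; use the nominal 10.07 Da doublet
#'   spacing for the FLI-tagged reagent.
#' @return Named list of \linkS4class{AdductSpec}.
#' @examples
#' defaultAdducts()$KK123
#' @export
defaultAdducts <- function(nominalPairDelta = FALSE) {
  pd <- if (nominalPairDelta) 10.07 else NA_real_
  list(
    KK123 = AdductSpec("KK123", 372.16),
    KK200 = AdductSpec("KK200", 462.27),
    KK202 = AdductSpec("KK202", 500.31),
    KK123_FLI = AdductSpec("KK123-FLI", 672.4322,
                           lightTagMass = 672.4322, heavyTagMass = 682.44,
                           pairDelta = pd,
                           overridePairDelta = nominalPairDelta))
}

.residueVector <- function(sequence, table = residueMasses()) {
  res <- strsplit(sequence, "")[[1]]
  m <- table$residues[res]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop(sprintf("unknown residue letter '%s' at position %d",
                 res[bad], bad))
  }
  unname(m)
}

.modDelta <- function(m) {
  if (is(m, "AdductSpec")) m@adductMass else m@deltaMass
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus all modification delta masses.
#'
#' @param p a \linkS4class{ModifiedPeptide}, \linkS4class{Peptide}, or
#'   plain sequence string.
#' @param table residue mass table, see \code{\link{residueMasses}}.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideMass("IAFPLLFGIFNLVYWATYLNREPQLK")
#' @export
peptideMass <- function(p, table = residueMasses()) {
  if (is(p, "Peptide")) p <- new("ModifiedPeptide", peptide = p,
                                 modPositions = integer(0), mods = list())
  if (is.character(p)) p <- ModifiedPeptide(p)
  stopifnot(is(p, "ModifiedPeptide"))
  validObject(p)
  base <- sum(.residueVector(p@peptide@sequence, table)) + table$water
  base + sum(vapply(p@mods, .modDelta, numeric(1)))
}

#' m/z from neutral mass
#'
#' Positive-mode \eqn{[M + zH]^{z+}}: \code{(mass + z * proton) / z}.
#'
#' @param neutralMass neutral monoisotopic mass in Da.
#' @param z positive integer charge.
#' @param table residue mass table (supplies the proton mass).
#' @return m/z.
#' @examples
#' mzFromMass(1000, 2)
#' @export
mzFromMass <- function(neutralMass, z, table = residueMasses()) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("'z' must be a positive integer")
  (neutralMass + z * table$proton) / z
}

#' Neutral mass from m/z
#'
#' Inverse of \code{\link{mzFromMass}}: \code{z * mz - z * proton}.
#'
#' @param mz observed m/z.
#' @param z positive integer charge.
#' @param table residue mass table.
#' @return Neutral mass in Da.
#' @export
massFromMz <- function(mz, z, table = residueMasses()) {
  if (any(z < 1) || any(z != as.integer(z)))
    stop("'z' must be a positive integer")
  z * mz - z * table$proton
}

#' Signed mass error in ppm
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return \code{1e6 * (observed - theoretical) / theoretical}.
#' @examples
#' ppmError(500.015, 500)
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("'theoretical' must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, except when the next residue is proline,
#' and enumerates peptides with 0 to \code{maxMissedCleavages} internal
#' missed cleavages.
#'
#' @param sequence protein residue string.
#' @param maxMissedCleavages maximum internal missed cleavages (>= 0).
#' @param minLength,maxLength peptide length bounds in residues.
#' @param proteinId protein identifier carried onto the peptides.
#' @return A data.frame with columns \code{sequence}, \code{proteinId},
#'   \code{start}, \code{end} (1-based inclusive protein coordinates) and
#'   \code{missedCleavages}.
#' @examples
#' digestProtein("AAKRPCCK", maxMissedCleavages = 1)
#' @export
digestProtein <- function(sequence, maxMissedCleavages = 3L,
                          minLength = 1L, maxLength = Inf,
                          proteinId = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string")
  if (maxMissedCleavages < 0L) stop("'maxMissedCleavages' must be >= 0")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  ## cleavage after position i: K/R at i, no P at i+1
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, n)                  # segment boundaries
  starts0 <- bounds[-length(bounds)] + 1L  # 0-missed segments
  ends0 <- bounds[-1L]
  nseg <- length(starts0)
  out <- vector("list", 0L)
  for (k in 0:min(maxMissedCleavages, nseg - 1L)) {
    i <- seq_len(nseg - k)
    st <- starts0[i]
    en <- ends0[i + k]
    len <- en - st + 1L
    keep <- len >= minLength & len <= maxLength
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      sequence = substring(sequence, st[keep], en[keep]),
      proteinId = proteinId, start = st[keep], end = en[keep],
      missedCleavages = k, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sequence = character(0), proteinId = character(0),
                      start = integer(0), end = integer(0),
                      missedCleavages = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read subunit sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}; the record id (up
#' to the first whitespace) becomes the protein id.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
readSubunits <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aas)
  names(seqs) <- sub("\\s.*$", "", names(aas))
  seqs
}

#' Read a chemistry/search configuration
#'
#' JSON config with an optional \code{chemistry} section (residue-table
#' overrides, modification and adduct registries) and an optional
#' \code{search} section mapped onto \code{\link{searchParams}}.
#'
#' @param path JSON file path.
#' @return A list with elements \code{table}, \code{modifications},
#'   \code{adducts} and \code{params}.
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  table <- residueMasses()
  mods <- defaultModifications()
  adducts <- defaultAdducts()
  chem <- cfg$chemistry
  if (!is.null(chem$residues))
    table$residues[names(chem$residues)] <- unlist(chem$residues)
  if (!is.null(chem$water)) table$water <- chem$water
  if (!is.null(chem$proton)) table$proton <- chem$proton
  if (!is.null(chem$modifications))
    for (nm in names(chem$modifications)) {
      m <- chem$modifications[[nm]]
      mods[[nm]] <- ModificationSpec(nm, m$deltaMass,
        specificity = if (is.null(m$specificity)) "any" else m$specificity,
        class = if (is.null(m$class)) "variable" else m$class)
    }
  if (!is.null(chem$adducts))
    for (nm in names(chem$adducts)) {
      a <- chem$adducts[[nm]]
      adducts[[nm]] <- AdductSpec(nm, a$adductMass,
        lightTagMass = if (is.null(a$lightTagMass)) NA_real_ else a$lightTagMass,
        heavyTagMass = if (is.null(a$heavyTagMass)) NA_real_ else a$heavyTagMass,
        pairDelta = if (is.null(a$pairDelta)) NA_real_ else a$pairDelta,
        overridePairDelta = isTRUE(a$overridePairDelta))
    }
  params <- do.call(searchParams, as.list(cfg$search))
  list(table = table, modifications = mods, adducts = adducts,
       params = params)
}
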