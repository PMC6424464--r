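.peakMatrix <- function(mz, intensity) {
  o <- order(mz)
  m <- cbind(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
  if (nrow(m) > 1L) {
    ## collapse coincident centroids so m/z stays strictly increasing
    grp <- cumsum(c(TRUE, diff(m[, 1L]) > 1e-9))
    if (max(grp) < nrow(m))
      m <- cbind(mz = tapply(m[, 1L], grp, min),
                 intensity = tapply(m[, 2L], grp, sum))
    dimnames(m) <- list(NULL, c("mz", "intensity"))
  }
  m
}

.emptyPeaks <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
}

#' Construct a Spectrum2
#'
#' @param precursorMz precursor m/z.
#' @param precursorCharge precursor charge (>= 1).
#' @param rt retention time in minutes.
#' @param mz,intensity peak series (sorted internally; coincident centroids
#'   are merged).
#' @param scanId optional scan identifier.
#' @return A \linkS4class{Spectrum2}.
#' @export
Spectrum2 <- function(precursorMz, precursorCharge, rt, mz = numeric(0),
                      intensity = numeric(0), scanId = NA_character_) {
  new("Spectrum2", precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge), rt = as.numeric(rt),
      peaks = .peakMatrix(mz, intensity), scanId = as.character(scanId))
}

#' Construct an MSRun
#'
#' @param ms1Rt numeric vector of MS1 retention times (minutes).
#' @param ms1Peaks list of peak matrices (columns mz, intensity) or of
#'   lists with \code{mz}/\code{intensity} elements, parallel to
#'   \code{ms1Rt}.
#' @param ms2 list of \linkS4class{Spectrum2}.
#' @param metadata free-form list.
#' @return An \linkS4class{MSRun} with MS1 scans sorted by retention time.
#' @export
MSRun <- function(ms1Rt = numeric(0), ms1Peaks = list(), ms2 = list(),
                  metadata = list()) {
  ms1Peaks <- lapply(ms1Peaks, function(p) {
    if (is.matrix(p)) .peakMatrix(p[, 1L], p[, 2L])
    else .peakMatrix(p$mz, p$intensity)
  })
  o <- order(ms1Rt)
  new("MSRun", ms1Rt = as.numeric(ms1Rt[o]), ms1Peaks = ms1Peaks[o],
      ms2 = ms2, metadata = metadata)
}

#' Read an LC-MS run
#'
#' Reads a centroided run from mzML (via \pkg{mzR}), MGF (MS2 only) or a
#' long-format CSV peak table with columns \code{scan}, \code{ms_level},
#' \code{rt_min}, \code{precursor_mz}, \code{precursor_z}, \code{mz},
#' \code{intensity}.
#'
#' @param path input file.
#' @param format \code{"mzml"}, \code{"mgf"} or \code{"csv"}; default
#'   guessed from the file extension.
#' @return An \linkS4class{MSRun}.
#' @export
readRun <- function(path, format = c("auto", "mzml", "mgf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mzml = "mzml", mgf = "mgf", csv = "csv",
                     stop("cannot guess format from extension: ", path))
  if (!file.exists(path)) stop("file not found: ", path)
  run <- switch(format,
    mzml = .readMzml(path),
    mgf = .readMgf(path),
    csv = .readCsvRun(path))
  run@metadata$source <- path
  run@metadata$format <- format
  validObject(run)
  run
}

.readMzml <- function(path) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) return(MSRun())
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  i1 <- which(hd$msLevel == 1L)
  i2 <- which(hd$msLevel == 2L)
  ms2 <- lapply(i2, function(i)
    Spectrum2(hd$precursorMZ[i], hd$precursorCharge[i],
              hd$retentionTime[i] / 60, mz = pk[[i]][, 1L],
              intensity = pk[[i]][, 2L],
              scanId = as.character(hd$acquisitionNum[i])))
  MSRun(ms1Rt = hd$retentionTime[i1] / 60, ms1Peaks = pk[i1], ms2 = ms2)
}

.readMgf <- function(path) {
  lines <- readLines(path)
  ms2 <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "BEGIN IONS") {
      j <- i + 1L
      prec <- NA_real_; z <- NA_integer_; rt <- NA_real_
      scan <- NA_character_
      mzv <- numeric(0); iv <- numeric(0)
      while (j <= n && lines[j] != "END IONS") {
        ln <- lines[j]
        num <- function(x, what) {
          v <- suppressWarnings(as.numeric(x))
          if (is.na(v)) stop("malformed ", what, " at MGF line ", j, ": ", ln)
          v
        }
        if (grepl("^PEPMASS=", ln)) {
          prec <- num(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1],
                      "PEPMASS")
        } else if (grepl("^CHARGE=", ln)) {
          z <- as.integer(num(sub("\\+$", "", sub("^CHARGE=", "", ln)),
                              "CHARGE"))
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- num(sub("^RTINSECONDS=", "", ln), "RTINSECONDS") / 60
        } else if (grepl("^TITLE=", ln)) {
          scan <- sub("^TITLE=", "", ln)
        } else if (grepl("^[0-9]", ln)) {
          v <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mzv <- c(mzv, v[1]); iv <- c(iv, v[2])
        } else if (!grepl("=", ln, fixed = TRUE) && nzchar(ln)) {
          stop("malformed MGF line ", j, ": ", ln)
        }
        j <- j + 1L
      }
      if (j > n) stop("MGF block starting at line ", i, " lacks END IONS")
      ms2[[length(ms2) + 1L]] <- Spectrum2(prec, z, rt, mzv, iv, scan)
      i <- j + 1L
    } else i <- i + 1L
  }
  MSRun(ms2 = ms2)
}

.readCsvRun <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan", "ms_level", "rt_min", "precursor_mz", "precursor_z",
            "mz", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CSV peak table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(MSRun())
  sp <- split(df, df$scan)
  ms1Rt <- numeric(0); ms1Peaks <- list(); ms2 <- list()
  for (s in sp) {
    if (s$ms_level[1L] == 1L) {
      ms1Rt <- c(ms1Rt, s$rt_min[1L])
      ms1Peaks[[length(ms1Peaks) + 1L]] <- .peakMatrix(s$mz, s$intensity)
    } else {
      ms2[[length(ms2) + 1L]] <- Spectrum2(
        s$precursor_mz[1L], s$precursor_z[1L], s$rt_min[1L], s$mz,
        s$intensity, scanId = as.character(s$scan[1L]))
    }
  }
  MSRun(ms1Rt = ms1Rt, ms1Peaks = ms1Peaks, ms2 = ms2)
}

#' Write an LC-MS run
#'
#' Inverse of \code{\link{readRun}} for the same three dialects. The mzML
#' writer goes through \code{mzR::writeMSData}; MGF keeps MS2 spectra only.
#'
#' @param run an \linkS4class{MSRun}.
#' @param path output file.
#' @param format \code{"mzml"}, \code{"mgf"} or \code{"csv"}; default
#'   guessed from the extension.
#' @return \code{path}, invisibly.
#' @export
writeRun <- function(run, path, format = c("auto", "mzml", "mgf", "csv")) {
  validObject(run)
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mzml = "mzml", mgf = "mgf", csv = "csv",
                     stop("cannot guess format from extension: ", path))
  switch(format,
    mzml = .writeMzml(run, path),
    mgf = .writeMgf(run, path),
    csv = .writeCsvRun(run, path))
  invisible(path)
}

.writeMzml <- function(run, path) {
  n1 <- length(run@ms1Rt)
  n2 <- length(run@ms2)
  n <- n1 + n2
  if (n == 0L) {
    ## a minimal zero-spectrum document; mzR cannot write empty runs
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
      '  <cvList count="2">',
      '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '    <cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      '  </cvList>',
      '  <fileDescription>',
      '    <fileContent>',
      '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '    </fileContent>',
      '  </fileDescription>',
      '  <softwareList count="1">',
      '    <software id="sw" version="0.1">',
      '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
      '    </software>',
      '  </softwareList>',
      '  <instrumentConfigurationList count="1">',
      '    <instrumentConfiguration id="ic">',
      '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '    </instrumentConfiguration>',
      '  </instrumentConfigurationList>',
      '  <dataProcessingList count="1">',
      '    <dataProcessing id="dp">',
      '      <processingMethod order="0" softwareRef="sw">',
      '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '      </processingMethod>',
      '    </dataProcessing>',
      '  </dataProcessingList>',
      '  <run id="empty" defaultInstrumentConfigurationRef="ic">',
      '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
      '  </run>',
      '</mzML>'), path)
    return(invisible(path))
  }
  rt1 <- run@ms1Rt * 60
  rt2 <- vapply(run@ms2, function(s) s@rt * 60, numeric(1))
  o <- order(c(rt1, rt2), c(rep(1L, n1), rep(2L, n2)))
  lev <- c(rep(1L, n1), rep(2L, n2))[o]
  pk <- c(run@ms1Peaks, lapply(run@ms2, function(s) s@peaks))[o]
  hd <- .mzmlHeader(n)
  hd$msLevel <- lev
  hd$retentionTime <- c(rt1, rt2)[o]
  hd$peaksCount <- vapply(pk, nrow, integer(1))
  hd$totIonCurrent <- vapply(pk, function(p) sum(p[, 2L]), numeric(1))
  hd$lowMZ <- vapply(pk, function(p) if (nrow(p)) min(p[, 1L]) else 0,
                     numeric(1))
  hd$highMZ <- vapply(pk, function(p) if (nrow(p)) max(p[, 1L]) else 0,
                      numeric(1))
  bp <- function(p, col) if (nrow(p)) p[which.max(p[, 2L]), col] else 0
  hd$basePeakMZ <- vapply(pk, bp, numeric(1), col = 1L)
  hd$basePeakIntensity <- vapply(pk, bp, numeric(1), col = 2L)
  i2 <- which(lev == 2L)
  ms2o <- run@ms2[order(rt2)]
  hd$precursorMZ[i2] <- vapply(ms2o, function(s) s@precursorMz, numeric(1))
  hd$precursorCharge[i2] <- vapply(ms2o, function(s) s@precursorCharge,
                                   integer(1))
  hd$precursorIntensity[i2] <- 0
  mzR::writeMSData(pk, file = path, header = hd)
  invisible(path)
}

.mzmlHeader <- function(n) {
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n), peaksCount = rep(0L, n),
    totIonCurrent = rep(0, n), retentionTime = rep(0, n),
    basePeakMZ = rep(0, n), basePeakIntensity = rep(0, n),
    collisionEnergy = rep(NA_real_, n), ionisationEnergy = rep(0, n),
    lowMZ = rep(0, n), highMZ = rep(0, n),
    precursorScanNum = rep(NA_integer_, n),
    precursorMZ = rep(NA_real_, n), precursorCharge = rep(NA_integer_, n),
    precursorIntensity = rep(NA_real_, n), mergedScan = rep(NA_integer_, n),
    mergedResultScanNum = rep(NA_integer_, n),
    mergedResultStartScanNum = rep(NA_integer_, n),
    mergedResultEndScanNum = rep(NA_integer_, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
}

.writeMgf <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(run@ms2)) {
    s <- run@ms2[[i]]
    writeLines(c("BEGIN IONS",
      paste0("TITLE=", if (is.na(s@scanId)) paste0("spectrum_", i)
             else s@scanId),
      sprintf("RTINSECONDS=%.6f", s@rt * 60),
      sprintf("PEPMASS=%.6f", s@precursorMz),
      sprintf("CHARGE=%d+", s@precursorCharge),
      if (nrow(s@peaks)) sprintf("%.6f %.6f", s@peaks[, 1L], s@peaks[, 2L]),
      "END IONS"), con)
  }
  invisible(path)
}

.writeCsvRun <- function(run, path) {
  rows <- list()
  scan <- 0L
  for (i in seq_along(run@ms1Rt)) {
    scan <- scan + 1L
    p <- run@ms1Peaks[[i]]
    if (!nrow(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      scan = scan, ms_level = 1L, rt_min = run@ms1Rt[i],
      precursor_mz = NA_real_, precursor_z = NA_integer_,
      mz = p[, 1L], intensity = p[, 2L])
  }
  for (s in run@ms2) {
    scan <- scan + 1L
    p <- s@peaks
    if (!nrow(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      scan = scan, ms_level = 2L, rt_min = s@rt,
      precursor_mz = s@precursorMz, precursor_z = s@precursorCharge,
      mz = p[, 1L], intensity = p[, 2L])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan = integer(0), ms_level = integer(0),
               rt_min = numeric(0), precursor_mz = numeric(0),
               precursor_z = integer(0), mz = numeric(0),
               intensity = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract an ion chromatogram
#'
#' Per MS1 scan, sums the intensities of peaks within \code{tolPpm} of the
#' target m/z; scans with no matching peak contribute zero.
#'
#' @param run an \linkS4class{MSRun}.
#' @param targetMz target m/z.
#' @param tolPpm extraction tolerance in ppm (> 0).
#' @param rtWindow optional \code{c(min, max)} retention-time window in
#'   minutes.
#' @param charge assumed charge recorded on the chromatogram.
#' @return A \linkS4class{Chromatogram}.
#' @export
extractXIC <- function(run, targetMz, tolPpm = 30, rtWindow = NULL,
                       charge = NA_integer_) {
  stopifnot(tolPpm > 0, targetMz > 0)
  idx <- seq_along(run@ms1Rt)
  if (!is.null(rtWindow))
    idx <- idx[run@ms1Rt >= rtWindow[1L] & run@ms1Rt <= rtWindow[2L]]
  tol <- targetMz * tolPpm * 1e-6
  int <- vapply(idx, function(i) {
    p <- run@ms1Peaks[[i]]
    if (!nrow(p)) return(0)
    sum(p[abs(p[, 1L] - targetMz) <= tol, 2L])
  }, numeric(1))
  new("Chromatogram", rt = run@ms1Rt[idx], intensity = int,
      targetMz = as.numeric(targetMz), tolPpm = as.numeric(tolPpm),
      charge = as.integer(charge))
}

#' Integrate a chromatogram
#'
#' Trapezoidal area of the baseline-subtracted intensity trace. The
#' baseline is a constant intensity percentile of the chromatogram window
#' (10th percentile by default); values driven negative by the subtraction
#' are clipped to zero.
#'
#' @param c a \linkS4class{Chromatogram}.
#' @param baselinePercentile baseline percentile in [0, 1].
#' @param rtBounds optional \code{c(min, max)} integration bounds in
#'   minutes (baseline still estimated from the full window).
#' @return Area in intensity * minutes.
#' @examples
#' xic <- new("Chromatogram", rt = c(0, 1, 2), intensity = c(0, 10, 0),
#'            targetMz = 500, tolPpm = 30, charge = NA_integer_)
#' integrateArea(xic)  # 10
#' @export
integrateArea <- function(c, baselinePercentile = 0.1, rtBounds = NULL) {
  if (length(c@rt) < 2L) return(0)
  base <- stats::quantile(c@intensity, baselinePercentile, names = FALSE)
  y <- pmax(c@intensity - base, 0)
  rt <- c@rt
  if (!is.null(rtBounds)) {
    keep <- rt >= rtBounds[1L] & rt <= rtBounds[2L]
    rt <- rt[keep]; y <- y[keep]
    if (length(rt) < 2L) return(0)
  }
  pracma::trapz(rt, y)
}
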