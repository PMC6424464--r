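#' Read a binding-site cluster annotation table
#'
#' TSV with columns \code{protein_id}, \code{start}, \code{end},
#' \code{cluster_id}, \code{cluster_name} and optionally \code{note}.
#' The packaged annotation (\code{system.file("extdata",
#' "site_clusters.tsv", package = "photolabelMS")}) maps the photolabeled
#' alpha1/beta3 residues onto the three structural binding-site clusters.
#'
#' @param path TSV file path.
#' @return A data.frame annotation table.
#' @export
readSiteAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("protein_id", "start", "end", "cluster_id", "cluster_name")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  overlapCheck <- split(df, df$protein_id)
  for (d in overlapCheck) {
    if (nrow(d) < 2L) next
    d <- d[order(d$start), ]
    for (i in seq_len(nrow(d) - 1L))
      if (d$end[i] >= d$start[i + 1L] &&
          d$cluster_id[i] != d$cluster_id[i + 1L])
        stop("annotation maps residues of '", d$protein_id[i],
             "' to more than one cluster")
  }
  df
}

#' Assign a localized interval to a binding-site cluster
#'
#' Pure coordinate lookup: the cluster whose annotated residues intersect
#' the localized interval. No intersection gives \code{"unassigned"};
#' intersection with several clusters gives \code{"ambiguous"} with the
#' candidate list attached as an attribute.
#'
#' @param result a \linkS4class{LocalizationResult}, or a protein id (with
#'   \code{interval} also supplied).
#' @param annotation annotation data.frame from
#'   \code{\link{readSiteAnnotation}}.
#' @param interval \code{c(start, end)} in protein coordinates, when
#'   \code{result} is a protein id.
#' @return The cluster id (as character), \code{"unassigned"}, or
#'   \code{"ambiguous"} (with attribute \code{clusters}).
#' @export
assignCluster <- function(result, annotation, interval = NULL) {
  if (is(result, "LocalizationResult")) {
    prot <- result@peptide@proteinId
    interval <- c(result@intervalStart, result@intervalEnd)
  } else {
    prot <- result
    if (is.null(interval)) stop("'interval' required with a protein id")
  }
  ann <- annotation[annotation$protein_id == prot &
                    annotation$end >= interval[1L] &
                    annotation$start <= interval[2L], , drop = FALSE]
  ids <- unique(ann$cluster_id)
  if (!length(ids)) return("unassigned")
  if (length(ids) > 1L)
    return(structure("ambiguous", clusters = as.character(ids)))
  as.character(ids)
}

#' Render the final site report
#'
#' Deterministic ordering by (protein, interval start); numeric fields at
#' fixed precision; identical content across output formats.
#'
#' @param rows data.frame with columns reagent, proteinId, sequence,
#'   intervalStart, intervalEnd, cluster, clusterName, and optionally
#'   efficiencyMean, efficiencySD, n, reductionPct.
#' @param format \code{"tsv"}, \code{"json"} or \code{"markdown"}.
#' @param path optional output file.
#' @return The rendered document as a character scalar (invisibly when
#'   written to \code{path}).
#' @export
renderReport <- function(rows, format = c("tsv", "json", "markdown"),
                         path = NULL) {
  format <- match.arg(format)
  numCols <- c("efficiencyMean", "efficiencySD", "reductionPct")
  if (nrow(rows)) {
    rows <- rows[order(rows$proteinId, rows$intervalStart,
                       rows$intervalEnd), , drop = FALSE]
    for (cn in intersect(numCols, names(rows)))
      rows[[cn]] <- round(as.numeric(rows[[cn]]), 4)
    rownames(rows) <- NULL
  }
  doc <- switch(format,
    tsv = paste0(paste(names(rows), collapse = "\t"), "\n",
                 if (nrow(rows)) paste(apply(rows, 1L, paste,
                                             collapse = "\t"),
                                       collapse = "\n") else "",
                 if (nrow(rows)) "\n" else ""),
    json = as.character(jsonlite::toJSON(rows, dataframe = "rows",
                                         digits = NA, pretty = TRUE)),
    markdown = {
      hdr <- paste0("| ", paste(names(rows), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(rows)), collapse = "|"), "|")
      body <- if (nrow(rows))
        apply(rows, 1L, function(r)
          paste0("| ", paste(r, collapse = " | "), " |"))
      else character(0)
      paste(c(hdr, sep, body, ""), collapse = "\n")
    })
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}
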