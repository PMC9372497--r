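## machine-readable run report: instance p-values, ROI priority table,
## fusion trace, and composition breakdowns by source atlas and lobe.

#' Build a machine-readable fusion run report
#'
#' Collects the outputs of \code{\link{selectMain}} and
#' \code{\link{fuseNetworks}} into one serializable structure: per-instance
#' p-values, the supplementary-ROI priority table with per-atlas
#' provenance, the prefix p-value trace, and the fused network's
#' composition broken down by source atlas and by lobe.
#'
#' @param selection a \code{SelectionResult}.
#' @param fusion a \code{FusionResult}.
#' @param stack the \code{ConditionStack} the run was computed on.
#' @return a named list (see Details); serializable with
#'   \code{\link{writeFusionReport}}.
#' @export
fusionReport <- function(selection, fusion, stack) {
  tab <- roiTable(stack)
  keys <- paste(tab$atlas, tab$roi_id, sep = ":")
  lookup <- function(k, col) tab[[col]][match(k, keys)]
  supp <- selection@suppRois
  priority <- data.frame(
    rank = seq_along(supp),
    roi = supp,
    atlas = lookup(supp, "atlas"),
    lobe = lookup(supp, "lobe"),
    pvalue = unname(selection@roiPvalues[supp]),
    stringsAsFactors = FALSE)
  fr <- fusion@fusedRois
  byAtlas <- as.list(table(lookup(fr, "atlas")))
  byLobe <- as.list(table(lookup(fr, "lobe")))
  list(
    mainInstance = selection@mainInstance,
    instancePvalues = as.list(selection@instancePvalues),
    mainSize = length(selection@mainRois),
    priority = priority,
    pvalueTrace = fusion@pvalueTrace,
    fusedIndex = fusion@fusedIndex,
    fusedPvalue = fusion@fusedPvalue,
    fusedSize = length(fr),
    fusedRois = fr,
    fusedByAtlas = lapply(byAtlas, as.integer),
    fusedByLobe = lapply(byLobe, as.integer),
    design = list(conditions = stack@conditions, subjects = stack@subjects,
                  nRois = nrow(tab)))
}

#' Write / read a fusion report as JSON
#' @param report a list from \code{\link{fusionReport}}.
#' @param path JSON file path.
#' @return \code{writeFusionReport}: \code{path}, invisibly;
#'   \code{readFusionReport}: the report list.
#' @export
writeFusionReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeFusionReport
#' @export
readFusionReport <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Write the report's tabular parts as TSV files
#'
#' Emits human-readable companions to the JSON report: the priority table
#' (\code{priority.tsv}), the prefix trace (\code{trace.tsv}), and the
#' instance p-values (\code{instances.tsv}).
#'
#' @param report a list from \code{\link{fusionReport}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReportTables <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$priority, file.path(dir, "priority.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trace <- data.frame(prefix = seq_along(report$pvalueTrace) - 1L,
                      pvalue = report$pvalueTrace)
  utils::write.table(trace, file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  inst <- data.frame(instance = names(report$instancePvalues),
                     pvalue = unlist(report$instancePvalues),
                     stringsAsFactors = FALSE)
  utils::write.table(inst, file.path(dir, "instances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
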