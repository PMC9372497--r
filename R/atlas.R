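## atlas model: network instances, lobe clipping, combined network.

#' Construct a network instance
#'
#' @param networkConcept network concept token (e.g. "FPN").
#' @param instanceName source-atlas token.
#' @param rois ROI \code{data.frame} with columns \code{roi_id},
#'   \code{name}, \code{x}, \code{y}, \code{z}, \code{lobe},
#'   \code{network}, \code{atlas}. Lobe labels are lower-cased before
#'   validation against the closed vocabulary.
#' @return a \code{\linkS4class{NetworkInstance}}.
#' @export
NetworkInstance <- function(networkConcept, instanceName, rois) {
  rois <- as.data.frame(rois, stringsAsFactors = FALSE)
  if ("lobe" %in% names(rois)) rois$lobe <- tolower(as.character(rois$lobe))
  for (col in c("roi_id", "name", "network", "atlas"))
    if (col %in% names(rois)) rois[[col]] <- as.character(rois[[col]])
  rownames(rois) <- NULL
  methods::new("NetworkInstance",
               networkConcept = as.character(networkConcept),
               instanceName = as.character(instanceName),
               rois = rois)
}

#' @describeIn nRois ROI count of an instance
#' @export
setMethod("nRois", "NetworkInstance", function(x) nrow(x@rois))
#' @describeIn roiTable ROI table of an instance
#' @export
setMethod("roiTable", "NetworkInstance", function(x) x@rois)
#' @describeIn roiKeys keys of an instance
#' @export
setMethod("roiKeys", "NetworkInstance",
          function(x) paste(x@rois$atlas, x@rois$roi_id, sep = ":"))
#' @describeIn networkConcept concept of an instance
#' @export
setMethod("networkConcept", "NetworkInstance", function(x) x@networkConcept)
#' @describeIn instanceName name of an instance
#' @export
setMethod("instanceName", "NetworkInstance", function(x) x@instanceName)

#' @describeIn nRois ROI count of a combined network
#' @export
setMethod("nRois", "CombinedNetwork", function(x) nrow(x@rois))
#' @describeIn roiTable ROI table of a combined network
#' @export
setMethod("roiTable", "CombinedNetwork", function(x) x@rois)
#' @describeIn roiKeys keys of a combined network
#' @export
setMethod("roiKeys", "CombinedNetwork",
          function(x) paste(x@rois$atlas, x@rois$roi_id, sep = ":"))
#' @describeIn networkConcept concept of a combined network
#' @export
setMethod("networkConcept", "CombinedNetwork", function(x) x@networkConcept)

#' Source-instance names of a combined network
#' @param x a \code{CombinedNetwork}.
#' @return character vector of instance names in combination order.
#' @export
sourceInstances <- function(x) {
  stopifnot(methods::is(x, "CombinedNetwork"))
  x@sources
}

setMethod("show", "NetworkInstance", function(object) {
  cat(sprintf("NetworkInstance '%s' of concept '%s': %d ROIs\n",
              object@instanceName, object@networkConcept, nrow(object@rois)))
  print(table(lobe = object@rois$lobe))
  invisible(object)
})

setMethod("show", "CombinedNetwork", function(object) {
  cat(sprintf("CombinedNetwork '%s': %d ROIs from %d instance(s) [%s]\n",
              object@networkConcept, nrow(object@rois),
              length(object@sources), paste(object@sources, collapse = ", ")))
  print(table(lobe = object@rois$lobe))
  invisible(object)
})

#' Read network instances from an atlas table
#'
#' The atlas table is tab-separated text with header columns
#' \code{roi_id name x y z lobe network atlas}, one row per ROI,
#' coordinates in MNI millimetres. Rows are grouped into one instance per
#' (network, atlas) pair; row order within each group is preserved.
#'
#' @param path path to the TSV file.
#' @return named list of \code{NetworkInstance} (names = instance names).
#' @seealso \code{\link{writeAtlasTable}}, \code{\link{readAtlasJSON}}
#' @export
readAtlasTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("atlas table '%s' does not exist", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  .instancesFromFrame(df, where = path)
}

.instancesFromFrame <- function(df, where = "atlas table") {
  missing <- setdiff(.ROI_COLUMNS, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing column(s): %s", where, paste(missing, collapse = ", ")))
  if (anyDuplicated(names(df)))
    stop(sprintf("%s: duplicate column(s): %s", where,
                 paste(unique(names(df)[duplicated(names(df))]), collapse = ", ")))
  if (nrow(df) == 0L) stop(sprintf("%s: no instances", where))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop(sprintf("%s: non-numeric coordinate '%s' in column %s, row %d",
                   where, df[[col]][which(is.na(v))[1L]], col, which(is.na(v))[1L]))
    df[[col]] <- v
  }
  grp <- paste(df$network, df$atlas, sep = "\r")
  out <- list()
  for (g in unique(grp)) {           # first-appearance order
    rows <- df[grp == g, , drop = FALSE]
    inst <- NetworkInstance(networkConcept = rows$network[1L],
                            instanceName = rows$atlas[1L],
                            rois = rows)
    out[[inst@instanceName]] <- inst
  }
  out
}

#' Write network instances to an atlas table
#' @param instances list of \code{NetworkInstance} (or a single one).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAtlasTable <- function(instances, path) {
  df <- .instancesToFrame(instances)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.instancesToFrame <- function(instances) {
  if (methods::is(instances, "NetworkInstance")) instances <- list(instances)
  do.call(rbind, lapply(instances, function(i) i@rois[, .ROI_COLUMNS]))
}

#' Read/write instances as a JSON document
#'
#' JSON equivalent of the atlas table: an array of row objects with the
#' same fields.
#' @param instances list of \code{NetworkInstance}.
#' @param path file path.
#' @return \code{readAtlasJSON}: named list of instances;
#'   \code{writeAtlasJSON}: \code{path}, invisibly.
#' @export
writeAtlasJSON <- function(instances, path) {
  df <- .instancesToFrame(instances)
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeAtlasJSON
#' @export
readAtlasJSON <- function(path) {
  if (!file.exists(path)) stop(sprintf("atlas JSON '%s' does not exist", path))
  df <- jsonlite::fromJSON(path)
  .instancesFromFrame(as.data.frame(df, stringsAsFactors = FALSE), where = path)
}

#' @describeIn clipToLobes clip a network instance
#' @export
setMethod("clipToLobes", "NetworkInstance", function(x, keep) {
  keep <- tolower(keep)
  if (length(keep) == 0L) stop("'keep' must name at least one lobe")
  bad <- setdiff(keep, .LOBES)
  if (length(bad) > 0L)
    stop(sprintf("unknown lobe label(s): %s", paste(bad, collapse = ", ")))
  sel <- x@rois$lobe %in% keep
  if (!any(sel)) stop("clipping removed all ROIs")
  NetworkInstance(x@networkConcept, x@instanceName,
                  x@rois[sel, , drop = FALSE])
})

#' Relabel the network concept of an instance
#'
#' Useful when conceptually equivalent networks carry different names in
#' their source atlases (e.g. an "ECN" treated as an FPN instance), since
#' \code{\link{combineInstances}} refuses to mix concepts.
#' @param x a \code{NetworkInstance}.
#' @param concept new concept token, applied to the instance and its rows.
#' @return the relabelled instance.
#' @export
relabelConcept <- function(x, concept) {
  stopifnot(methods::is(x, "NetworkInstance"))
  rois <- x@rois
  rois$network <- as.character(concept)
  NetworkInstance(concept, x@instanceName, rois)
}

#' Combine network instances into a combined cognitive network
#'
#' Concatenates the ROI lists of all instances of one network concept, in
#' input order. Cross-instance coordinate duplicates are retained as
#' distinct ROIs: the combined size is always the sum of the instance
#' sizes.
#'
#' @param instances non-empty list of \code{NetworkInstance} sharing one
#'   network concept.
#' @return a \code{\linkS4class{CombinedNetwork}}.
#' @examples
#' ccn <- combineInstances(syntheticInstances())
#' nRois(ccn)                  # 72
#' table(roiTable(ccn)$lobe)   # 47 frontal, 25 parietal
#' @export
combineInstances <- function(instances) {
  if (methods::is(instances, "NetworkInstance")) instances <- list(instances)
  if (length(instances) == 0L) stop("no instances to combine")
  concepts <- unique(vapply(instances, function(i) i@networkConcept, character(1L)))
  if (length(concepts) > 1L)
    stop(sprintf("cannot combine instances of different network concepts: %s",
                 paste(concepts, collapse = ", ")))
  sources <- unname(vapply(instances, function(i) i@instanceName, character(1L)))
  if (anyDuplicated(sources))
    stop("instance names must be unique within a combination")
  rois <- .instancesToFrame(instances)
  rownames(rois) <- NULL
  methods::new("CombinedNetwork", networkConcept = concepts,
               sources = sources, rois = rois)
}
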