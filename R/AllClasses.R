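## Closed anatomical-lobe vocabulary. Clipping semantics depend on these
## labels, so unknown labels are rejected at load rather than mapped.
.LOBES <- c("frontal", "parietal", "occipital", "temporal",
            "limbic", "insula", "cerebellum", "other")

.ROI_COLUMNS <- c("roi_id", "name", "x", "y", "z", "lobe", "network", "atlas")

## Shared validator for ROI tables. `where` names the container in error
## messages; distinct coordinates are only required *within* an instance.
.validateRoiFrame <- function(df, where = "ROI table",
                              requireDistinctCoords = TRUE,
                              requireUniqueIds = TRUE) {
  missing <- setdiff(.ROI_COLUMNS, names(df))
  if (length(missing) > 0L)
    return(sprintf("%s: missing column(s) %s", where,
                   paste(missing, collapse = ", ")))
  if (nrow(df) < 1L)
    return(sprintf("%s: must contain at least one ROI", where))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    bad <- which(apply(xyz, 1L, function(r) !is.numeric(r) || any(!is.finite(r))))[1L]
    return(sprintf("%s: non-finite or non-numeric MNI coordinates in row %d (roi_id '%s')",
                   where, bad, df$roi_id[bad]))
  }
  if (requireUniqueIds && anyDuplicated(df$roi_id)) {
    dup <- df$roi_id[duplicated(df$roi_id)][1L]
    return(sprintf("%s: duplicate roi_id '%s'", where, dup))
  }
  badLobe <- which(!(df$lobe %in% .LOBES))
  if (length(badLobe) > 0L)
    return(sprintf("%s: unknown lobe label '%s' in row %d (allowed: %s)",
                   where, df$lobe[badLobe[1L]], badLobe[1L],
                   paste(.LOBES, collapse = ", ")))
  if (requireDistinctCoords) {
    key <- paste(xyz[, 1L], xyz[, 2L], xyz[, 3L])
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1L]
      return(sprintf("%s: duplicate MNI coordinates (%g, %g, %g) in row %d (roi_id '%s')",
                     where, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], i, df$roi_id[i]))
    }
  }
  TRUE
}

#' One atlas's version of a cognitive network
#'
#' A \code{NetworkInstance} holds the ordered set of regions of interest
#' (ROIs) that one brain atlas assigns to a cognitive-network concept such
#' as the fronto-parietal network (FPN). ROIs are point regions with MNI
#' millimetre coordinates and an anatomical lobe label drawn from a closed
#' vocabulary (\code{frontal}, \code{parietal}, \code{occipital},
#' \code{temporal}, \code{limbic}, \code{insula}, \code{cerebellum},
#' \code{other}).
#'
#' Two ROIs inside the same instance may never share MNI coordinates;
#' across instances, coordinate duplicates are deliberately retained as
#' distinct regions because they originate from different atlases. ROI
#' identity is therefore the pair (source atlas, roi_id), exposed as
#' \code{atlas:roi_id} by \code{\link{roiKeys}}, never the coordinates.
#'
#' @slot networkConcept single token naming the network concept (e.g. "FPN").
#' @slot instanceName single token naming the source atlas.
#' @slot rois \code{data.frame} with columns \code{roi_id}, \code{name},
#'   \code{x}, \code{y}, \code{z}, \code{lobe}, \code{network}, \code{atlas}.
#'
#' @seealso \code{\link{readAtlasTable}}, \code{\link{clipToLobes}},
#'   \code{\link{combineInstances}}
#' @export
setClass("NetworkInstance",
  representation(networkConcept = "character",
                 instanceName = "character",
                 rois = "data.frame"),
  validity = function(object) {
    if (length(object@networkConcept) != 1L || !nzchar(object@networkConcept))
      return("networkConcept must be a single non-empty string")
    if (length(object@instanceName) != 1L || !nzchar(object@instanceName))
      return("instanceName must be a single non-empty string")
    .validateRoiFrame(object@rois,
                      where = sprintf("instance '%s'", object@instanceName),
                      requireDistinctCoords = TRUE)
  })

#' Combined cognitive network (union of atlas instances)
#'
#' The concatenation, in source order, of every instance of one cognitive
#' network concept. No deduplication is performed: ROIs with identical MNI
#' coordinates that come from different atlases are retained as distinct
#' members, so the combined size is always the sum of the instance sizes.
#'
#' @slot networkConcept the shared network concept token.
#' @slot sources instance names, in combination order.
#' @slot rois ROI table (same columns as \code{\linkS4class{NetworkInstance}});
#'   coordinate duplicates across sources allowed.
#' @seealso \code{\link{combineInstances}}
#' @export
setClass("CombinedNetwork",
  representation(networkConcept = "character",
                 sources = "character",
                 rois = "data.frame"),
  validity = function(object) {
    if (length(object@networkConcept) != 1L)
      return("networkConcept must be a single string")
    if (length(object@sources) < 1L)
      return("at least one source instance required")
    ok <- .validateRoiFrame(object@rois, where = "combined network",
                            requireDistinctCoords = FALSE,
                            requireUniqueIds = FALSE)
    if (!isTRUE(ok)) return(ok)
    key <- paste(object@rois$atlas, object@rois$roi_id, sep = ":")
    if (anyDuplicated(key))
      return(sprintf("duplicate (atlas, roi_id) pair '%s'",
                     key[duplicated(key)][1L]))
    TRUE
  })

#' Per-subject, per-condition ROI time series
#'
#' @slot condition condition token.
#' @slot subject subject token.
#' @slot data numeric matrix, rows = time points, columns = ROIs in
#'   combined-network order (column names = \code{atlas:roi_id} keys).
#' @export
setClass("TimeSeriesSet",
  representation(condition = "character",
                 subject = "character",
                 data = "matrix"),
  validity = function(object) {
    if (length(object@condition) != 1L || !nzchar(object@condition))
      return("condition must be a single non-empty token")
    if (length(object@subject) != 1L || !nzchar(object@subject))
      return("subject must be a single non-empty token")
    if (!is.numeric(object@data))
      return("data must be a numeric matrix")
    if (nrow(object@data) < 3L)
      return("time series must have at least 3 time points")
    if (any(!is.finite(object@data)))
      return("time series contains non-finite values")
    TRUE
  })

#' Condition x subject stack of functional-connectivity matrices
#'
#' The central 4-D container of the pipeline: one Pearson correlation
#' matrix (plus matching two-sided edge p-values) per condition and
#' subject, over the ROIs of a combined network. Dimension order is
#' condition, subject, ROI, ROI.
#'
#' Every stored slice is symmetric with unit diagonal and off-diagonal
#' values in [-1, 1]; this is asserted by the validity method at
#' construction.
#'
#' @slot conditions ordered condition tokens (dimension 1).
#' @slot subjects ordered subject tokens (dimension 2).
#' @slot rois ROI table of the combined network (dimensions 3-4).
#' @slot matrices 4-D numeric array of correlations.
#' @slot pvals 4-D numeric array of two-sided edge p-values.
#' @seealso \code{\link{buildStack}}, \code{\link{thresholdGraph}}
#' @export
setClass("ConditionStack",
  representation(conditions = "character",
                 subjects = "character",
                 rois = "data.frame",
                 matrices = "array",
                 pvals = "array"),
  validity = function(object) {
    nC <- length(object@conditions); nS <- length(object@subjects)
    nR <- nrow(object@rois)
    want <- c(nC, nS, nR, nR)
    if (!identical(dim(object@matrices), as.integer(want)))
      return(sprintf("matrices must have shape %s", paste(want, collapse = " x ")))
    if (!identical(dim(object@pvals), as.integer(want)))
      return("pvals must have the same shape as matrices")
    tol <- 1e-8
    for (ci in seq_len(nC)) for (si in seq_len(nS)) {
      M <- object@matrices[ci, si, , ]
      if (max(abs(M - t(M))) > tol)
        return(sprintf("slice [%d,%d] is not symmetric", ci, si))
      if (max(abs(diag(M) - 1)) > tol)
        return(sprintf("slice [%d,%d] does not have a unit diagonal", ci, si))
      if (min(M) < -1 - tol || max(M) > 1 + tol)
        return(sprintf("slice [%d,%d] has values outside [-1, 1]", ci, si))
      P <- object@pvals[ci, si, , ]
      if (min(P) < -tol || max(P) > 1 + tol)
        return(sprintf("p-value slice [%d,%d] outside [0, 1]", ci, si))
    }
    TRUE
  })

#' Undirected binary graph over combined-network ROIs
#'
#' @slot nodes ordered ROI keys (\code{atlas:roi_id}).
#' @slot adjacency symmetric logical matrix with a FALSE diagonal.
#' @seealso \code{\link{thresholdGraph}}, \code{\link{graphProperty}}
#' @export
setClass("BinaryGraph",
  representation(nodes = "character", adjacency = "matrix"),
  validity = function(object) {
    A <- object@adjacency
    n <- length(object@nodes)
    if (!is.logical(A)) return("adjacency must be logical")
    if (!identical(dim(A), c(n, n)))
      return("adjacency dimensions must match the node list")
    if (!identical(A, t(A))) return("adjacency must be symmetric")
    if (any(diag(A))) return("self-loops are not allowed")
    TRUE
  })

#' Condition x subject matrix of graph-property values
#'
#' Holds one graph-property value per (condition, subject) cell; the rows
#' (conditions) are compared by \code{\link{discriminability}}.
#'
#' @slot conditions ordered condition tokens (rows).
#' @slot subjects ordered subject tokens (columns).
#' @slot values numeric matrix, |conditions| x |subjects|.
#' @export
setClass("IndexMatrix",
  representation(conditions = "character",
                 subjects = "character",
                 values = "matrix"),
  validity = function(object) {
    want <- c(length(object@conditions), length(object@subjects))
    if (!identical(dim(object@values), as.integer(want)))
      return("values must be |conditions| x |subjects|")
    if (any(!is.finite(object@values)))
      return("values must be finite")
    TRUE
  })

#' Result of main-network selection and supplementary-ROI prioritization
#'
#' @slot mainInstance name of the selected main instance.
#' @slot mainRois its ROI keys (non-priority order).
#' @slot suppRois supplementary ROI keys sorted ascending by nodal
#'   discriminability p-value (stable ties; degenerate ROIs last at p = 1).
#' @slot instancePvalues named candidate p-value per instance.
#' @slot roiPvalues named nodal p-value per supplementary ROI.
#' @seealso \code{\link{selectMain}}
#' @export
setClass("SelectionResult",
  representation(mainInstance = "character",
                 mainRois = "character",
                 suppRois = "character",
                 instancePvalues = "numeric",
                 roiPvalues = "numeric"),
  validity = function(object) {
    if (length(intersect(object@mainRois, object@suppRois)) > 0L)
      return("main and supplementary ROI sets must be disjoint")
    if (!setequal(names(object@roiPvalues), object@suppRois))
      return("roiPvalues must be named by the supplementary ROIs")
    p <- unname(object@roiPvalues[object@suppRois])
    if (is.unsorted(p)) return("suppRois must be sorted ascending by p-value")
    TRUE
  })

#' Result of the greedy prefix fusion search
#'
#' @slot fusedRois ROI keys of the fused network (main ROIs followed by the
#'   absorbed supplementary prefix).
#' @slot fusedIndex number of supplementary ROIs absorbed (>= 0).
#' @slot pvalueTrace candidate p-value per prefix length 0..|suppRois|.
#' @slot fusedPvalue minimum of the trace.
#' @seealso \code{\link{fuseNetworks}}
#' @export
setClass("FusionResult",
  representation(fusedRois = "character",
                 fusedIndex = "integer",
                 pvalueTrace = "numeric",
                 fusedPvalue = "numeric"),
  validity = function(object) {
    if (object@fusedIndex < 0L || object@fusedIndex > length(object@pvalueTrace) - 1L)
      return("fusedIndex out of range of the trace")
    if (abs(object@fusedPvalue - min(object@pvalueTrace)) > 1e-12)
      return("fusedPvalue must equal the minimum of the trace")
    if (which.min(object@pvalueTrace) != object@fusedIndex + 1L)
      return("fusedIndex must be the first argmin of the trace")
    TRUE
  })

#' Planted-subnetwork simulation design
#'
#' Describes a synthetic multi-condition, multi-subject experiment in
#' which a known ROI subset (the planted set) carries a condition-dependent
#' change in pairwise correlation. Defaults mirror a two-condition study
#' with 21 subjects and a 72-ROI combined network partitioned into four
#' atlas-like instances of sizes 10/21/24/17.
#'
#' @slot nConditions,nSubjects,nRois,nTime design counts.
#' @slot instanceSizes sizes of the mock instances (sums to nRois).
#' @slot frontalCounts number of frontal-labelled ROIs per instance
#'   (remainder labelled parietal).
#' @slot plantedRois ROI keys carrying the condition effect.
#' @slot baseCorr baseline within-planted-block correlation.
#' @slot effect added planted-block correlation in condition 1.
#' @slot subjectSd SD of the per-subject correlation jitter.
#' @slot seed RNG seed.
#' @seealso \code{\link{plantedDesign}}, \code{\link{generatePlanted}}
#' @export
setClass("PlantedDesign",
  representation(nConditions = "integer", nSubjects = "integer",
                 nRois = "integer", nTime = "integer",
                 instanceSizes = "integer", frontalCounts = "integer",
                 plantedRois = "character",
                 baseCorr = "numeric", effect = "numeric",
                 subjectSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nConditions < 2L) return("need at least 2 conditions")
    if (object@nSubjects < 2L) return("need at least 2 subjects")
    if (object@nTime < 3L) return("need at least 3 time points")
    if (sum(object@instanceSizes) != object@nRois)
      return("instanceSizes must sum to nRois")
    if (any(object@instanceSizes < 1L))
      return("every instance needs at least one ROI")
    if (length(object@frontalCounts) != length(object@instanceSizes) ||
        any(object@frontalCounts < 0L) ||
        any(object@frontalCounts > object@instanceSizes))
      return("frontalCounts must be within [0, instanceSizes]")
    if (object@baseCorr < 0 || object@baseCorr + abs(object@effect) >= 1)
      return("baseCorr and effect must keep correlations inside (-1, 1)")
    if (object@subjectSd < 0) return("subjectSd must be non-negative")
    TRUE
  })
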