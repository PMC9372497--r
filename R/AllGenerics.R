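#' Number of ROIs in a container
#' @param x a \code{NetworkInstance}, \code{CombinedNetwork} or
#'   \code{ConditionStack}.
#' @return integer count.
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' ROI table of a container
#' @param x an object holding ROIs.
#' @return the underlying ROI \code{data.frame}.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' Qualified ROI keys
#'
#' ROI identity is the pair (source atlas, roi_id); the key is the string
#' \code{atlas:roi_id}. Keys are unique within any combined network even
#' when MNI coordinates coincide across atlases.
#' @param x an object holding ROIs.
#' @return character vector of keys, in container order.
#' @export
setGeneric("roiKeys", function(x) standardGeneric("roiKeys"))

#' Network concept token
#' @param x an object tagged with a network concept.
#' @return single character token.
#' @export
setGeneric("networkConcept", function(x) standardGeneric("networkConcept"))

#' Instance (source atlas) name
#' @param x a \code{NetworkInstance}.
#' @return single character token.
#' @export
setGeneric("instanceName", function(x) standardGeneric("instanceName"))

#' Condition tokens of a design
#' @param x a \code{ConditionStack}, \code{IndexMatrix} or
#'   \code{TimeSeriesSet}.
#' @return character vector (or single token for a time-series set).
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' Subject tokens of a design
#' @param x a \code{ConditionStack}, \code{IndexMatrix} or
#'   \code{TimeSeriesSet}.
#' @return character vector (or single token for a time-series set).
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' Restrict a network instance to a set of anatomical lobes
#'
#' @param x a \code{NetworkInstance}.
#' @param keep character vector of lobe labels to retain (subset of the
#'   closed vocabulary). Defaults to the frontal + parietal boundary of the
#'   fronto-parietal network.
#' @return a new \code{NetworkInstance} containing exactly the ROIs whose
#'   lobe is in \code{keep}, original order preserved. Errors if the result
#'   would be empty.
#' @examples
#' inst <- syntheticInstances(clipped = FALSE)[["synGao32"]]
#' nRois(clipToLobes(inst))   # 9 -> 7 after dropping the insula ROIs
#' @export
setGeneric("clipToLobes",
           function(x, keep = c("frontal", "parietal")) standardGeneric("clipToLobes"))
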