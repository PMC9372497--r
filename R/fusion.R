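## fusion: main-network selection, supplementary-ROI prioritization, and
## the greedy prefix search for the fused network.

#' @describeIn nRois size of a fused network
#' @export
setMethod("nRois", "FusionResult", function(x) length(x@fusedRois))

#' Accessors for selection and fusion results
#' @param x a \code{SelectionResult} or \code{FusionResult}.
#' @return the corresponding component.
#' @name fusion-accessors
NULL

#' @rdname fusion-accessors
#' @export
mainInstance <- function(x) x@mainInstance
#' @rdname fusion-accessors
#' @export
mainRois <- function(x) x@mainRois
#' @rdname fusion-accessors
#' @export
suppRois <- function(x) x@suppRois
#' @rdname fusion-accessors
#' @export
instancePvalues <- function(x) x@instancePvalues
#' @rdname fusion-accessors
#' @export
roiPvalues <- function(x) x@roiPvalues
#' @rdname fusion-accessors
#' @export
fusedRois <- function(x) x@fusedRois
#' @rdname fusion-accessors
#' @export
fusedIndex <- function(x) x@fusedIndex
#' @rdname fusion-accessors
#' @export
pvalueTrace <- function(x) x@pvalueTrace
#' @rdname fusion-accessors
#' @export
fusedPvalue <- function(x) x@fusedPvalue

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: main instance '%s' (%d ROIs), %d supplementary ROIs\n",
              object@mainInstance, length(object@mainRois),
              length(object@suppRois)))
  cat("  instance p-values:\n")
  print(signif(object@instancePvalues, 4L))
  invisible(object)
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: %d ROIs (fusedIndex = %d), p = %.3g\n",
              length(object@fusedRois), object@fusedIndex,
              object@fusedPvalue))
  invisible(object)
})

#' Select the main cognitive network and prioritize supplementary ROIs
#'
#' Stage 1 scores every candidate instance by the discriminability of its
#' graph property across conditions (\code{\link{scoreCandidate}}) and
#' selects the instance with the minimum p-value as the main network
#' (first occurrence wins on ties). Stage 2 ranks the remaining ROIs by
#' the discriminability of their nodal degree property within the full
#' combined-network graph, ascending p (stable ties); ROIs whose nodal
#' property is degenerate (zero variance across subjects in every
#' condition) sort to the end with p = 1.
#'
#' @param stack a \code{ConditionStack} over the combined network.
#' @param instances list of \code{NetworkInstance}; every instance ROI
#'   must be present in the stack.
#' @param metric graph property metric (default \code{"degree"}).
#' @param q FDR rate for edge thresholding.
#' @param mode edge sign mode (\code{"positive"} / \code{"absolute"}).
#' @param scope candidate-property scope (see \code{\link{graphProperty}}).
#' @param paired pair the two-condition test across subjects.
#' @return a \code{\linkS4class{SelectionResult}}.
#' @export
selectMain <- function(stack, instances, metric = "degree", q = 0.05,
                       mode = "positive", scope = "induced", paired = TRUE) {
  if (methods::is(instances, "NetworkInstance")) instances <- list(instances)
  if (length(instances) == 0L) stop("need at least one instance")
  stackKeys <- roiKeys(stack)
  instKeys <- lapply(instances, roiKeys)
  nm <- unname(vapply(instances, instanceName, character(1L)))
  for (k in seq_along(instances)) {
    absent <- setdiff(instKeys[[k]], stackKeys)
    if (length(absent) > 0L)
      stop(sprintf("instance '%s' has ROI(s) absent from the stack: %s",
                   nm[k], paste(utils::head(absent, 3L), collapse = ", ")))
  }
  graphs <- stackGraphs(stack, q = q, mode = mode)
  instP <- vapply(instKeys, function(keys)
    scoreCandidate(stack, keys, metric = metric, scope = scope,
                   paired = paired, graphs = graphs), numeric(1L))
  names(instP) <- nm
  mi <- which.min(instP)              # first occurrence wins ties
  main <- instKeys[[mi]]
  unsorted <- unlist(instKeys[-mi], use.names = FALSE)
  if (length(unsorted) > 0L) {
    roiP <- vapply(unsorted, function(key)
      scoreCandidate(stack, key, metric = metric, paired = paired,
                     graphs = graphs), numeric(1L))
    roiP[!is.finite(roiP)] <- 1
    ord <- order(roiP, seq_along(roiP))   # stable ascending
    supp <- unsorted[ord]
    roiP <- roiP[ord]
    names(roiP) <- supp
  } else {
    supp <- character(0L)
    roiP <- stats::setNames(numeric(0L), character(0L))
  }
  methods::new("SelectionResult", mainInstance = nm[mi], mainRois = main,
               suppRois = supp, instancePvalues = instP, roiPvalues = roiP)
}

#' Greedy prefix fusion of supplementary ROIs into the main network
#'
#' Evaluates the candidate networks formed by the main ROIs plus the first
#' i supplementary ROIs for every prefix length i = 0..|suppRois| (length
#' 0 is the main network alone, so the fused network can never score worse
#' than the main network), and absorbs the prefix with the minimum
#' discriminability p-value (first occurrence on ties). The search is
#' fully deterministic.
#'
#' @param stack a \code{ConditionStack}.
#' @param selection a \code{SelectionResult} consistent with the stack.
#' @param metric,q,mode,scope,paired scoring parameters, as in
#'   \code{\link{selectMain}}.
#' @param suppOrder optional externally produced priority ordering (any
#'   permutation of \code{suppRois(selection)}), enabling rankings from
#'   external feature-importance methods to drive the same prefix search.
#' @return a \code{\linkS4class{FusionResult}}.
#' @export
fuseNetworks <- function(stack, selection, metric = "degree", q = 0.05,
                         mode = "positive", scope = "induced",
                         paired = TRUE, suppOrder = NULL) {
  stopifnot(methods::is(selection, "SelectionResult"))
  supp <- if (is.null(suppOrder)) selection@suppRois else as.character(suppOrder)
  if (!setequal(supp, selection@suppRois) ||
      length(supp) != length(selection@suppRois))
    stop("suppOrder must be a permutation of the selection's supplementary ROIs")
  main <- selection@mainRois
  graphs <- stackGraphs(stack, q = q, mode = mode)
  trace <- vapply(0L:length(supp), function(i)
    scoreCandidate(stack, c(main, utils::head(supp, i)), metric = metric,
                   scope = scope, paired = paired, graphs = graphs),
    numeric(1L))
  idx <- which.min(trace) - 1L        # first argmin; prefix length
  methods::new("FusionResult",
               fusedRois = c(main, utils::head(supp, idx)),
               fusedIndex = idx, pvalueTrace = trace,
               fusedPvalue = trace[idx + 1L])
}
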