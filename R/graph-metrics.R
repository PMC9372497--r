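## graph metrics on FDR-thresholded binary connectivity graphs.

#' Construct a binary graph
#' @param nodes ordered node (ROI key) vector.
#' @param adjacency symmetric logical matrix, FALSE diagonal.
#' @return a \code{\linkS4class{BinaryGraph}}.
#' @export
BinaryGraph <- function(nodes, adjacency) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "logical"
  dimnames(adjacency) <- list(nodes, nodes)
  methods::new("BinaryGraph", nodes = as.character(nodes),
               adjacency = adjacency)
}

setMethod("show", "BinaryGraph", function(object) {
  n <- length(object@nodes)
  m <- sum(object@adjacency) / 2L
  cat(sprintf("BinaryGraph: %d nodes, %d edges (density %.3f)\n",
              n, m, if (n > 1L) m / (n * (n - 1L) / 2L) else 0))
  invisible(object)
})

#' Edge list of a binary graph
#' @param g a \code{BinaryGraph}.
#' @return \code{data.frame} with columns \code{from}, \code{to} (one row
#'   per undirected edge).
#' @export
edgeList <- function(g) {
  stopifnot(methods::is(g, "BinaryGraph"))
  idx <- which(g@adjacency & upper.tri(g@adjacency), arr.ind = TRUE)
  data.frame(from = g@nodes[idx[, 1L]], to = g@nodes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' @rdname edgeList
#' @param path output TSV path.
#' @return \code{writeEdgeList}: \code{path}, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  utils::write.table(edgeList(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Threshold one connectivity slice into a binary graph
#'
#' Edges are the node pairs whose correlation p-value survives
#' Benjamini-Hochberg FDR control at rate \code{q} on that slice
#' (family = all node pairs of the slice) and whose sign satisfies the
#' chosen mode: \code{"positive"} keeps r > 0 only (the common connectome
#' convention), \code{"absolute"} keeps either sign.
#'
#' @param stack a \code{ConditionStack}.
#' @param condition,subject slice selectors (token or index).
#' @param q FDR rate (default 0.05).
#' @param mode \code{"positive"} or \code{"absolute"}.
#' @return a \code{\linkS4class{BinaryGraph}} on the stack's ROI keys.
#' @export
thresholdGraph <- function(stack, condition, subject, q = 0.05,
                           mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  r <- connMatrix(stack, condition, subject)
  p <- pvalMatrix(stack, condition, subject)
  mask <- fdrEdges(p, q)
  if (mode == "positive") mask <- mask & (r > 0)
  mask <- mask & t(mask)          # sign filter keeps symmetry
  diag(mask) <- FALSE
  BinaryGraph(roiKeys(stack), mask)
}

#' Threshold every slice of a stack
#'
#' Convenience cache used by \code{\link{selectMain}} and
#' \code{\link{fuseNetworks}} so each slice is thresholded once.
#'
#' @inheritParams thresholdGraph
#' @return nested list: \code{graphs[[ci]][[si]]} is the
#'   \code{BinaryGraph} of condition \code{ci}, subject \code{si}.
#' @export
stackGraphs <- function(stack, q = 0.05, mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  lapply(seq_along(stack@conditions), function(ci)
    lapply(seq_along(stack@subjects), function(si)
      thresholdGraph(stack, ci, si, q = q, mode = mode)))
}

.subsetIndex <- function(g, subset) {
  i <- match(subset, g@nodes)
  if (any(is.na(i)))
    stop(sprintf("node(s) not in graph: %s",
                 paste(utils::head(subset[is.na(i)], 3L), collapse = ", ")))
  i
}

#' Degree centrality of one node
#'
#' Degree divided by (n - 1), where n is the number of nodes of the full
#' graph; lies in [0, 1].
#'
#' @param g a \code{BinaryGraph} with >= 2 nodes.
#' @param v node key.
#' @return numeric in [0, 1].
#' @export
nodalDegreeCentrality <- function(g, v) {
  stopifnot(methods::is(g, "BinaryGraph"))
  n <- length(g@nodes)
  if (n < 2L) stop("graph must have at least 2 nodes")
  i <- .subsetIndex(g, v)
  if (length(i) != 1L) stop("'v' must be a single node")
  sum(g@adjacency[i, ]) / (n - 1L)
}

#' Mean degree centrality of an induced subgraph
#'
#' Restricts the graph to \code{subset}, computes each member's degree
#' within that induced subgraph normalized by (|subset| - 1), and returns
#' the mean. This makes a candidate network's score independent of ROIs
#' outside the candidate.
#'
#' @param g a \code{BinaryGraph}.
#' @param subset node keys, |subset| >= 2 (use
#'   \code{\link{nodalDegreeCentrality}} for single nodes).
#' @return numeric in [0, 1].
#' @export
subsetMeanDegreeCentrality <- function(g, subset) {
  stopifnot(methods::is(g, "BinaryGraph"))
  i <- .subsetIndex(g, subset)
  k <- length(i)
  if (k < 2L) stop("subset must contain at least 2 nodes; use nodalDegreeCentrality")
  A <- g@adjacency[i, i, drop = FALSE]
  mean(rowSums(A)) / (k - 1L)
}

## local clustering coefficients from the adjacency matrix: the triangle
## count through v is (A^3)_vv / 2, the open-triple count k_v (k_v - 1) / 2
.localClustering <- function(A) {
  M <- A * 1
  a3 <- diag(M %*% M %*% M)
  deg <- rowSums(M)
  ifelse(deg >= 2, a3 / (deg * (deg - 1)), 0)
}

## all-pairs geodesic distances by breadth-first expansion of the
## boolean reachability matrix (unreachable pairs stay Inf)
.geodesics <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n < 2L) return(D)
  M <- A * 1
  P <- diag(1, n)
  for (step in seq_len(n - 1L)) {
    P <- (P %*% M) > 0
    fresh <- P & !is.finite(D)
    if (!any(fresh)) break
    D[fresh] <- step
  }
  D
}

#' Clustering coefficient (induced subgraph or single node)
#'
#' For a multi-node subset: mean local clustering coefficient of the
#' subgraph induced by \code{subset} (nodes with degree < 2 count 0). For
#' a single node: its local clustering coefficient within the full graph.
#'
#' @inheritParams subsetMeanDegreeCentrality
#' @return numeric in [0, 1].
#' @export
clusteringCoefficient <- function(g, subset) {
  stopifnot(methods::is(g, "BinaryGraph"))
  i <- .subsetIndex(g, subset)
  if (length(i) == 1L)
    return(unname(.localClustering(g@adjacency)[i]))
  unname(mean(.localClustering(g@adjacency[i, i, drop = FALSE])))
}

#' Global efficiency (induced subgraph or single node)
#'
#' Mean inverse shortest-path length over ordered node pairs of the
#' induced subgraph (disconnected pairs contribute 0). For a single node:
#' the node's mean inverse distance to every other node of the full graph.
#'
#' @inheritParams subsetMeanDegreeCentrality
#' @return numeric in [0, 1].
#' @export
globalEfficiency <- function(g, subset) {
  stopifnot(methods::is(g, "BinaryGraph"))
  i <- .subsetIndex(g, subset)
  if (length(i) == 1L) {
    if (length(g@nodes) < 2L) stop("graph must have at least 2 nodes")
    d <- .geodesics(g@adjacency)[i, -i]
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    return(unname(mean(inv)))
  }
  D <- .geodesics(g@adjacency[i, i, drop = FALSE])
  inv <- 1 / D[row(D) != col(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Graph-property dispatcher
#'
#' Computes the configured property of a node subset on a thresholded
#' graph. The subset size decides the flavour: a single ROI yields the
#' nodal property within the full graph (its degree centrality, local
#' clustering, or nodal efficiency), while a multi-ROI subset yields the
#' candidate-network property. For multi-ROI subsets, \code{scope}
#' selects between the induced-subgraph reading (default: member degrees
#' counted inside the candidate only, normalized by |subset| - 1) and the
#' full-graph reading (degrees within the whole combined-network graph,
#' normalized by |nodes| - 1, averaged over the subset; degree metric
#' only).
#'
#' @param g a \code{BinaryGraph}.
#' @param subset node keys (length 1 for the nodal property).
#' @param metric \code{"degree"} (default), \code{"clustering"}, or
#'   \code{"efficiency"}.
#' @param scope \code{"induced"} (default) or \code{"full"}; only
#'   meaningful for multi-node subsets.
#' @return numeric property value.
#' @export
graphProperty <- function(g, subset,
                          metric = c("degree", "clustering", "efficiency"),
                          scope = c("induced", "full")) {
  metric <- match.arg(metric)
  scope <- match.arg(scope)
  if (length(subset) == 1L) {
    return(switch(metric,
      degree = nodalDegreeCentrality(g, subset),
      clustering = clusteringCoefficient(g, subset),
      efficiency = globalEfficiency(g, subset)))
  }
  if (scope == "full") {
    if (metric != "degree")
      stop("full-graph scope is only defined for the degree metric")
    i <- .subsetIndex(g, subset)
    n <- length(g@nodes)
    return(mean(rowSums(g@adjacency[i, , drop = FALSE])) / (n - 1L))
  }
  switch(metric,
    degree = subsetMeanDegreeCentrality(g, subset),
    clustering = clusteringCoefficient(g, subset),
    efficiency = globalEfficiency(g, subset))
}
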