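## statistical dispatcher: discriminability of graph properties across
## cognitive conditions.

#' Construct an index matrix
#' @param conditions ordered condition tokens (rows).
#' @param subjects ordered subject tokens (columns).
#' @param values numeric matrix |conditions| x |subjects|.
#' @return an \code{\linkS4class{IndexMatrix}}.
#' @export
IndexMatrix <- function(conditions, subjects, values) {
  values <- as.matrix(values)
  dimnames(values) <- list(conditions, subjects)
  methods::new("IndexMatrix", conditions = as.character(conditions),
               subjects = as.character(subjects), values = values)
}

#' @describeIn conditions conditions of an index matrix
#' @export
setMethod("conditions", "IndexMatrix", function(x) x@conditions)
#' @describeIn subjects subjects of an index matrix
#' @export
setMethod("subjects", "IndexMatrix", function(x) x@subjects)

setMethod("show", "IndexMatrix", function(object) {
  cat(sprintf("IndexMatrix: %d condition(s) x %d subject(s)\n",
              length(object@conditions), length(object@subjects)))
  print(round(object@values, 4L))
  invisible(object)
})

#' Discriminability p-value of an index matrix
#'
#' Compares the rows (conditions) of the property matrix. With exactly two
#' conditions a two-sided t test is used, paired across subjects by
#' default (the same subjects perform every condition in a within-subject
#' design); with more than two conditions a one-way ANOVA F test is used.
#'
#' Degenerate inputs are resolved deterministically: if every condition
#' row is constant the test is undefined and p = 1 is returned with a
#' warning; if the paired differences are constant but non-zero the
#' t statistic diverges and the limiting p = 0 is returned.
#'
#' @param m an \code{IndexMatrix} with >= 2 conditions and >= 2 subjects.
#' @param paired pair the two-condition t test across subjects
#'   (default TRUE); ignored for > 2 conditions.
#' @return p-value in [0, 1] with attributes \code{method} and
#'   \code{paired} recording the dispatch.
#' @examples
#' m <- IndexMatrix(c("add", "sub"), paste0("s", 1:6),
#'                  rbind(rnorm(6, 1), rnorm(6, 0)))
#' discriminability(m)
#' @export
discriminability <- function(m, paired = TRUE) {
  stopifnot(methods::is(m, "IndexMatrix"))
  v <- m@values
  nc <- nrow(v)
  if (nc < 2L) stop("need at least 2 conditions")
  if (ncol(v) < 2L) stop("need at least 2 subjects")
  rowVar <- apply(v, 1L, stats::var)
  method <- if (nc == 2L) if (paired) "paired t" else "two-sample t" else "one-way ANOVA"
  finish <- function(p) {
    p <- min(max(p, 0), 1)
    attr(p, "method") <- method
    attr(p, "paired") <- if (nc == 2L) paired else NA
    p
  }
  if (all(rowVar == 0)) {
    warning("zero variance in all groups; test undefined, p = 1")
    return(finish(1))
  }
  if (nc == 2L) {
    x <- v[1L, ]; y <- v[2L, ]
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) {
        # constant differences: t statistic 0 (all zero) or +-Inf limit
        return(finish(if (all(d == 0)) 1 else 0))
      }
      return(finish(stats::t.test(x, y, paired = TRUE)$p.value))
    }
    return(finish(stats::t.test(x, y, var.equal = TRUE)$p.value))
  }
  grp <- factor(rep(seq_len(nc), times = ncol(v)))
  val <- as.vector(v)                 # column-major: conditions fastest
  ow <- stats::oneway.test(val ~ grp, var.equal = TRUE)
  p <- ow$p.value
  if (!is.finite(p)) {
    # zero residual variance: F is 0/0 when the group means coincide and
    # diverges otherwise
    means <- rowMeans(v)
    p <- if (max(means) - min(means) == 0) 1 else 0
  }
  finish(p)
}

#' Per-cell index matrix of a candidate ROI subset
#'
#' Fills the |conditions| x |subjects| matrix of graph-property values for
#' one candidate subset: each cell is the property of \code{subset} on the
#' FDR-thresholded graph of that design cell.
#'
#' @param stack a \code{ConditionStack}.
#' @param subset ROI keys of the candidate (length 1 gives the nodal
#'   property on the full graph).
#' @param metric,scope passed to \code{\link{graphProperty}}.
#' @param q,mode thresholding parameters (see \code{\link{thresholdGraph}}).
#' @param graphs optional precomputed \code{\link{stackGraphs}} cache;
#'   when supplied, \code{q} and \code{mode} are ignored.
#' @return an \code{\linkS4class{IndexMatrix}}.
#' @export
candidateIndexMatrix <- function(stack, subset, metric = "degree",
                                 q = 0.05, mode = "positive",
                                 scope = "induced", graphs = NULL) {
  if (is.null(graphs)) graphs <- stackGraphs(stack, q = q, mode = mode)
  nC <- length(stack@conditions); nS <- length(stack@subjects)
  vals <- matrix(NA_real_, nC, nS)
  for (ci in seq_len(nC)) for (si in seq_len(nS))
    vals[ci, si] <- graphProperty(graphs[[ci]][[si]], subset,
                                  metric = metric, scope = scope)
  IndexMatrix(stack@conditions, stack@subjects, vals)
}

#' Discriminability score of a candidate ROI subset
#'
#' The core scoring primitive of the selection and fusion algorithms:
#' compute the graph property of \code{subset} in every design cell, then
#' test whether that property discriminates the conditions.
#'
#' @inheritParams candidateIndexMatrix
#' @param paired see \code{\link{discriminability}}.
#' @return p-value in [0, 1].
#' @export
scoreCandidate <- function(stack, subset, metric = "degree", q = 0.05,
                           mode = "positive", scope = "induced",
                           paired = TRUE, graphs = NULL) {
  im <- candidateIndexMatrix(stack, subset, metric = metric, q = q,
                             mode = mode, scope = scope, graphs = graphs)
  p <- suppressWarnings(discriminability(im, paired = paired))
  as.numeric(p)
}
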