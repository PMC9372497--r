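## connectivity: Pearson functional connectivity, FDR edge selection, and
## the condition x subject stack of matrices.

#' Construct a per-subject, per-condition time-series set
#' @param condition condition token.
#' @param subject subject token.
#' @param data numeric matrix, rows = time points, columns = ROIs in
#'   combined-network order; column names should be ROI keys.
#' @return a \code{\linkS4class{TimeSeriesSet}}.
#' @export
TimeSeriesSet <- function(condition, subject, data) {
  methods::new("TimeSeriesSet", condition = as.character(condition),
               subject = as.character(subject), data = as.matrix(data))
}

#' @describeIn conditions condition of a time-series set
#' @export
setMethod("conditions", "TimeSeriesSet", function(x) x@condition)
#' @describeIn subjects subject of a time-series set
#' @export
setMethod("subjects", "TimeSeriesSet", function(x) x@subject)

setMethod("show", "TimeSeriesSet", function(object) {
  cat(sprintf("TimeSeriesSet [%s, %s]: %d time points x %d ROIs\n",
              object@condition, object@subject,
              nrow(object@data), ncol(object@data)))
  invisible(object)
})

#' Pearson functional connectivity of one time-series matrix
#'
#' Computes the full product-moment correlation matrix of the columns,
#' with two-sided p-values from the t distribution on t - 2 degrees of
#' freedom. Columns with zero variance cannot carry a correlation: their
#' edges are set to r = 0 with p = 1 and a warning is emitted, so a single
#' flat ROI does not abort a group run.
#'
#' @param x numeric matrix, rows = time points (>= 3), columns = ROIs.
#' @return list with components \code{r} (symmetric, unit diagonal) and
#'   \code{p} (two-sided p-values, zero diagonal).
#' @examples
#' ts <- matrix(rnorm(200), 40, 5)
#' fc <- pearsonFC(ts)
#' range(fc$r[upper.tri(fc$r)])
#' @export
pearsonFC <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 time points")
  sds <- apply(x, 2L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  if (any(flat)) {
    cn <- colnames(x)
    if (is.null(cn)) cn <- as.character(seq_len(ncol(x)))
    warning(sprintf("%d zero-variance column(s) (%s): affected edges set to r = 0, p = 1",
                    sum(flat),
                    paste(utils::head(cn[flat], 3L), collapse = ", ")))
    r[flat, ] <- 0; r[, flat] <- 0
  }
  diag(r) <- 1
  p <- .corPvalue(r, n)
  diag(p) <- 0
  if (any(flat)) { p[flat, ] <- 1; p[, flat] <- 1; diag(p) <- 0 }
  dimnames(p) <- dimnames(r)
  list(r = r, p = p)
}

## two-sided p for a Pearson r at sample size n (t distribution, n - 2 df)
.corPvalue <- function(r, n) {
  denom <- pmax(1 - r^2, .Machine$double.xmin)
  tstat <- abs(r) * sqrt((n - 2) / denom)
  2 * stats::pt(-tstat, df = n - 2)
}

#' Benjamini-Hochberg edge selection on a p-value matrix
#'
#' Applies the BH step-up procedure to the upper-triangle p-values (the
#' family size is the number of distinct node pairs) and returns the
#' symmetric boolean mask of edges surviving FDR control at rate \code{q}.
#'
#' @param p symmetric matrix of edge p-values.
#' @param q target false-discovery rate, 0 < q < 1.
#' @return symmetric logical matrix, FALSE diagonal.
#' @export
fdrEdges <- function(p, q = 0.05) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (!(q > 0 && q < 1)) stop("q must lie strictly between 0 and 1")
  ut <- upper.tri(p)
  keep <- stats::p.adjust(p[ut], method = "BH") <= q
  mask <- matrix(FALSE, nrow(p), ncol(p), dimnames = dimnames(p))
  mask[ut] <- keep
  mask | t(mask)
}

#' Assemble the condition x subject connectivity stack
#'
#' Builds the 4-D array of functional-connectivity matrices (and matching
#' edge p-values) over the ROIs of a combined network, one slice per
#' (condition, subject) cell. The design must be complete and balanced:
#' every condition x subject pair present exactly once. Condition and
#' subject order follow first appearance in \code{series}.
#'
#' @param series list of \code{TimeSeriesSet}, one per design cell.
#' @param ccn the \code{CombinedNetwork} whose ROI order defines the
#'   matrix dimensions; each series must have one column per ROI (matching
#'   keys when column names are present).
#' @return a \code{\linkS4class{ConditionStack}}.
#' @export
buildStack <- function(series, ccn) {
  stopifnot(methods::is(ccn, "CombinedNetwork"))
  if (length(series) == 0L) stop("no time series supplied")
  keys <- roiKeys(ccn)
  cs <- vapply(series, function(s) s@condition, character(1L))
  ss <- vapply(series, function(s) s@subject, character(1L))
  cell <- paste(cs, ss, sep = "\r")
  if (anyDuplicated(cell)) {
    d <- which(duplicated(cell))[1L]
    stop(sprintf("duplicate design cell (condition '%s', subject '%s')",
                 cs[d], ss[d]))
  }
  conds <- unique(cs); subs <- unique(ss)
  want <- as.vector(outer(conds, subs, paste, sep = "\r"))
  absent <- setdiff(want, cell)
  if (length(absent) > 0L)
    stop(sprintf("incomplete design; missing cell(s): %s",
                 paste(gsub("\r", " x ", absent), collapse = ", ")))
  nR <- length(keys)
  mats <- array(NA_real_, dim = c(length(conds), length(subs), nR, nR),
                dimnames = list(conds, subs, keys, keys))
  pvs <- mats
  for (k in seq_along(series)) {
    x <- series[[k]]@data
    if (ncol(x) != nR)
      stop(sprintf("series [%s, %s] has %d columns; combined network has %d ROIs",
                   cs[k], ss[k], ncol(x), nR))
    if (!is.null(colnames(x)) && !identical(colnames(x), keys))
      stop(sprintf("series [%s, %s] column names do not match the combined ROI keys",
                   cs[k], ss[k]))
    fc <- pearsonFC(x)
    ci <- match(cs[k], conds); si <- match(ss[k], subs)
    mats[ci, si, , ] <- fc$r
    pvs[ci, si, , ] <- fc$p
  }
  methods::new("ConditionStack", conditions = conds, subjects = subs,
               rois = roiTable(ccn), matrices = mats, pvals = pvs)
}

#' @describeIn conditions conditions of a stack
#' @export
setMethod("conditions", "ConditionStack", function(x) x@conditions)
#' @describeIn subjects subjects of a stack
#' @export
setMethod("subjects", "ConditionStack", function(x) x@subjects)
#' @describeIn nRois ROI count of a stack
#' @export
setMethod("nRois", "ConditionStack", function(x) nrow(x@rois))
#' @describeIn roiTable ROI table of a stack
#' @export
setMethod("roiTable", "ConditionStack", function(x) x@rois)
#' @describeIn roiKeys keys of a stack
#' @export
setMethod("roiKeys", "ConditionStack",
          function(x) paste(x@rois$atlas, x@rois$roi_id, sep = ":"))

setMethod("show", "ConditionStack", function(object) {
  cat(sprintf("ConditionStack: %d condition(s) x %d subject(s) x %d x %d ROIs\n",
              length(object@conditions), length(object@subjects),
              nrow(object@rois), nrow(object@rois)))
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  invisible(object)
})

.sliceIndex <- function(stack, condition, subject) {
  ci <- if (is.character(condition)) match(condition, stack@conditions) else as.integer(condition)
  si <- if (is.character(subject)) match(subject, stack@subjects) else as.integer(subject)
  if (is.na(ci) || ci < 1L || ci > length(stack@conditions))
    stop("unknown condition")
  if (is.na(si) || si < 1L || si > length(stack@subjects))
    stop("unknown subject")
  c(ci, si)
}

#' Extract one connectivity slice from a stack
#' @param stack a \code{ConditionStack}.
#' @param condition condition token or index.
#' @param subject subject token or index.
#' @return correlation (\code{connMatrix}) or p-value (\code{pvalMatrix})
#'   matrix of that design cell.
#' @export
connMatrix <- function(stack, condition, subject) {
  i <- .sliceIndex(stack, condition, subject)
  stack@matrices[i[1L], i[2L], , ]
}

#' @rdname connMatrix
#' @export
pvalMatrix <- function(stack, condition, subject) {
  i <- .sliceIndex(stack, condition, subject)
  stack@pvals[i[1L], i[2L], , ]
}

#' Write / read a directory of per-cell time-series tables
#'
#' One TSV per design cell, named \code{{condition}__{subject}.tsv}, with a
#' header row of ROI keys in combined order and one row per time point.
#'
#' @param series list of \code{TimeSeriesSet}.
#' @param dir directory (created if needed).
#' @return \code{writeTimeSeriesDir}: \code{dir}, invisibly;
#'   \code{readTimeSeriesDir}: list of \code{TimeSeriesSet}.
#' @export
writeTimeSeriesDir <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in series) {
    f <- file.path(dir, sprintf("%s__%s.tsv", s@condition, s@subject))
    utils::write.table(s@data, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !is.null(colnames(s@data)))
  }
  invisible(dir)
}

#' @rdname writeTimeSeriesDir
#' @export
readTimeSeriesDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "__.*\\.tsv$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no '{condition}__{subject}.tsv' files found in '%s'", dir))
  lapply(files, function(f) {
    base <- sub("\\.tsv$", "", basename(f))
    parts <- strsplit(base, "__", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("file name '%s' does not match '{condition}__{subject}.tsv'",
                   basename(f)))
    x <- as.matrix(utils::read.delim(f, header = TRUE, sep = "\t",
                                     check.names = FALSE))
    TimeSeriesSet(parts[1L], parts[2L], x)
  })
}

#' Serialize / restore a condition stack as a directory of TSV tables
#'
#' Writes one correlation and one p-value TSV per design cell plus the ROI
#' table and a small JSON manifest; \code{loadStack} restores a
#' bit-compatible \code{ConditionStack}.
#'
#' @param stack a \code{ConditionStack}.
#' @param dir directory (created if needed).
#' @return \code{saveStack}: \code{dir}, invisibly; \code{loadStack}: a
#'   \code{ConditionStack}.
#' @export
saveStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(stack@rois, file.path(dir, "rois.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(conditions = stack@conditions,
                            subjects = stack@subjects),
                       file.path(dir, "stack.json"), auto_unbox = FALSE)
  for (ci in seq_along(stack@conditions)) for (si in seq_along(stack@subjects)) {
    tag <- sprintf("%s__%s", stack@conditions[ci], stack@subjects[si])
    utils::write.table(stack@matrices[ci, si, , ],
                       file.path(dir, paste0(tag, ".corr.tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(stack@pvals[ci, si, , ],
                       file.path(dir, paste0(tag, ".pval.tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname saveStack
#' @export
loadStack <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "stack.json"))
  rois <- utils::read.delim(file.path(dir, "rois.tsv"), sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  keys <- paste(rois$atlas, rois$roi_id, sep = ":")
  nR <- nrow(rois)
  dims <- c(length(meta$conditions), length(meta$subjects), nR, nR)
  mats <- array(NA_real_, dims,
                dimnames = list(meta$conditions, meta$subjects, keys, keys))
  pvs <- mats
  for (ci in seq_along(meta$conditions)) for (si in seq_along(meta$subjects)) {
    tag <- sprintf("%s__%s", meta$conditions[ci], meta$subjects[si])
    mats[ci, si, , ] <- as.matrix(utils::read.delim(
      file.path(dir, paste0(tag, ".corr.tsv")), header = FALSE, sep = "\t"))
    pvs[ci, si, , ] <- as.matrix(utils::read.delim(
      file.path(dir, paste0(tag, ".pval.tsv")), header = FALSE, sep = "\t"))
  }
  methods::new("ConditionStack", conditions = meta$conditions,
               subjects = meta$subjects, rois = rois,
               matrices = mats, pvals = pvs)
}
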