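## synthetic data: planted-subnetwork generator and size-faithful
## synthetic atlas fixtures.

## deterministic, globally unique synthetic MNI coordinates for ROI j
.synCoords <- function(j) {
  cbind(x = -60 + 3 * ((j - 1L) %% 41L),
        y = -88 + 11 * ((j - 1L) %/% 41L),
        z = -20 + 2 * ((j - 1L) %% 35L))
}

.instanceKeysFor <- function(instanceSizes, atlases) {
  lapply(seq_along(instanceSizes), function(k)
    paste(atlases[k], sprintf("r%02d", seq_len(instanceSizes[k])), sep = ":"))
}

## default instance sizes: the 10/21/24/17 partition at 72 ROIs, scaled
## proportionally otherwise (largest-remainder rounding)
.defaultSizes <- function(nRois) {
  base <- c(10L, 21L, 24L, 17L)
  if (nRois == 72L) return(base)
  raw <- nRois * base / 72
  sz <- floor(raw)
  rem <- nRois - sum(sz)
  if (rem > 0L) {
    o <- order(raw - sz, decreasing = TRUE)
    sz[o[seq_len(rem)]] <- sz[o[seq_len(rem)]] + 1L
  }
  as.integer(sz)
}

#' Specify a planted-subnetwork simulation design
#'
#' Describes a multi-condition, multi-subject synthetic experiment over a
#' combined network partitioned into atlas-like instances. A known ROI
#' subset (the planted set) carries a condition-dependent correlation:
#' within the planted block the pairwise correlation is
#' \code{baseCorr + effect} in condition 1 and \code{baseCorr} in every
#' other condition, while all remaining pairs sit at \code{baseCorr / 2}
#' regardless of condition. Per-subject variability enters as symmetric
#' Gaussian jitter (SD \code{subjectSd}) added to the subject's
#' correlation targets, shared across that subject's conditions.
#'
#' Defaults mirror a two-condition within-subject study of 21 subjects
#' over a 72-ROI combined network split 10/21/24/17 across four mock
#' atlases with 47 frontal and 25 parietal ROIs. The default planted set
#' is the whole second instance plus the first ROI of each other
#' instance, so the condition effect is concentrated in one instance but
#' spills into a few supplementary ROIs.
#'
#' @param nConditions,nSubjects,nRois,nTime design counts (defaults
#'   2, 21, 72, 180).
#' @param instanceSizes integer sizes of the mock instances (must sum to
#'   \code{nRois}); default splits \code{nRois} proportionally to
#'   10/21/24/17.
#' @param frontalCounts frontal ROIs per instance (rest parietal);
#'   defaults to the 47/72 frontal share, exactly 6/13/17/11 at the
#'   default scale.
#' @param plantedRois ROI keys carrying the effect; \code{NULL} for the
#'   default described above.
#' @param baseCorr baseline planted-block correlation (default 0.3, a
#'   typical within-network functional-connectivity level).
#' @param effect added planted-block correlation in condition 1
#'   (default 0.4).
#' @param subjectSd SD of the per-subject correlation jitter
#'   (default 0.05).
#' @param seed RNG seed for \code{\link{generatePlanted}}.
#' @return a \code{\linkS4class{PlantedDesign}}.
#' @export
plantedDesign <- function(nConditions = 2L, nSubjects = 21L, nRois = 72L,
                          nTime = 180L, instanceSizes = NULL,
                          frontalCounts = NULL, plantedRois = NULL,
                          baseCorr = 0.3, effect = 0.4, subjectSd = 0.05,
                          seed = 1L) {
  if (is.null(instanceSizes)) instanceSizes <- .defaultSizes(as.integer(nRois))
  instanceSizes <- as.integer(instanceSizes)
  if (is.null(frontalCounts)) {
    if (identical(instanceSizes, c(10L, 21L, 24L, 17L))) {
      frontalCounts <- c(6L, 13L, 17L, 11L)
    } else {
      frontalCounts <- pmin(instanceSizes, as.integer(round(instanceSizes * 47 / 72)))
    }
  }
  atlases <- paste0("atlas", LETTERS[seq_along(instanceSizes)])
  keys <- .instanceKeysFor(instanceSizes, atlases)
  if (is.null(plantedRois)) {
    anchor <- min(2L, length(keys))
    plantedRois <- keys[[anchor]]
    for (k in seq_along(keys))
      if (k != anchor) plantedRois <- c(plantedRois, keys[[k]][1L])
  }
  universe <- unlist(keys, use.names = FALSE)
  if (!all(plantedRois %in% universe))
    stop("plantedRois must be drawn from the generated ROI keys")
  methods::new("PlantedDesign",
               nConditions = as.integer(nConditions),
               nSubjects = as.integer(nSubjects),
               nRois = as.integer(nRois), nTime = as.integer(nTime),
               instanceSizes = instanceSizes,
               frontalCounts = as.integer(frontalCounts),
               plantedRois = as.character(plantedRois),
               baseCorr = baseCorr, effect = effect,
               subjectSd = subjectSd, seed = as.integer(seed))
}

setMethod("show", "PlantedDesign", function(object) {
  cat(sprintf(paste0("PlantedDesign: %d condition(s) x %d subject(s) x %d ROIs, ",
                     "t = %d\n  instances: %s | planted: %d ROIs | ",
                     "baseCorr %.2f, effect %.2f, subjectSd %.2f, seed %d\n"),
              object@nConditions, object@nSubjects, object@nRois,
              object@nTime, paste(object@instanceSizes, collapse = "/"),
              length(object@plantedRois), object@baseCorr, object@effect,
              object@subjectSd, object@seed))
  invisible(object)
})

## project a symmetric matrix to the nearest PSD correlation matrix
## (eigenvalue clipping + rescale to unit diagonal)
.nearPSDcorr <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 1e-10) return(S)
  v <- pmax(e$values, 1e-8)
  S2 <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(S2))
  S2 <- S2 * tcrossprod(d)
  diag(S2) <- 1
  S2
}

.targetCorr <- function(design, conditionIndex, plantedIdx) {
  n <- design@nRois
  S <- matrix(design@baseCorr / 2, n, n)
  block <- design@baseCorr + if (conditionIndex == 1L) design@effect else 0
  S[plantedIdx, plantedIdx] <- block
  diag(S) <- 1
  S
}

#' Generate planted-subnetwork time series
#'
#' Draws zero-mean Gaussian ROI time series whose population correlation
#' follows the block structure of the design (see
#' \code{\link{plantedDesign}}). Each subject receives one symmetric
#' jitter matrix applied to the targets of all their conditions; jittered
#' targets are projected to the nearest positive-semidefinite correlation
#' matrix before sampling. Fully reproducible from the design seed.
#'
#' The base (unjittered) target of every condition is checked for
#' positive semidefiniteness up front and generation aborts, reporting
#' the offending eigenvalue, if the requested block correlations are
#' infeasible.
#'
#' @param design a \code{PlantedDesign}.
#' @return list with components \code{instances} (named list of mock
#'   \code{NetworkInstance}), \code{series} (list of
#'   \code{TimeSeriesSet}, one per design cell), \code{planted} (the
#'   planted ROI keys) and \code{design}.
#' @examples
#' d <- plantedDesign(nSubjects = 4L, nRois = 24L, nTime = 60L, seed = 7L)
#' sim <- generatePlanted(d)
#' stack <- buildStack(sim$series, combineInstances(sim$instances))
#' @export
generatePlanted <- function(design) {
  stopifnot(methods::is(design, "PlantedDesign"))
  set.seed(design@seed)
  atlases <- paste0("atlas", LETTERS[seq_along(design@instanceSizes)])
  keyList <- .instanceKeysFor(design@instanceSizes, atlases)
  instances <- list()
  j0 <- 0L
  for (k in seq_along(design@instanceSizes)) {
    sz <- design@instanceSizes[k]
    xyz <- .synCoords(j0 + seq_len(sz))
    lobe <- c(rep("frontal", design@frontalCounts[k]),
              rep("parietal", sz - design@frontalCounts[k]))
    rois <- data.frame(roi_id = sprintf("r%02d", seq_len(sz)),
                       name = sprintf("%s ROI %d", atlases[k], seq_len(sz)),
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       lobe = lobe, network = "synFPN",
                       atlas = atlases[k], stringsAsFactors = FALSE)
    instances[[atlases[k]]] <- NetworkInstance("synFPN", atlases[k], rois)
    j0 <- j0 + sz
  }
  keys <- unlist(keyList, use.names = FALSE)
  plantedIdx <- match(design@plantedRois, keys)
  targets <- lapply(seq_len(design@nConditions), function(ci) {
    S <- .targetCorr(design, ci, plantedIdx)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf("target correlation matrix for condition %d is not positive semidefinite (eigenvalue %.4g)",
                   ci, min(ev)))
    S
  })
  conds <- sprintf("cond%d", seq_len(design@nConditions))
  subs <- sprintf("sub%02d", seq_len(design@nSubjects))
  n <- design@nRois
  series <- vector("list", design@nConditions * design@nSubjects)
  k <- 0L
  for (si in seq_len(design@nSubjects)) {
    J <- matrix(stats::rnorm(n * n, sd = design@subjectSd), n, n)
    J <- (J + t(J)) / 2
    diag(J) <- 0
    for (ci in seq_len(design@nConditions)) {
      S <- .nearPSDcorr(targets[[ci]] + J)
      L <- chol(S + diag(1e-8, n))
      X <- matrix(stats::rnorm(design@nTime * n), design@nTime, n) %*% L
      colnames(X) <- keys
      k <- k + 1L
      series[[k]] <- TimeSeriesSet(conds[ci], subs[si], X)
    }
  }
  list(instances = instances, series = series,
       planted = design@plantedRois, design = design)
}

#' Recovery metrics of a planted design
#'
#' Measures how well the selection + fusion pipeline recovered a known
#' planted ROI set: precision and recall of the planted ROIs within the
#' fused network, and recall within the top-k of the supplementary
#' priority list, where k is the number of planted ROIs that were
#' available as supplementary candidates.
#'
#' @param selection a \code{SelectionResult}.
#' @param fusion a \code{FusionResult}.
#' @param planted character vector of planted ROI keys (or the list
#'   returned by \code{\link{generatePlanted}}).
#' @return list with \code{precisionFused}, \code{recallFused},
#'   \code{topkRecall}, \code{k} and \code{mainIsPlantedInstance}
#'   (whether every main ROI is planted).
#' @export
evaluateRecovery <- function(selection, fusion, planted) {
  if (is.list(planted) && !is.null(planted$planted)) planted <- planted$planted
  planted <- as.character(planted)
  fused <- fusion@fusedRois
  hit <- intersect(fused, planted)
  suppPlanted <- intersect(selection@suppRois, planted)
  k <- length(suppPlanted)
  topk <- utils::head(selection@suppRois, k)
  list(precisionFused = if (length(fused)) length(hit) / length(fused) else 0,
       recallFused = if (length(planted)) length(hit) / length(planted) else 0,
       topkRecall = if (k > 0L) length(intersect(topk, planted)) / k else 1,
       k = k,
       mainIsPlantedInstance = all(selection@mainRois %in% planted))
}

## ---- size-faithful synthetic atlas fixtures ------------------------------

.SYN_SPECS <- list(
  synAAL          = list(network = "FPN", lobes = c(frontal = 6L, parietal = 4L)),
  synDosenbach160 = list(network = "FPN", lobes = c(frontal = 13L, parietal = 8L)),
  synPower264     = list(network = "FPN", lobes = c(frontal = 17L, parietal = 7L,
                                                    temporal = 1L)),
  synWillard499   = list(network = "ECN", lobes = c(frontal = 11L, parietal = 6L,
                                                    temporal = 1L, limbic = 1L,
                                                    cerebellum = 5L)),
  synGao32        = list(network = "FPN", lobes = c(frontal = 4L, parietal = 3L,
                                                    insula = 2L)))

#' Size-faithful synthetic atlas fixtures
#'
#' Deterministic stand-ins for the published fronto-parietal / executive
#' control network definitions of four brain atlases (plus a small
#' manually defined atlas), matching the real instance sizes and lobe
#' distributions but with synthetic coordinates: the raw set is
#' 10/21/25/24/9 ROIs, and the lobe-clipped, combinable set is
#' 10/21/24/17 ROIs (6/13/17/11 frontal, 4/8/7/6 parietal) for a 72-ROI
#' combined network. These fixtures exercise the combination and clipping
#' arithmetic; they are \emph{not} real atlas coordinate tables, and real
#' tables in the same TSV format can be supplied instead.
#'
#' @param clipped if TRUE (default), return the four frontal+parietal
#'   instances ready for combination (all relabelled to concept "FPN",
#'   small manual atlas excluded); if FALSE, return all five raw
#'   instances with their original lobe make-up and network labels.
#' @return \code{syntheticInstances}: named list of
#'   \code{NetworkInstance}; \code{syntheticAtlasTable}: the equivalent
#'   ROI \code{data.frame}.
#' @examples
#' nRois(combineInstances(syntheticInstances()))   # 72
#' @export
syntheticInstances <- function(clipped = TRUE) {
  out <- list()
  j0 <- 0L
  for (nm in names(.SYN_SPECS)) {
    spec <- .SYN_SPECS[[nm]]
    sz <- sum(spec$lobes)
    xyz <- .synCoords(j0 + seq_len(sz))
    rois <- data.frame(roi_id = sprintf("r%02d", seq_len(sz)),
                       name = sprintf("%s region %d", nm, seq_len(sz)),
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       lobe = rep(names(spec$lobes), spec$lobes),
                       network = spec$network, atlas = nm,
                       stringsAsFactors = FALSE)
    out[[nm]] <- NetworkInstance(spec$network, nm, rois)
    j0 <- j0 + sz
  }
  if (!clipped) return(out)
  out <- out[setdiff(names(out), "synGao32")]
  lapply(out, function(inst)
    relabelConcept(clipToLobes(inst, c("frontal", "parietal")), "FPN"))
}

#' @rdname syntheticInstances
#' @export
syntheticAtlasTable <- function(clipped = TRUE) {
  .instancesToFrame(syntheticInstances(clipped = clipped))
}
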