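## Spherical ROI extraction from 4-D NIfTI volumes.

#' Extract mean spherical ROI time series from a 4-D NIfTI image
#'
#' For each ROI, averages the signal of all voxels whose world (MNI mm)
#' coordinates lie within \code{radius} of the ROI centre, per time point.
#' The image affine (qform/sform) maps voxel indices to world coordinates;
#' inputs are assumed to be preprocessed and normalized to MNI space.
#'
#' @param image a 4-D NIfTI image, or a path readable by
#'   \code{RNifti::readNifti}.
#' @param rois a \code{NetworkInstance}, \code{CombinedNetwork}, or ROI
#'   \code{data.frame} with columns \code{roi_id}, \code{x}, \code{y},
#'   \code{z}, \code{atlas}.
#' @param radius sphere radius in millimetres (default 5).
#' @param condition,subject tokens stored in the returned set.
#' @return a \code{\linkS4class{TimeSeriesSet}} with one column per ROI
#'   (named by ROI key), rows = volumes.
#' @export
extractRoiTimeSeries <- function(image, rois, radius = 5,
                                 condition = "cond", subject = "sub") {
  if (!(radius > 0)) stop("radius must be positive")
  img <- if (is.character(image)) RNifti::readNifti(image) else RNifti::asNifti(image)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4-D image, got %d dimension(s)", length(dim(arr))))
  dims <- dim(arr)[1:3]
  nT <- dim(arr)[4L]
  tab <- if (is.data.frame(rois)) rois else roiTable(rois)
  keys <- paste(tab$atlas, tab$roi_id, sep = ":")
  vox <- RNifti::pixdim(img)[1:3]
  out <- matrix(NA_real_, nT, nrow(tab), dimnames = list(NULL, keys))
  for (i in seq_len(nrow(tab))) {
    centre <- c(tab$x[i], tab$y[i], tab$z[i])
    cv <- as.numeric(RNifti::worldToVoxel(matrix(centre, 1L), img))
    half <- ceiling(radius / vox) + 1
    lo <- pmax(floor(cv - half), 1)
    hi <- pmin(ceiling(cv + half), dims)
    if (any(lo > hi))
      stop(sprintf("sphere of radius %g mm around ROI '%s' contains no voxels",
                   radius, keys[i]))
    grid <- as.matrix(expand.grid(i = lo[1L]:hi[1L], j = lo[2L]:hi[2L],
                                  k = lo[3L]:hi[3L]))
    world <- RNifti::voxelToWorld(grid, img)
    d2 <- rowSums((world - matrix(centre, nrow(world), 3L, byrow = TRUE))^2)
    inside <- grid[d2 <= radius^2, , drop = FALSE]
    if (nrow(inside) == 0L)
      stop(sprintf("sphere of radius %g mm around ROI '%s' contains no voxels",
                   radius, keys[i]))
    for (t in seq_len(nT)) {
      vol <- arr[, , , t]
      out[t, i] <- mean(vol[inside])
    }
  }
  TimeSeriesSet(condition, subject, out)
}
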