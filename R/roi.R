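#' Extract ROI time series from a 4D NIfTI volume
#'
#' Convenience extractor for users starting from preprocessed volumetric
#' data: averages the BOLD signal over all voxels whose center lies within
#' `radius_mm` of each parcel coordinate (coordinates are interpreted in
#' the volume's world/MNI space via its stored affine). Requires the
#' RNifti package.
#'
#' @param nifti Path to a `.nii`/`.nii.gz` file, or an `niftiImage`/4D
#'   array already read with RNifti.
#' @param parcels Parcel table with `x`, `y`, `z` in mm.
#' @param radius_mm Sphere radius (default 5 mm, the usual convention for
#'   264-region functional parcellations).
#' @return `T x R` matrix of mean time series, columns named by region id.
#' @export
extract_roi_timeseries <- function(nifti, parcels, radius_mm = 5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("extract_roi_timeseries() requires the RNifti package")
  }
  validate_parcel_table(parcels)
  img <- if (is.character(nifti)) RNifti::readNifti(nifti) else nifti
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D (x, y, z, t) volume")
  dims <- dim(arr)
  affine <- RNifti::xform(img)

  # world coordinates of all voxel centers (0-based voxel indices)
  grid <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                                k = 0:(dims[3] - 1)))
  world <- grid %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(grid), 3, byrow = TRUE)

  n_t <- dims[4]
  flat <- matrix(arr, ncol = n_t) # voxels x time, voxel order matches grid
  out <- matrix(NA_real_, n_t, nrow(parcels))
  colnames(out) <- as.character(parcels$region_id)
  r2 <- radius_mm^2
  for (p in seq_len(nrow(parcels))) {
    d2 <- (world[, 1] - parcels$x[p])^2 + (world[, 2] - parcels$y[p])^2 +
      (world[, 3] - parcels$z[p])^2
    inside <- d2 <= r2
    if (!any(inside)) {
      stop(sprintf(
        "no voxel within %g mm of region %s (%g, %g, %g): outside field of view",
        radius_mm, parcels$region_id[p], parcels$x[p], parcels$y[p],
        parcels$z[p]))
    }
    out[, p] <- colMeans(flat[inside, , drop = FALSE])
  }
  out
}
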