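#' Analysis grid
#'
#' A light container fixing the voxel grid every volume in an analysis must
#' live on: array shape, voxel size, and the binary brain mask. All pipeline
#' statistics are computed over mask voxels only, in R's native raster order
#' (first array index fastest-varying). Grid mismatches are always errors,
#' never silent resampling.
#'
#' @param mask logical or 0/1 3D array; the brain mask.
#' @param voxel_mm numeric length-3 voxel size in millimetres.
#' @return an object of class `analysis_grid`.
#' @export
analysis_grid <- function(mask, voxel_mm = c(3, 3, 3)) {
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  m <- as.array(mask)
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary {0,1}")
  m <- array(as.logical(m), dim = dim(mask))
  structure(list(shape = dim(m), voxel_mm = as.numeric(voxel_mm), mask = m),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat("analysis_grid:", paste(x$shape, collapse = " x "),
      "voxels;", sum(x$mask), "in mask\n")
  invisible(x)
}

stop_if_grid_mismatch <- function(vol, grid) {
  if (!identical(dim(vol), as.integer(grid$shape)) &&
      !identical(as.integer(dim(vol)), as.integer(grid$shape)))
    stop(sprintf("grid mismatch: volume is %s, analysis grid is %s",
                 paste(dim(vol), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

#' Vectorize a volume over a mask
#'
#' Extracts the in-mask voxels of a 3D volume as a vector in a fixed raster
#' order (first axis fastest), the order used for every map comparison in the
#' package.
#'
#' @param vol 3D array on the analysis grid.
#' @param mask logical 3D array of the same shape.
#' @return numeric vector of length `sum(mask)`.
#' @export
vectorize <- function(vol, mask) {
  if (!identical(dim(vol), dim(mask)))
    stop("grid mismatch between volume and mask")
  as.vector(vol[mask])
}

#' Restore a masked vector to a full volume
#'
#' Inverse of [vectorize()]: in-mask voxels receive the vector values in
#' raster order, out-of-mask voxels are 0.
#'
#' @param vec numeric vector with one value per mask voxel.
#' @param mask logical 3D array.
#' @param fill value outside the mask (default 0).
#' @return 3D array of `dim(mask)`.
#' @export
devectorize <- function(vec, mask, fill = 0) {
  if (length(vec) != sum(mask))
    stop(sprintf("length mismatch: vector has %d values, mask has %d voxels",
                 length(vec), sum(mask)))
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- vec
  vol
}

#' Read a NIfTI volume
#'
#' Thin wrapper over [RNifti::readNifti()] returning a plain array, with an
#' optional check against an open analysis grid.
#'
#' @param path NIfTI-1 file path.
#' @param grid optional `analysis_grid` the volume must match.
#' @return numeric array.
#' @export
read_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  if (!is.null(grid)) stop_if_grid_mismatch(vol, grid)
  vol
}

#' Write a NIfTI volume
#'
#' @param vol 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size stored in the header.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(vol, pixdim = voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

## Z-score a masked map vector; sd uses the n-1 denominator.
zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot Z-score a constant map")
  (x - mean(x)) / s
}

## Deterministic sub-seed derivation: keeps every derived seed a valid
## 32-bit integer whatever the user seed is.
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  s <- 0
  for (k in key) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}
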