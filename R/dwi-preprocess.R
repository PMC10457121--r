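#' Diffusion-weighted image blocks
#'
#' A `dwi_block` bundles one 4D acquisition (x, y, z, volume) with its
#' per-volume b-values, gradient directions and the (b, TE, TI, TR)
#' acquisition block it belongs to. Volumes and masks must share the same
#' voxel grid; no resampling or registration is performed here.
#'
#' @param volume 4D numeric array (or 3D for a single volume).
#' @param bvals Numeric vector, one b-value (s/mm^2) per volume.
#' @param bvecs 3-by-n matrix of gradient directions (FSL convention);
#'   unit norm (tolerance 1e-3) required wherever `b > 0`.
#' @param acquisition One-row protocol tibble (see [new_protocol()]).
#' @return A `dwi_block` object.
#' @export
dwi_block <- function(volume, bvals, bvecs, acquisition) {
  if (length(dim(volume)) == 3) dim(volume) <- c(dim(volume), 1)
  stopifnot(length(dim(volume)) == 4)
  nvol <- dim(volume)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  if (length(bvals) != nvol || ncol(bvecs) != nvol) {
    abort("bvals/bvecs must match the number of volumes.")
  }
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & abs(nrm - 1) > 1e-3)) {
    abort("Gradient directions must be unit norm where b > 0.")
  }
  validate_protocol(acquisition)
  structure(list(volume = volume, bvals = bvals, bvecs = bvecs,
                 acquisition = acquisition),
            class = "dwi_block")
}

#' @export
print.dwi_block <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<dwi_block> %dx%dx%d grid, %d volumes; TE = %g ms\n",
              d[1], d[2], d[3], d[4], x$acquisition$TE[1]))
  invisible(x)
}

#' Read FSL-style gradient tables and NIfTI volumes
#'
#' `read_bvals()`/`read_bvecs()` parse the plain-text FSL convention (one
#' whitespace-separated row of b-values; three rows of direction
#' components). `read_dwi_block()` assembles a [dwi_block()] from a NIfTI
#' file and its gradient tables.
#'
#' @param path File path.
#' @return Numeric vector, 3-by-n matrix, or a [dwi_block()].
#' @export
read_bvals <- function(path) {
  scan(path, quiet = TRUE)
}

#' @rdname read_bvals
#' @export
read_bvecs <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (nrow(m) != 3) abort("bvec files must have exactly three rows.")
  m
}

#' @rdname read_bvals
#' @param bval_path,bvec_path Paths to the gradient tables.
#' @param acquisition One-row protocol tibble for this block.
#' @export
read_dwi_block <- function(path, bval_path, bvec_path, acquisition) {
  vol <- as.array(RNifti::readNifti(path))
  dwi_block(vol, read_bvals(bval_path), read_bvecs(bvec_path), acquisition)
}

#' Restrict a block to one diffusion shell
#'
#' Keeps only volumes with `|b - target_b| <= tol`. At b = 6000 s/mm^2 the
#' in vivo signal is intra-axonal; b = 0 volumes are excluded by the
#' tolerance and are used for QC only, never in the spherical mean.
#'
#' @param block A [dwi_block()].
#' @param target_b Shell b-value, s/mm^2.
#' @param tol Shell tolerance, s/mm^2 (default 100).
#' @return A [dwi_block()] containing only matching volumes.
#' @export
extract_shell <- function(block, target_b, tol = 100) {
  stopifnot(inherits(block, "dwi_block"), tol >= 0)
  keep <- abs(block$bvals - target_b) <= tol
  if (!any(keep)) {
    abort(sprintf("No volumes within %g s/mm^2 of b = %g.", tol, target_b))
  }
  dwi_block(block$volume[, , , keep, drop = FALSE],
            block$bvals[keep], block$bvecs[, keep, drop = FALSE],
            block$acquisition)
}

#' Orientation-averaged spherical mean
#'
#' Per voxel, the arithmetic mean of the diffusion-weighted signal over
#' gradient directions. The spherical mean removes the dependence on the
#' fibre orientation distribution, so a single decay model can be fitted
#' per voxel.
#'
#' @param block A [dwi_block()] (typically one shell, see
#'   [extract_shell()]).
#' @return A 3D array of spherical means with attributes `acquisition`
#'   (the block's protocol row) and `n_directions`.
#' @export
spherical_mean <- function(block) {
  stopifnot(inherits(block, "dwi_block"))
  n <- dim(block$volume)[4]
  out <- apply(block$volume, c(1, 2, 3), mean)
  attr(out, "acquisition") <- block$acquisition
  attr(out, "n_directions") <- n
  out
}

#' Rician bias attenuation
#'
#' Magnitude MRI noise is Rician, which biases low-SNR signals upward.
#' The correction subtracts the noise power in quadrature:
#' `sqrt(max(value^2 - sigma^2, 0))`. It is the identity at `sigma = 0`
#' and never returns negative values. Sigma estimation (e.g. MP-PCA) is
#' delegated upstream; pass a scalar or a voxelwise map.
#'
#' @param value Intensities (any shape).
#' @param sigma Noise standard deviation, scalar or array conformable
#'   with `value`; nonnegative.
#' @return Corrected intensities, same shape as `value`.
#' @examples
#' rician_correct(5, 3)  # 4
#' @export
rician_correct <- function(value, sigma) {
  if (any(sigma < 0)) abort("sigma must be nonnegative.")
  out <- sqrt(pmax(value^2 - sigma^2, 0))
  attributes(out) <- attributes(value)
  out
}

#' Reduce a voxel map over an ROI mask
#'
#' Applies `mean` or `median` over the masked voxels of a 3D map,
#' dropping non-finite voxels (flagged fit failures) from the reduction.
#'
#' @param map 3D numeric array (e.g. a parameter or spherical-mean map).
#' @param mask 3D array on the same grid; nonzero/`TRUE` = included.
#' @param reducer `"mean"` or `"median"`.
#' @return A one-row tibble with `value`, `n_used` and `reducer`.
#' @export
roi_reduce <- function(map, mask, reducer = c("mean", "median")) {
  reducer <- match.arg(reducer)
  if (!identical(dim(map)[1:3], dim(mask)[1:3])) {
    abort("map and mask are on different voxel grids.")
  }
  vals <- map[mask != 0]
  if (length(vals) == 0) abort("Empty ROI mask.")
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("All masked voxels are non-finite.")
  f <- switch(reducer, mean = mean, median = median)
  tibble(value = f(vals), n_used = length(vals), reducer = reducer)
}

#' Read or write a 3D/4D volume as NIfTI-1
#'
#' Thin wrappers over RNifti used by the pipeline for maps and masks.
#'
#' @param path File path.
#' @return `read_volume()` returns a plain numeric array.
#' @export
read_volume <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' @rdname read_volume
#' @param vol Numeric array.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
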