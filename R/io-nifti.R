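## NIfTI-1 I/O via RNifti. Phantom slices are 2D; images are written as
## nr x nc x 1 (x nvol) volumes with the in-plane voxel size and a 0.1 mm
## slice thickness in the header.

as_nifti_image <- function(arr, voxel_size, slice_thickness = 0.1) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- c(voxel_size, voxel_size, slice_thickness, rep(1, max(nd - 3, 0)))
  RNifti::pixdim(img) <- pd[seq_len(nd)]
  img
}

#' Write / read a DWI stack as NIfTI plus FSL gradient tables
#'
#' `write_dwi_stack()` writes `<prefix>.nii.gz` (4D: rows x cols x 1 x
#' volumes) together with `<prefix>.bval` / `<prefix>.bvec`;
#' `read_dwi_stack()` reconstructs the `dwi_stack`. Signals and gradient
#' tables round-trip exactly.
#'
#' @param stack A `dwi_stack`.
#' @param prefix Path prefix (no extension).
#' @return `write_dwi_stack()`: the prefix, invisibly. `read_dwi_stack()`:
#'   a `dwi_stack`.
#' @export
write_dwi_stack <- function(stack, prefix) {
  gs <- stack$grid_shape
  arr <- array(stack$signals, dim = c(gs[1], gs[2], 1, ncol(stack$signals)))
  RNifti::writeNifti(as_nifti_image(arr, stack$voxel_size), paste0(prefix, ".nii.gz"),
                     datatype = "double")
  write_bvals_bvecs(stack$scheme, prefix)
  invisible(prefix)
}

#' @rdname write_dwi_stack
#' @param S0 Reference signal level recorded with the read stack (defaults
#'   to the median of the b0 volumes).
#' @export
read_dwi_stack <- function(prefix, S0 = NULL) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  scheme <- read_bvals_bvecs(prefix)
  d <- dim(img)
  nvol <- d[length(d)]
  gs <- c(d[1], d[2])
  signals <- matrix(as.vector(img), prod(gs), nvol)
  if (is.null(S0)) {
    S0 <- stats::median(signals[, scheme$bvals == 0, drop = FALSE])
  }
  structure(
    list(signals = signals, scheme = scheme, grid_shape = as.integer(gs),
         voxel_size = RNifti::pixdim(img)[1], S0 = S0, sigma = NA_real_,
         snr = NA_real_),
    class = "dwi_stack"
  )
}

#' Write a label map, orientation or scalar map as NIfTI
#'
#' @param map Matrix (or `roi_set`) to write.
#' @param path Output `.nii.gz` path.
#' @param voxel_size In-plane voxel size in mm (taken from an `roi_set`
#'   automatically).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size = NULL) {
  if (inherits(map, "roi_set")) {
    voxel_size <- map$voxel_size
    map <- map$labels
  }
  if (is.null(voxel_size)) abort("voxel_size required for plain matrices")
  arr <- array(map, dim = c(dim(map), 1))
  RNifti::writeNifti(as_nifti_image(arr, voxel_size), path)
  invisible(path)
}

#' Read a label map written by [write_map()] back into an `roi_set`
#'
#' @param path A `.nii.gz` label image using the package's region coding
#'   (0 background, 1 CA1, 2 CA3, 3 DG, 4 hilus, 5 srCA1).
#' @return An `roi_set` (without phantom centerline metadata).
#' @export
read_roiset <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  labels <- matrix(as.integer(round(as.vector(img))), d[1], d[2])
  structure(
    list(labels = labels, roi_names = ROI_LABELS,
         voxel_size = RNifti::pixdim(img)[1],
         grid_shape = as.integer(d[1:2])),
    class = "roi_set"
  )
}
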