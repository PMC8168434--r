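#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving voxel data and geometry. `read_volume`
#' returns a plain numeric array with the NIfTI header kept as an attribute;
#' `write_volume` accepts arrays of 3 or 4 dimensions.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param x Numeric array (3D or 4D).
#' @return `read_volume`: numeric array. `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname read_volume
#' @param pixdim Voxel dimensions written to the header (mm; defaults to the
#'   protocol's 5 mm slices with ~1.2 mm in-plane).
#' @export
write_volume <- function(x, path, pixdim = c(1.2, 1.2, 5)) {
  img <- RNifti::asNifti(x)
  nd <- length(dim(x))
  pd <- c(pixdim, rep(1, max(0, nd - 3)))[seq_len(nd)]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume and check it against an image grid
#'
#' @param path NIfTI file of 0/1 values.
#' @param image_dim Expected 3D grid dimensions (e.g. `dim(signal)[1:3]`).
#' @param image_path Name of the image the mask belongs to (for error text).
#' @return Logical 3D array.
#' @export
read_mask <- function(path, image_dim = NULL, image_path = "<image>") {
  arr <- read_volume(path)
  if (!is.null(image_dim) &&
      !identical(as.integer(dim(arr)), as.integer(image_dim))) {
    stop("read_mask: geometry mismatch between mask '", path,
         "' and image '", image_path, "'", call. = FALSE)
  }
  arr != 0
}

#' Read a cohort dynamic series
#'
#' @param path 4D NIfTI file.
#' @param params An [acq_params()]; the file's time-axis length must equal
#'   `params$n_timepoints`.
#' @return A [dynamic_series()].
#' @export
read_dynamic <- function(path, params) {
  arr <- read_volume(path)
  if (length(dim(arr)) != 4L) {
    stop("read_dynamic: '", path, "' is not a 4D volume", call. = FALSE)
  }
  if (dim(arr)[4] != params$n_timepoints) {
    stop("read_dynamic: '", path, "' has ", dim(arr)[4],
         " frames but the configuration expects ", params$n_timepoints,
         call. = FALSE)
  }
  dynamic_series(array(as.numeric(arr), dim(arr)), acq_times(params), params)
}
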