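#' Read a volume from a NIfTI-1 file
#'
#' The NIfTI qform/sform affine is decomposed into spacing (column norms),
#' direction (normalized columns) and origin (4th column), matching this
#' package's 0-based voxel-centre convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file '%s': %s", path,
                                 conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a 3D volume", path))
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  direction <- sweep(xf[1:3, 1:3], 2, spacing, "/")
  volume(arr, spacing = spacing, origin = xf[1:3, 4],
         direction = direction)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a [volume()] or [labelmap()].
#' @param path output path (`.nii` or `.nii.gz`); label maps are stored
#'   with an integer datatype.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  aff <- rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin),
               c(0, 0, 0, 1))
  data <- vol$data
  dt <- "double"
  if (is_labelmap(vol)) {
    data <- array(as.integer(data), dim(data))
    dt <- "int16"
  }
  attr(data, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(data, datatype = dt)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from a NIfTI-1 file
#'
#' @param path path to an integer-valued NIfTI file with codes in
#'   `{0,1,2,3}`.
#' @return A [labelmap()].
#' @export
read_labelmap <- function(path) {
  v <- read_volume(path)
  if (max(abs(v$data - round(v$data))) > 1e-6)
    stop(sprintf("'%s' does not contain integer labels", path))
  labelmap(round(v$data), v)
}
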