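#' Read a 4D NIfTI-1 volume series
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask optional path to a 3D mask image on the same grid.
#' @return A [volume_series()] with the TR taken from `pixdim[4]` and the
#'   affine from the stored xform.
#' @export
read_volume_series <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("dimensionality error: expected a 4D series, got ",
         length(dim(arr)), "D")
  tr <- RNifti::pixdim(img)[4]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  m <- NULL
  if (!is.null(mask)) {
    m <- as.array(RNifti::readNifti(mask)) != 0
    if (length(dim(m)) == 4L) m <- m[, , , 1]
  }
  volume_series(arr, tr = tr, affine = affine, mask = m)
}

#' Write a volume (3D) or volume series (4D) as NIfTI-1
#'
#' @param img a [volume_series()], or a plain 3D/4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr repetition time in seconds (ignored if `img` carries one).
#' @param affine 4x4 voxel-to-world transform (ignored if `img` carries one).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(img, path, tr = 1, affine = diag(4)) {
  if (inherits(img, "volume_series")) {
    arr <- img$data; tr <- img$tr; affine <- img$affine
  } else arr <- as.array(img)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- c(vox, tr)[seq_len(min(length(dim(arr)), 4L))]
  nim <- RNifti::asNifti(arr)
  nim <- RNifti::`pixdim<-`(nim, pd)
  xf <- structure(affine, code = 2L)
  nim <- RNifti::`sform<-`(nim, xf)
  nim <- RNifti::`qform<-`(nim, xf)
  RNifti::writeNifti(nim, path)
  invisible(path)
}
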