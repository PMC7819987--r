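#' Construct a CTVolume
#'
#' @param voxels 3-D numeric array of Hounsfield units.
#' @param spacing voxel edge lengths in mm; defaults to 0.5 x 0.5 x 5,
#'   i.e. thin in-plane sampling with 5 mm slices.
#' @param origin physical position (mm) of the grid corner.
#' @return a [CTVolume-class]
#' @examples
#' vol <- CTVolume(array(33, dim = c(32, 32, 8)))
#' voxelSpacing(vol)
#' @export
CTVolume <- function(voxels, spacing = c(0.5, 0.5, 5), origin = c(0, 0, 0)) {
  if (is.matrix(voxels)) stop("voxels must be a 3-D array")
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname voxelData
setMethod("voxelData", "CTVolume", function(object) object@voxels)

#' @rdname voxelSpacing
setMethod("voxelSpacing", "CTVolume", function(object) object@spacing)

#' @rdname voxelOrigin
setMethod("voxelOrigin", "CTVolume", function(object) object@origin)

#' @describeIn CTVolume grid dimensions
#' @param x a CTVolume
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], field of view %.0f x %.0f x %.0f mm\n",
              min(object@voxels), max(object@voxels),
              d[1] * object@spacing[1], d[2] * object@spacing[2],
              d[3] * object@spacing[3]))
})

#' Read a CTVolume from a NIfTI file
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return a [CTVolume-class]; spacing is taken from the NIfTI pixdim.
#' @export
readCTVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    sp <- c(0.5, 0.5, 5)
  CTVolume(arr, spacing = sp[1:3])
}

#' Write a CTVolume (or label volume) to NIfTI
#'
#' @param vol a [CTVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeCTVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@voxels, pixdim = vol@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an integer label map as NIfTI
#'
#' Used for segmentation component masks and phantom ground-truth masks.
#'
#' @param labels integer 3-D array (0 = background).
#' @param spacing voxel spacing in mm.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labels, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)),
                         pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
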