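#' Load a 4D diffusion-weighted series with its gradient scheme
#'
#' Reads a NIfTI volume and FSL bval/bvec files into a `dwi_volume` object.
#' Signals are stored as double regardless of the on-disk dtype (the fit
#' works on log-signals). Directions are interpreted in the image coordinate
#' frame of the supplied volume; no gradient re-orientation is performed
#' (preprocessed, axis-aligned input is assumed).
#'
#' @param image_path path to a 4D NIfTI (.nii/.nii.gz).
#' @param bval_path,bvec_path FSL gradient files.
#' @param mask_path optional NIfTI brain/ROI mask (0/1).
#' @inheritParams gradient_table
#' @return An object of class `dwi_volume`: list with `data` (4D double
#'   array), `affine` (4x4 voxel-to-world, 0-based voxel indices), `gradients`
#'   and optional `mask` (logical 3D array).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, mask_path = NULL,
                     b0_threshold = 50) {
  img <- RNifti::readNifti(image_path)
  data <- strip_nifti_attrs(img)
  if (length(dim(data)) != 4L)
    stop(sprintf("not a 4D series: %s has %d dimension(s)",
                 image_path, length(dim(data))))
  gtab <- read_gradients(bval_path, bvec_path, b0_threshold = b0_threshold)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- strip_nifti_attrs(RNifti::readNifti(mask_path))
    if (!identical(dim(m)[1:3], dim(data)[1:3]))
      stop("mask shape does not match image spatial shape")
    mask <- array(m != 0, dim = dim(m)[1:3])
  }
  dwi_volume(data, affine, gtab, mask)
}

#' Construct a `dwi_volume` in memory
#'
#' @param data 4D numeric array (x, y, z, measurement).
#' @param affine invertible 4x4 voxel-to-world matrix (mm; voxel indices are
#'   0-based as in the NIfTI convention).
#' @param gradients a [gradient_table()] whose length matches `dim(data)[4]`.
#' @param mask optional logical 3D array matching the spatial shape.
#' @return `dwi_volume` object.
#' @export
dwi_volume <- function(data, affine, gradients, mask = NULL) {
  stopifnot(inherits(gradients, "gradient_table"))
  data <- array(as.double(data), dim = dim(data))
  if (length(dim(data)) != 4L) stop("not a 4D series")
  if (dim(data)[4L] != length(gradients$bvals))
    stop(sprintf("4th dimension (%d) does not match gradient table length (%d)",
                 dim(data)[4L], length(gradients$bvals)))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask shape does not match image spatial shape")
    mask <- array(as.logical(mask), dim = dim(mask))
  }
  structure(list(data = data, affine = affine, gradients = gradients,
                 mask = mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume %d x %d x %d, %d measurements\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("voxel size (mm): %s\n",
              paste(format(sqrt(colSums(x$affine[1:3, 1:3]^2)), digits = 3),
                    collapse = " x ")))
  print(x$gradients)
  if (!is.null(x$mask)) cat(sprintf("mask: %d voxels\n", sum(x$mask)))
  invisible(x)
}

# drop RNifti header attributes, keeping a plain numeric array
strip_nifti_attrs <- function(img) {
  array(as.double(img), dim = dim(img))
}

# Build an RNifti image carrying data + sform affine (0-based voxel indices).
nifti_with_affine <- function(data, affine) {
  d <- dim(data)
  nd <- length(d)
  dimfield <- c(nd, d, rep(1L, 7L - nd))
  pix <- sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
  hdr <- RNifti::niftiHeader(list(
    dim = dimfield,
    pixdim = c(1, pix, rep(1, 4)),
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
    sform_code = 2L, qform_code = 0L))
  RNifti::asNifti(data, reference = hdr)
}

#' Write a DWI volume and its gradient files
#'
#' @param dwi a [dwi_volume()].
#' @param image_path,bval_path,bvec_path output paths.
#' @export
write_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  RNifti::writeNifti(nifti_with_affine(dwi$data, dwi$affine), image_path)
  write_gradients(dwi$gradients, bval_path, bvec_path)
  invisible(NULL)
}

#' Write a 3D scalar map as NIfTI
#'
#' NaN background is preserved. Data are written as float32; read-back agrees
#' with the input within single precision.
#'
#' @param volume 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path (.nii/.nii.gz).
#' @export
write_map <- function(volume, affine, path) {
  if (length(dim(volume)) != 3L) stop("map must be a 3D array")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  img <- nifti_with_affine(volume, affine)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(NULL)
}

#' Read a 3D scalar map
#'
#' @param path NIfTI path.
#' @return list with `data` (3D array) and `affine`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  data <- strip_nifti_attrs(img)
  if (length(dim(data)) != 3L)
    stop(sprintf("not a 3D map: %s", path))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(data = data, affine = affine)
}
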