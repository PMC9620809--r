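#' Volume containers
#'
#' Lightweight S3 containers used throughout the pipeline. A
#' `tensor_volume` stores one symmetric 3x3 diffusion tensor per voxel in
#' 6-component form (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz; units mm^2/s) as a 4-D
#' array, plus a 4x4 voxel-to-world affine (0-based voxel indices, world
#' coordinates in mm). A `scalar_map` stores one scalar per voxel (FA,
#' MD, masks, parcellation labels) with the same affine convention. All
#' inter-module exchange of positions is in world mm.
#'
#' @param D numeric array of dimension `c(nx, ny, nz, 6)`.
#' @param data numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices -> mm).
#' @return An object of class `tensor_volume` or `scalar_map`.
#' @name volumes
NULL

TENSOR_COMPONENTS <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stopf("affine must be a 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps) stopf("affine must be invertible")
  invisible(affine)
}

#' @rdname volumes
#' @export
tensor_volume <- function(D, affine = diag(4)) {
  if (length(dim(D)) != 4L || dim(D)[4] != 6L) {
    stopf("D must be an array of dimension c(nx, ny, nz, 6)")
  }
  check_affine(affine)
  structure(list(D = D, affine = affine, dims = dim(D)[1:3]),
            class = "tensor_volume")
}

#' @rdname volumes
#' @export
scalar_map <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stopf("data must be a 3-D array")
  check_affine(affine)
  structure(list(data = data, affine = affine, dims = dim(data)),
            class = "scalar_map")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %s voxels, voxel size %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(voxel_size(x$affine), 3), collapse = "x")))
  invisible(x)
}

#' @export
print.scalar_map <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("<scalar_map> %s voxels, range [%.4g, %.4g]\n",
              paste(x$dims, collapse = "x"), rng[1], rng[2]))
  invisible(x)
}

# Edge lengths of a voxel from the affine.
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# points: n x 3 world mm -> n x 3 continuous 0-based voxel coordinates.
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3L)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

# voxels: n x 3 0-based voxel coordinates -> n x 3 world mm.
voxel_to_world <- function(voxels, affine) {
  voxels <- matrix(voxels, ncol = 3L)
  t(affine[1:3, 1:3] %*% t(voxels) + affine[1:3, 4])
}

# Expand a 6-component tensor vector to the symmetric 3x3 matrix.
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3L, 3L)
}

mat_to_tensor6 <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

#' Read and write volumes as NIfTI
#'
#' Tensor volumes are stored as 4-D NIfTI with the 6 symmetric components
#' (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) along the 4th dimension; scalar maps,
#' masks and integer parcellations as 3-D NIfTI. The voxel-to-world affine
#' is written to the sform/qform.
#'
#' @param x a `tensor_volume` or `scalar_map`.
#' @param file path to a `.nii` / `.nii.gz` file.
#' @return `read_*` return the corresponding container; `write_*` return
#'   the file path invisibly.
#' @name nifti_io
NULL

write_affine_nifti <- function(arr, affine, file) {
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname nifti_io
#' @export
write_tensor_nifti <- function(x, file) {
  stopifnot(inherits(x, "tensor_volume"))
  write_affine_nifti(x$D, x$affine, file)
}

#' @rdname nifti_io
#' @export
read_tensor_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  tensor_volume(array(as.numeric(img), dim = dim(img)), unclass(aff))
}

#' @rdname nifti_io
#' @export
write_scalar_nifti <- function(x, file) {
  stopifnot(inherits(x, "scalar_map"))
  write_affine_nifti(x$data, x$affine, file)
}

#' @rdname nifti_io
#' @export
read_scalar_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  scalar_map(array(as.numeric(img), dim = dim(img)), unclass(aff))
}

#' Read and write FSL-style gradient tables
#'
#' `bvals` is a single whitespace-separated row of b-values (s/mm^2);
#' `bvecs` has three rows (x, y, z components), one column per volume.
#'
#' @param bvals,bvecs numeric vector / 3-row matrix.
#' @param path file path prefix or file.
#' @return `read_gradients` returns `list(bvals, bvecs)` with `bvecs` as an
#'   n x 3 matrix of unit vectors (zero rows allowed for b = 0).
#' @name gradient_io
NULL

#' @rdname gradient_io
#' @export
write_gradients <- function(bvals, bvecs, path) {
  writeLines(paste(format(bvals, scientific = FALSE), collapse = " "),
             paste0(path, ".bval"))
  m <- t(bvecs)  # 3 x n
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 10), collapse = " "))
  writeLines(lines, paste0(path, ".bvec"))
  invisible(path)
}

#' @rdname gradient_io
#' @export
read_gradients <- function(path) {
  bvals <- scan(paste0(path, ".bval"), quiet = TRUE)
  m <- as.matrix(read.table(paste0(path, ".bvec")))
  list(bvals = bvals, bvecs = t(m))
}
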