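#' Specify a synthetic fiber bundle
#'
#' A bundle is a tube of given radius around a polyline centerline. Voxels
#' inside the tube receive an anisotropic tensor whose principal
#' eigenvector follows the local centerline tangent; voxels outside receive
#' the isotropic background tensor. Spherical caps at the two centerline
#' endpoints are painted with integer parcellation labels so that
#' streamlines tracked along the bundle terminate inside labelled regions.
#'
#' @param centerline numeric matrix (>= 2 rows x 3 columns) of points in
#'   world mm.
#' @param radius tube radius in mm (> 0).
#' @param inside_eigenvalues three positive diffusivities (mm^2/s), sorted
#'   descending; the first is aligned with the centerline tangent.
#' @param background_eigenvalues three positive diffusivities for
#'   out-of-bundle voxels (isotropic if all equal).
#' @param endpoint_labels pair of distinct positive integers labelling the
#'   start/end regions.
#' @param endpoint_radius radius (mm) of the spherical label caps;
#'   defaults to `2 * radius`.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(centerline,
                        radius = 3,
                        inside_eigenvalues = c(1.7e-3, 0.2e-3, 0.2e-3),
                        background_eigenvalues = rep(0.7e-3, 3),
                        endpoint_labels = c(1L, 2L),
                        endpoint_radius = 2 * radius) {
  centerline <- matrix(as.numeric(centerline), ncol = 3L)
  if (nrow(centerline) < 2L) stopf("centerline needs at least 2 points")
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be > 0")
  for (ev in list(inside_eigenvalues, background_eigenvalues)) {
    if (length(ev) != 3L || any(ev <= 0)) stopf("eigenvalues must be 3 positive values")
    if (is.unsorted(rev(ev))) stopf("eigenvalues must be sorted descending")
  }
  endpoint_labels <- as.integer(endpoint_labels)
  if (length(endpoint_labels) != 2L || any(endpoint_labels <= 0L)) {
    stopf("endpoint_labels must be two positive integers")
  }
  structure(list(centerline = centerline, radius = radius,
                 inside_eigenvalues = as.numeric(inside_eigenvalues),
                 background_eigenvalues = as.numeric(background_eigenvalues),
                 endpoint_labels = endpoint_labels,
                 endpoint_radius = endpoint_radius),
            class = "bundle_spec")
}

# Distance from points (n x 3) to a polyline, plus tangent of the nearest
# segment. Vectorized over points, loop over segments.
polyline_distance <- function(points, centerline) {
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  tangent <- matrix(0, n, 3L)
  nseg <- nrow(centerline) - 1L
  for (s in seq_len(nseg)) {
    a <- centerline[s, ]
    b <- centerline[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(points, 2L, a)
    t_par <- if (len2 > 0) pmin(1, pmax(0, (ap %*% ab)[, 1] / len2)) else rep(0, n)
    proj <- outer(t_par, ab)
    d2 <- rowSums((ap - proj)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      tangent[upd, ] <- matrix(ab / sqrt(len2), nrow = sum(upd), ncol = 3L,
                               byrow = TRUE)
    }
  }
  list(dist = sqrt(best_d2), tangent = tangent)
}

# Symmetric tensor (6-component) with eigenvalues ev and principal axis t.
tensor_from_axis <- function(t_axis, ev) {
  t_axis <- t_axis / sqrt(sum(t_axis^2))
  ref <- if (abs(t_axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(t_axis[2] * ref[3] - t_axis[3] * ref[2],
         t_axis[3] * ref[1] - t_axis[1] * ref[3],
         t_axis[1] * ref[2] - t_axis[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t_axis[2] * u[3] - t_axis[3] * u[2],
         t_axis[3] * u[1] - t_axis[1] * u[3],
         t_axis[1] * u[2] - t_axis[2] * u[1])
  D <- ev[1] * tcrossprod(t_axis) + ev[2] * tcrossprod(u) + ev[3] * tcrossprod(v)
  mat_to_tensor6(D)
}

#' Build a tensor-field phantom with labelled bundle endpoints
#'
#' Generates a synthetic diffusion tensor volume containing one or more
#' coherent fiber bundles in an isotropic background, together with an
#' integer parcellation volume (spherical caps at bundle endpoints) and a
#' white-matter mask (voxels whose FA exceeds the background FA, i.e. the
#' in-bundle voxels).
#'
#' @param shape integer grid dimensions, e.g. `c(30, 30, 30)`.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param bundles list of [bundle_spec()] objects.
#' @return `list(tensors, parcellation, wm_mask)` — a [tensor_volume()] and
#'   two [scalar_map()]s (integer labels; 0/1 mask).
#' @examples
#' b <- bundle_spec(rbind(c(5, 15, 15), c(25, 15, 15)), radius = 3)
#' ph <- make_bundle_phantom(c(15, 15, 15), voxel_size = 2, bundles = list(b))
#' @export
make_bundle_phantom <- function(shape, voxel_size = 2, bundles) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive integers")
  if (!length(bundles)) stopf("at least one bundle required")
  affine <- diag(c(rep(voxel_size, 3), 1))
  extent_lo <- rep(-voxel_size / 2, 3)
  extent_hi <- (shape - 0.5) * voxel_size

  labs <- unlist(lapply(bundles, `[[`, "endpoint_labels"))
  if (anyDuplicated(labs)) stopf("endpoint labels must be unique across bundles")
  for (i in seq_along(bundles)) {
    cl <- bundles[[i]]$centerline
    if (any(t(cl) < extent_lo) || any(t(t(cl)) > matrix(extent_hi, nrow(cl), 3, byrow = TRUE))) {
      stopf("bundle %d centerline extends outside the grid", i)
    }
  }

  # world coordinates of all voxel centers
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  centers <- voxel_to_world(idx, affine)
  nvox <- nrow(centers)

  D <- array(0, c(shape, 6L))
  parc <- array(0L, shape)
  inbundle <- rep(FALSE, nvox)

  bg <- bundles[[1]]$background_eigenvalues
  bg6 <- c(bg[1], 0, 0, bg[2], 0, bg[3])
  for (c6 in 1:6) D[, , , c6] <- bg6[c6]

  lin <- function(rows) idx[rows, 1] + shape[1] * (idx[rows, 2] + shape[2] * idx[rows, 3]) + 1L

  for (b in bundles) {
    pd <- polyline_distance(centers, b$centerline)
    inside <- which(pd$dist <= b$radius & !inbundle)
    inbundle[inside] <- TRUE
    for (r in inside) {
      t6 <- tensor_from_axis(pd$tangent[r, ], b$inside_eigenvalues)
      flat <- lin(r)
      for (c6 in 1:6) D[flat + (c6 - 1L) * nvox] <- t6[c6]
    }
    ends <- list(b$centerline[1, ], b$centerline[nrow(b$centerline), ])
    for (e in 1:2) {
      d2 <- rowSums(sweep(centers, 2L, ends[[e]])^2)
      cap <- which(d2 <= b$endpoint_radius^2)
      parc[lin(cap)] <- b$endpoint_labels[e]
    }
  }

  mask <- array(0, shape)
  mask[lin(which(inbundle))] <- 1

  list(tensors = tensor_volume(D, affine),
       parcellation = scalar_map(parc + 0, affine),
       wm_mask = scalar_map(mask, affine))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Per voxel and gradient direction the noise-free signal is the
#' monoexponential tensor model `S = s0 * exp(-b * g' D g)`. Optional
#' Rician noise is applied to match magnitude MRI: two independent
#' Gaussian channels of standard deviation `noise_sd` are added in
#' quadrature, `S_noisy = sqrt((S + e1)^2 + e2^2)`.
#'
#' @param tensors a [tensor_volume()].
#' @param bvals numeric vector of b-values (s/mm^2); at least one must be 0.
#' @param bvecs n x 3 matrix of unit gradient directions (rows for b = 0
#'   volumes may be zero).
#' @param s0 non-diffusion-weighted signal level.
#' @param noise_sd Rician channel standard deviation (0 = noise free).
#' @param seed optional RNG seed for the noise draw.
#' @return list with 4-D signal array `signal` (`c(dims, n_volumes)`),
#'   `bvals`, `bvecs`, and the affine.
#' @export
simulate_dwi <- function(tensors, bvals, bvecs, s0 = 1000, noise_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(tensors, "tensor_volume"))
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  bvals <- as.numeric(bvals)
  if (nrow(bvecs) != length(bvals)) stopf("bvals/bvecs length mismatch")
  if (any(bvals < 0)) stopf("bvals must be nonnegative")
  if (!any(bvals == 0)) stopf("at least one b=0 volume required")
  nb <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nb - 1) > 1e-6
  if (any(bad)) stopf("bvec rows for b > 0 must be unit vectors (row %d)", which(bad)[1])

  dims <- tensors$dims
  nvox <- prod(dims)
  Dm <- matrix(tensors$D, nvox, 6L)  # per-voxel components
  # quadratic form g'Dg per direction: coefficients on the 6 components
  Q <- cbind(bvecs[, 1]^2, 2 * bvecs[, 1] * bvecs[, 2], 2 * bvecs[, 1] * bvecs[, 3],
             bvecs[, 2]^2, 2 * bvecs[, 2] * bvecs[, 3], bvecs[, 3]^2)
  expo <- Dm %*% t(Q * bvals)     # nvox x ndir, b * g'Dg
  S <- s0 * exp(-expo)
  if (noise_sd > 0) {
    S <- with_seed(seed, {
      e1 <- matrix(rnorm(length(S), sd = noise_sd), nrow(S))
      e2 <- matrix(rnorm(length(S), sd = noise_sd), nrow(S))
      sqrt((S + e1)^2 + e2^2)
    })
  }
  list(signal = array(S, c(dims, length(bvals))), bvals = bvals,
       bvecs = bvecs, affine = tensors$affine)
}

#' Evenly spaced gradient scheme
#'
#' Generates `n` approximately uniform unit directions on the sphere via a
#' Fibonacci spiral, preceded by `n_b0` b = 0 volumes; the default matches
#' a 32-direction, b = 1000 s/mm^2 acquisition.
#'
#' @param n number of diffusion-weighted directions.
#' @param bval b-value for the weighted volumes (s/mm^2).
#' @param n_b0 number of b = 0 volumes.
#' @return list `bvals`, `bvecs`.
#' @export
gradient_scheme <- function(n = 32, bval = 1000, n_b0 = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  list(bvals = c(rep(0, n_b0), rep(bval, n)),
       bvecs = rbind(matrix(0, n_b0, 3), dirs))
}
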