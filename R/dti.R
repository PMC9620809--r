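# Tensor model fitting and scalar-map / histogram metrics.

# Vectorized eigenvalues of symmetric 3x3 tensors given as an n x 6 matrix
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). Returns n x 3, descending. Uses the
# trigonometric closed form for symmetric 3x3 matrices.
tensor_eigenvalues <- function(Dm) {
  Dm <- matrix(Dm, ncol = 6L)
  xx <- Dm[, 1]; xy <- Dm[, 2]; xz <- Dm[, 3]
  yy <- Dm[, 4]; yz <- Dm[, 5]; zz <- Dm[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(iso, 1, p)  # avoid 0/0; isotropic handled below
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; bxz <- xz / ps; byz <- yz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  out
}

# FA from an n x 3 eigenvalue matrix (no clamping applied here).
fa_from_eigenvalues <- function(ev) {
  ev <- matrix(ev, ncol = 3L)
  md <- rowMeans(ev)
  num <- rowSums((ev - md)^2)
  den <- rowSums(ev^2)
  fa <- sqrt(1.5 * num / ifelse(den > 0, den, 1))
  fa[den <= 0] <- 0
  pmin(fa, 1)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per masked voxel, solves the monoexponential model
#' `log S_i = log S0 - b_i g_i' D g_i` for the 6 unique tensor components
#' and `log S0` by ordinary least squares on the log-signals. Voxels with
#' any non-positive signal inside the mask are flagged invalid (tensor set
#' to `NA`) and excluded from downstream maps.
#'
#' @param dwi list with `signal` (4-D array), as from [simulate_dwi()], or
#'   a 4-D array.
#' @param bvals,bvecs gradient table (see [simulate_dwi()]).
#' @param mask optional [scalar_map()] or 3-D array; nonzero voxels are fit.
#' @param affine affine to attach when `dwi` is a bare array.
#' @return A [tensor_volume()]; attribute `invalid` holds the count of
#'   flagged voxels.
#' @export
tensor_fit <- function(dwi, bvals = NULL, bvecs = NULL, mask = NULL,
                       affine = NULL) {
  if (is.list(dwi)) {
    signal <- dwi$signal
    if (is.null(bvals)) bvals <- dwi$bvals
    if (is.null(bvecs)) bvecs <- dwi$bvecs
    if (is.null(affine)) affine <- dwi$affine
  } else {
    signal <- dwi
  }
  if (is.null(affine)) affine <- diag(4)
  dims <- dim(signal)[1:3]
  ndir <- dim(signal)[4]
  bvecs <- matrix(bvecs, ncol = 3L)
  if (length(bvals) != ndir) stopf("bvals length does not match signal volumes")
  if (sum(bvals > 0) < 6L || !any(bvals == 0)) {
    stopf("need >= 6 diffusion-weighted directions and >= 1 b=0 volume")
  }
  # design: log S = X beta, beta = (log S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
  X <- cbind(1, -bvals * cbind(bvecs[, 1]^2, 2 * bvecs[, 1] * bvecs[, 2],
                               2 * bvecs[, 1] * bvecs[, 3], bvecs[, 2]^2,
                               2 * bvecs[, 2] * bvecs[, 3], bvecs[, 3]^2))
  pinv <- solve(crossprod(X), t(X))

  nvox <- prod(dims)
  S <- matrix(signal, nvox, ndir)
  in_mask <- if (is.null(mask)) {
    rep(TRUE, nvox)
  } else {
    m <- if (inherits(mask, "scalar_map")) mask$data else mask
    as.vector(m) != 0
  }
  valid <- in_mask & rowSums(S <= 0) == 0L

  D <- matrix(NA_real_, nvox, 6L)
  if (any(valid)) {
    beta <- log(S[valid, , drop = FALSE]) %*% t(pinv)
    D[valid, ] <- beta[, 2:7, drop = FALSE]
  }
  D[!in_mask, ] <- 0
  out <- tensor_volume(array(D, c(dims, 6L)), affine)
  attr(out, "invalid") <- sum(in_mask & !valid)
  out
}

#' FA and MD maps from a tensor volume
#'
#' `fa_map()` computes fractional anisotropy per voxel,
#' `FA = sqrt(3/2) * sqrt(sum((lambda - MD)^2) / sum(lambda^2))`, with
#' negative eigenvalues clamped to 0 first (the number of affected voxels
#' is recorded in attribute `n_clamped`); an all-zero tensor yields
#' FA = 0. `md_map()` computes mean diffusivity, trace/3 (mm^2/s).
#'
#' @param t a [tensor_volume()].
#' @return A [scalar_map()].
#' @export
fa_map <- function(t) {
  stopifnot(inherits(t, "tensor_volume"))
  Dm <- matrix(t$D, prod(t$dims), 6L)
  ev <- tensor_eigenvalues(Dm)
  n_clamped <- sum(rowSums(ev < 0, na.rm = TRUE) > 0, na.rm = TRUE)
  ev <- pmax(ev, 0)
  fa <- fa_from_eigenvalues(ev)
  out <- scalar_map(array(fa, t$dims), t$affine)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' @rdname fa_map
#' @export
md_map <- function(t) {
  stopifnot(inherits(t, "tensor_volume"))
  Dm <- matrix(t$D, prod(t$dims), 6L)
  md <- (Dm[, 1] + Dm[, 4] + Dm[, 6]) / 3
  scalar_map(array(md, t$dims), t$affine)
}

#' Normalized histogram summary of a scalar map
#'
#' Bins masked voxel values into `n_bins` equal-width bins over
#' `[0, range_max]` (the convention used for white-matter FA and MD
#' histograms: 1,000 bins, FA range 0-1, MD range 0-4e-3 mm^2/s).
#' Bin proportions sum to 1; out-of-range values are clipped into the
#' terminal bins and counted. The peak is the highest bin (ties broken by
#' the lowest bin index); its location is reported at the bin center. The
#' median is the empirical median of the raw masked values, not of the
#' binned data.
#'
#' @param map a [scalar_map()] or numeric array/vector.
#' @param mask optional mask ([scalar_map()] or array); nonzero = included.
#' @param range_max upper edge of the histogram range.
#' @param n_bins number of bins.
#' @return An object of class `histogram_summary`: list with `peak_height`,
#'   `peak_location`, `median`, `n_bins`, `bin_width`, `proportions`,
#'   `n_clipped`.
#' @examples
#' h <- histogram_summary(rep(0.35, 100), range_max = 1, n_bins = 1000)
#' h$peak_location  # 0.3505: center of the bin [0.350, 0.351)
#' @export
histogram_summary <- function(map, mask = NULL, range_max = 1, n_bins = 1000L) {
  vals <- if (inherits(map, "scalar_map")) as.vector(map$data) else as.vector(map)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "scalar_map")) mask$data else mask
    vals <- vals[as.vector(m) != 0]
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("empty mask: no voxels to histogram")
  n_bins <- as.integer(n_bins)
  bw <- range_max / n_bins
  # right-open bins [k*bw, (k+1)*bw); the 1e-9-bin nudge keeps values that
  # sit on a bin edge (up to representation error) in the upper bin
  idx <- floor(vals / bw + 1e-9)
  n_clipped <- sum(idx < 0) + sum(idx >= n_bins & vals != range_max)
  idx <- pmin(pmax(idx, 0), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  prop <- counts / length(vals)
  peak_bin <- which.max(prop)           # ties -> lowest bin index
  structure(list(peak_height = prop[peak_bin],
                 peak_location = (peak_bin - 0.5) * bw,
                 median = median(vals),
                 n_bins = n_bins, bin_width = bw,
                 proportions = prop, n_clipped = n_clipped),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("<histogram_summary> peak %.4g at %.4g, median %.4g (%d bins)\n",
              x$peak_height, x$peak_location, x$median, x$n_bins))
  invisible(x)
}

#' WMH lesion-load score
#'
#' Percentage of white-matter-hyperintensity lesion volume relative to
#' whole-brain volume.
#'
#' @param wmh_volume_ml lesion volume (mL), `0 <= wmh <= brain`.
#' @param brain_volume_ml whole-brain volume (mL), `> 0`.
#' @return Lesion load in percent.
#' @examples
#' wmh_lesion_load(30, 1200)  # 2.5
#' @export
wmh_lesion_load <- function(wmh_volume_ml, brain_volume_ml) {
  if (any(brain_volume_ml <= 0)) stopf("brain volume must be > 0")
  if (any(wmh_volume_ml < 0) || any(wmh_volume_ml > brain_volume_ml)) {
    stopf("wmh volume must satisfy 0 <= wmh <= brain volume")
  }
  100 * wmh_volume_ml / brain_volume_ml
}
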