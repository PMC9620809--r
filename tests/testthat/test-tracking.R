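# Geometry fixtures: uniform anisotropic slabs (helper slab_phantom) and a
# sharp 60-degree bend field built at fine voxel size so the direction
# discontinuity stays below the integration step.

bend_field <- function(shape, voxel_size, x_bend, angle_deg) {
  affine <- diag(c(rep(voxel_size, 3), 1))
  ev <- c(1.7e-3, 0.2e-3, 0.2e-3)
  a <- angle_deg * pi / 180
  mk <- function(ax) {
    u <- c(-ax[2], ax[1], 0)
    v <- c(0, 0, 1)
    D <- ev[1] * tcrossprod(ax) + ev[2] * tcrossprod(u) + ev[3] * tcrossprod(v)
    c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  }
  t1 <- mk(c(1, 0, 0))
  t2 <- mk(c(cos(a), sin(a), 0))
  D <- array(0, c(shape, 6))
  x <- (seq_len(shape[1]) - 1) * voxel_size
  for (c6 in 1:6) {
    D[x < x_bend, , , c6] <- t1[c6]
    D[x >= x_bend, , , c6] <- t2[c6]
  }
  tensor_volume(D, affine)
}

test_that("tracking parameter validation enforces the documented ranges", {
  expect_error(tracking_params(step_size = 0), "step_size")
  expect_error(tracking_params(max_angle = 95), "max_angle")
  expect_error(tracking_params(min_length = 300), "min_length")
  expect_error(tracking_params(fa_cutoff = 1.5), "fa_cutoff")
  p <- tracking_params()
  expect_equal(p$step_size, 0.5)
  expect_equal(p$max_angle, 45)
  expect_equal(c(p$min_length, p$max_length), c(20, 250))
  expect_equal(p$fa_cutoff, 0.15)
  expect_equal(p$seeds_per_voxel_axis, 4L)
})

test_that("direction field returns the sign-aligned principal eigenvector", {
  ph <- slab_phantom(c(10, 5, 5), voxel_size = 2, x0 = 0, x1 = 18)
  d1 <- direction_field(ph, c(9, 4, 4), incoming = c(1, 0, 0))
  expect_equal(d1$direction, c(1, 0, 0), tolerance = 1e-12)
  d2 <- direction_field(ph, c(9, 4, 4), incoming = c(-1, 0, 0))
  expect_equal(d2$direction, c(-1, 0, 0), tolerance = 1e-12)
  expect_null(direction_field(ph, c(100, 4, 4)))
})

test_that("tensor interpolation midway between voxels averages the tensors", {
  D <- array(0, c(2, 1, 1, 6))
  set.seed(3)
  for (i in 1:2) {
    A <- matrix(rnorm(9, sd = 5e-4), 3)
    S <- crossprod(A) + diag(3) * 1e-3
    D[i, 1, 1, ] <- c(S[1, 1], S[1, 2], S[1, 3], S[2, 2], S[2, 3], S[3, 3])
  }
  tv <- tensor_volume(D, diag(c(2, 2, 2, 1)))
  # midpoint of voxel centers 0 and 2 mm along x
  res <- direction_field(tv, c(1, 0, 0), incoming = c(1, 1, 1))
  Dmid <- (matrix(D[1, 1, 1, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3) +
             matrix(D[2, 1, 1, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3)) / 2
  e <- eigen(Dmid, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v * c(1, 1, 1)) < 0) v <- -v
  expect_equal(res$direction, v, tolerance = 1e-10)
})

test_that("streamlines in a straight slab are straight and span the FA extent", {
  vs <- 2
  ph <- slab_phantom(c(40, 9, 9), voxel_size = vs, x0 = 18, x1 = 58)
  mask <- array(0, c(40, 9, 9))
  mask[10:29, 4:6, 4:6] <- 1   # seeds inside the slab
  tg <- whole_brain_tractography(ph, mask, tracking_params(seeds_per_voxel_axis = 2))
  expect_equal(length(tg), tg$n_seeds)   # every in-slab seed accepted

  # RK4 on a constant field is exact: zero lateral deviation
  dev <- vapply(tg$streamlines, function(m) {
    max(abs(m[, 2] - m[1, 2])) + max(abs(m[, 3] - m[1, 3]))
  }, numeric(1))
  expect_lt(max(dev), 1e-6)

  # length window from the FA-crossing oracle: the interpolated FA falls
  # below the cutoff a fraction u into the boundary voxel gap
  u <- fa_crossing_fraction()
  extent <- (58 - 18) + 2 * u * vs
  step <- 0.5
  expect_true(all(tg$length_mm <= extent + 1e-9))
  expect_true(all(tg$length_mm >= extent - 2 * step - 1e-9))
})

test_that("tracking is bit-identical across runs and under axis sign flips", {
  ph <- slab_phantom(c(30, 7, 7), voxel_size = 2, x0 = 10, x1 = 48)
  mask <- array(0, c(30, 7, 7))
  mask[8:22, 3:5, 3:5] <- 1
  p <- tracking_params(seeds_per_voxel_axis = 2)
  t1 <- whole_brain_tractography(ph, mask, p)
  t2 <- whole_brain_tractography(ph, mask, p)
  expect_identical(t1$streamlines, t2$streamlines)
  # the tensor encodes an axial (sign-free) direction: building the same
  # slab with the -x axis yields the identical tensor field and tractogram
  ph_neg <- slab_phantom(c(30, 7, 7), voxel_size = 2, x0 = 10, x1 = 48,
                         axis = c(-1, 0, 0))
  expect_equal(ph_neg$D, ph$D, tolerance = 1e-15)
  t3 <- whole_brain_tractography(ph_neg, mask, p)
  expect_equal(t3$streamlines, t1$streamlines, tolerance = 1e-12)
})

test_that("a slab shorter than the minimum track length yields no streamlines", {
  ph <- slab_phantom(c(30, 7, 7), voxel_size = 2, x0 = 20, x1 = 34)  # ~15 mm
  mask <- array(0, c(30, 7, 7))
  mask[11:17, 3:5, 3:5] <- 1
  tg <- whole_brain_tractography(ph, mask, tracking_params(seeds_per_voxel_axis = 2))
  expect_equal(length(tg), 0L)
  expect_gt(tg$rejections[["too_short"]], 0)
  r <- track_from_seed(ph, c(27, 6, 6))
  expect_s3_class(r, "rejected_seed")
  expect_equal(r$reason, "too_short")
})

test_that("a 60-degree bend terminates every track at the bend", {
  vs <- 0.05
  shape <- c(round(60 / vs), round(6 / vs), 3)
  ph <- bend_field(shape, vs, x_bend = 30, angle_deg = 60)
  mask <- array(0, dim = shape)
  mask[round(20.1 / vs) + 1, seq(round(2 / vs), round(4 / vs), by = 10), 2] <- 1
  tg <- whole_brain_tractography(ph, mask, tracking_params(seeds_per_voxel_axis = 1))
  expect_gt(length(tg), 0)
  expect_true(all(tg$term_forward == "angle_exceeded"))
  maxx <- vapply(tg$streamlines, function(m) max(m[, 1]), numeric(1))
  expect_true(all(maxx <= 30 + 0.5 + vs))
})

test_that("seed grids and degenerate fields behave as specified", {
  ph <- slab_phantom(c(9, 9, 9), voxel_size = 2, x0 = 0, x1 = 16)
  mask <- array(0, c(9, 9, 9))
  mask[5, 5, 5] <- 1
  tg <- whole_brain_tractography(ph, mask, tracking_params())  # grid 4 -> 64
  expect_equal(tg$n_seeds, 64L)

  iso <- slab_phantom(c(9, 9, 9), voxel_size = 2, x0 = 100, x1 = 120)  # all bg
  tg0 <- whole_brain_tractography(iso, array(1, c(9, 9, 9)),
                                  tracking_params(seeds_per_voxel_axis = 1))
  expect_equal(length(tg0), 0L)
})

test_that("accepted streamlines respect the length window and angle bound", {
  theta <- seq(0, pi, length.out = 41)
  cl <- cbind(20 + 12 * cos(theta), 8 + 12 * sin(theta), 8)
  b <- bundle_spec(cl, radius = 2.5, endpoint_radius = 4)
  ph <- make_bundle_phantom(c(20, 14, 8), voxel_size = 2, bundles = list(b))
  p <- tracking_params(seeds_per_voxel_axis = 2)
  tg <- whole_brain_tractography(ph$tensors, ph$wm_mask, p)
  expect_gt(length(tg), 100)
  expect_true(all(tg$length_mm >= p$min_length & tg$length_mm <= p$max_length))
  worst <- 0
  for (m in tg$streamlines) {
    seg <- diff(m)
    seg <- seg / sqrt(rowSums(seg^2))
    cosang <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
    worst <- max(worst, max(acos(pmin(1, pmax(-1, cosang))) * 180 / pi))
  }
  expect_lte(worst, p$max_angle + 1e-6)
})

test_that("TCK output round-trips its float payload", {
  ph <- slab_phantom(c(30, 7, 7), voxel_size = 2, x0 = 10, x1 = 48)
  mask <- array(0, c(30, 7, 7))
  mask[15, 4, 4] <- 1
  tg <- whole_brain_tractography(ph, mask, tracking_params(seeds_per_voxel_axis = 1))
  f <- tempfile(fileext = ".tck")
  write_tck(tg, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  hdr_end <- grepRaw("END\n", raw, fixed = TRUE) + 3L
  txt <- rawToChar(raw[seq_len(hdr_end)])
  expect_match(txt, "mrtrix tracks")
  off <- as.integer(sub(".*file: \\. (\\d+).*", "\\1", txt))
  floats <- readBin(raw[(off + 1):length(raw)], "numeric", size = 4,
                    n = (length(raw) - off) / 4, endian = "little")
  pts <- matrix(floats[seq_len(3 * nrow(tg$streamlines[[1]]))], ncol = 3,
                byrow = TRUE)
  expect_equal(pts, tg$streamlines[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  sidecar <- read.table(paste0(f, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(sidecar), length(tg))
  expect_equal(sidecar$length_mm, tg$length_mm)
})
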