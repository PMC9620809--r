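# Hand-built parcellation spanning x in [0, 58] at 2 mm voxels: label 3
# around x = 4, label 7 around x = 52.
toy_parcellation <- function() {
  parc <- array(0, c(30, 5, 5))
  parc[2:4, , ] <- 3
  parc[26:28, , ] <- 7
  scalar_map(parc, diag(c(2, 2, 2, 1)))
}

straight_track <- function(x0, x1, y = 4, z = 4, step = 1) {
  xs <- seq(x0, x1, by = step)
  cbind(xs, y, z)
}

test_that("endpoint labels come from the containing voxel, 0 outside/unlabeled", {
  parc <- toy_parcellation()
  expect_equal(endpoint_labels(straight_track(4, 52), parc), c(3L, 7L))
  expect_equal(endpoint_labels(straight_track(4, 30), parc), c(3L, 0L))
  expect_equal(endpoint_labels(straight_track(-40, 52), parc), c(0L, 7L))
  expect_equal(endpoint_labels(straight_track(3, 6), parc), c(3L, 3L))
})

test_that("edge weights are the hand-summed inverse streamline lengths", {
  parc <- toy_parcellation()
  # three A-B tracks with polyline lengths 20, 25 and 50 mm
  trk <- list(rbind(c(6, 4, 4), c(26, 4, 4)),
              rbind(c(6, 4, 4), c(18, 4, 4), c(31, 4, 4)),
              rbind(c(4, 4, 4), c(54, 4, 4)))
  parc2 <- scalar_map(array(0, c(30, 5, 5)), diag(c(2, 2, 2, 1)))
  parc2$data[2:4, , ] <- 1         # x in [2, 6]
  parc2$data[13:28, , ] <- 2       # x in [24, 54]
  cm <- build_connectome(trk, parc2)
  expect_equal(cm$weights["1", "2"], 1 / 20 + 1 / 25 + 1 / 50)
  expect_equal(cm$weights["1", "2"], 0.11)
  expect_identical(cm$weights, t(cm$weights))
  expect_equal(diag(cm$weights), c("1" = 0, "2" = 0))
})

test_that("total connectome weight conserves the streamline-level sum", {
  theta <- seq(0, pi, length.out = 41)
  cl <- cbind(20 + 12 * cos(theta), 8 + 12 * sin(theta), 8)
  b <- bundle_spec(cl, radius = 2.5, endpoint_radius = 4)
  ph <- make_bundle_phantom(c(20, 14, 8), voxel_size = 2, bundles = list(b))
  tg <- whole_brain_tractography(ph$tensors, ph$wm_mask,
                                 tracking_params(seeds_per_voxel_axis = 2))
  cm <- build_connectome(tg, ph$parcellation)
  # independent per-streamline accumulation oracle
  total <- 0
  n_conn <- 0L
  for (i in seq_along(tg$streamlines)) {
    lab <- endpoint_labels(tg$streamlines[[i]], ph$parcellation)
    if (all(lab > 0) && lab[1] != lab[2]) {
      total <- total + 1 / tg$length_mm[i]
      n_conn <- n_conn + 1L
    }
  }
  expect_gt(n_conn, 0)
  expect_equal(sum(cm$weights) / 2, total)
  expect_equal(cm$n_connecting, n_conn)
})

test_that("self-connections are removed: a loop phantom gives a zero matrix", {
  theta <- seq(0, pi, length.out = 41)
  cl <- cbind(20 + 12 * cos(theta), 8 + 12 * sin(theta), 8)
  b <- bundle_spec(cl, radius = 2.5, endpoint_radius = 4)
  ph <- make_bundle_phantom(c(20, 14, 8), voxel_size = 2, bundles = list(b))
  tg <- whole_brain_tractography(ph$tensors, ph$wm_mask,
                                 tracking_params(seeds_per_voxel_axis = 2))
  loop_parc <- ph$parcellation
  loop_parc$data[loop_parc$data == 2] <- 1   # both caps share one label
  cm <- build_connectome(tg, loop_parc, labels = c(1L, 5L))
  expect_gt(cm$n_self, 0)
  expect_true(all(cm$weights == 0))
})

test_that("relabeling nodes permutes the matrix consistently", {
  b1 <- bundle_spec(rbind(c(6, 8, 8), c(42, 8, 8)), radius = 2,
                    endpoint_labels = c(1L, 2L))
  b2 <- bundle_spec(rbind(c(6, 24, 8), c(42, 24, 8)), radius = 2,
                    endpoint_labels = c(3L, 4L))
  ph <- make_bundle_phantom(c(25, 17, 9), voxel_size = 2,
                            bundles = list(b1, b2))
  tg <- whole_brain_tractography(ph$tensors, ph$wm_mask,
                                 tracking_params(seeds_per_voxel_axis = 2))
  cm <- build_connectome(tg, ph$parcellation)
  # relabel 1->4, 2->3, 3->2, 4->1
  relab <- ph$parcellation
  relab$data <- array(c(0, 4, 3, 2, 1)[ph$parcellation$data + 1],
                      dim = dim(ph$parcellation$data))
  cm2 <- build_connectome(tg, relab)
  perm <- c(4, 3, 2, 1)
  expect_equal(unname(cm2$weights), unname(cm$weights[perm, perm]))

  # dropping every streamline of one edge zeroes exactly that entry
  keep <- vapply(tg$streamlines, function(s) {
    !all(endpoint_labels(s, ph$parcellation) %in% c(1L, 2L))
  }, logical(1))
  cm3 <- build_connectome(tg$streamlines[keep], ph$parcellation,
                          labels = 1:4)
  expect_equal(cm3$weights["1", "2"], 0)
  expect_equal(cm3$weights["3", "4"], cm$weights["3", "4"])
})

test_that("empty tractograms warn and produce an all-zero matrix", {
  parc <- toy_parcellation()
  expect_warning(cm <- build_connectome(list(), parc), "empty")
  expect_true(all(cm$weights == 0))
  expect_equal(cm$labels, c(3L, 7L))
})

test_that("connectome TSV and edge-list round trips preserve weights", {
  W <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  W[1, 2] <- W[2, 1] <- 0.25
  W[2, 3] <- W[3, 2] <- 0.1
  f <- tempfile(fileext = ".tsv")
  write_connectome_tsv(W, f)
  back <- read_connectome_tsv(f)
  expect_equal(unname(back$weights), unname(W))
  fe <- tempfile(fileext = ".tsv")
  write_edge_list_tsv(W, fe)
  el <- read.table(fe, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 2L)
  expect_equal(sort(el$weight), c(0.1, 0.25))
})
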