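#' Parcellation labels at streamline endpoints
#'
#' Returns the integer parcellation label of the voxel containing each
#' terminal point of a streamline (nearest-voxel assignment, no dilation).
#' Endpoints in unlabeled tissue or outside the volume map to 0.
#'
#' @param s streamline: numeric matrix of world-mm points (>= 2 rows).
#' @param parc parcellation [scalar_map()] of integer labels (0 =
#'   unlabeled).
#' @return Integer pair `c(label_start, label_end)`.
#' @export
endpoint_labels <- function(s, parc) {
  stopifnot(inherits(parc, "scalar_map"))
  ends <- rbind(s[1, ], s[nrow(s), ])
  vox <- round(world_to_voxel(ends, parc$affine))
  dims <- parc$dims
  out <- integer(2L)
  for (i in 1:2) {
    v <- vox[i, ]
    if (any(v < 0) || any(v > dims - 1L)) {
      out[i] <- 0L
    } else {
      out[i] <- as.integer(parc$data[v[1] + 1L, v[2] + 1L, v[3] + 1L])
    }
  }
  out
}

#' Build the inverse-length-weighted structural connectome
#'
#' Each streamline whose two endpoints terminate in two distinct labelled
#' regions A and B contributes `1 / length(s)` (mm^-1) to edge (A, B);
#' streamlines terminating in their region of origin (A = A) or with an
#' unlabeled endpoint contribute nothing. The inverse-length scaling
#' compensates for the super-resolution seeding, under which longer tracks
#' accumulate proportionally more seed points. The result is a symmetric
#' nonnegative matrix with an exactly zero diagonal.
#'
#' @param trk a `tractogram` (or plain list of point matrices).
#' @param parc parcellation [scalar_map()]; region set taken from its
#'   nonzero labels unless `labels` is given.
#' @param labels optional integer vector of region labels fixing node
#'   order.
#' @return An object of class `connectivity_matrix`: the weight matrix
#'   with region labels as dimnames, plus per-streamline assignment
#'   bookkeeping (`n_connecting`, `n_self`, `n_unlabeled`).
#' @export
build_connectome <- function(trk, parc, labels = NULL) {
  streamlines <- if (inherits(trk, "tractogram")) trk$streamlines else trk
  lengths_mm <- if (inherits(trk, "tractogram")) {
    trk$length_mm
  } else {
    vapply(streamlines, function(m) {
      sum(sqrt(rowSums((m[-1, , drop = FALSE] -
                          m[-nrow(m), , drop = FALSE])^2)))
    }, numeric(1))
  }
  if (is.null(labels)) {
    labels <- sort(unique(as.integer(parc$data)))
    labels <- labels[labels > 0L]
  }
  n <- length(labels)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  n_self <- 0L; n_unlab <- 0L; n_conn <- 0L
  if (!length(streamlines)) {
    warnf("empty tractogram: connectome is all-zero")
  }
  for (i in seq_along(streamlines)) {
    lab <- endpoint_labels(streamlines[[i]], parc)
    if (any(lab == 0L)) { n_unlab <- n_unlab + 1L; next }
    if (lab[1] == lab[2]) { n_self <- n_self + 1L; next }
    a <- match(lab[1], labels); b <- match(lab[2], labels)
    if (is.na(a) || is.na(b)) { n_unlab <- n_unlab + 1L; next }
    w <- 1 / lengths_mm[i]
    W[a, b] <- W[a, b] + w
    W[b, a] <- W[b, a] + w
    n_conn <- n_conn + 1L
  }
  structure(list(weights = W, labels = as.integer(labels),
                 n_connecting = n_conn, n_self = n_self,
                 n_unlabeled = n_unlab),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes, %d edges, total weight %.4g mm^-1\n",
              length(x$labels), sum(x$weights[upper.tri(x$weights)] > 0),
              sum(x$weights) / 2))
  invisible(x)
}

as_weight_matrix <- function(m) {
  if (inherits(m, "connectivity_matrix")) m$weights else as.matrix(m)
}

#' Read/write connectivity matrices as TSV
#'
#' `write_connectome_tsv` writes the square matrix with region labels as
#' header; `write_edge_list_tsv` writes the nonzero upper triangle as
#' `node_a`, `node_b`, `weight` rows.
#'
#' @param m a `connectivity_matrix` or plain matrix.
#' @param file output path.
#' @return the path, invisibly (readers return the matrix).
#' @export
write_connectome_tsv <- function(m, file) {
  W <- as_weight_matrix(m)
  write.table(W, file, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  invisible(file)
}

#' @rdname write_connectome_tsv
#' @export
read_connectome_tsv <- function(file) {
  W <- as.matrix(read.table(file, sep = "\t", header = TRUE, row.names = 1L,
                            check.names = FALSE))
  dimnames(W) <- list(rownames(W), rownames(W))
  structure(list(weights = W, labels = as.integer(rownames(W)),
                 n_connecting = NA_integer_, n_self = NA_integer_,
                 n_unlabeled = NA_integer_),
            class = "connectivity_matrix")
}

#' @rdname write_connectome_tsv
#' @export
write_edge_list_tsv <- function(m, file) {
  W <- as_weight_matrix(m)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  el <- data.frame(node_a = rownames(W)[idx[, 1]],
                   node_b = colnames(W)[idx[, 2]],
                   weight = W[idx])
  write.table(el, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
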