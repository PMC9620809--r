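# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities through different algorithms
# than the package (enumeration, Floyd-Warshall, long-format linear
# models, closed forms) so that agreement is a genuine cross-check.

# ---- geometry fixtures -------------------------------------------------

# Uniform anisotropic slab: tensors with principal axis `axis` wherever
# the voxel center's x lies in [x0, x1], isotropic elsewhere. Returns a
# tensor_volume with voxel centers at i * voxel_size.
slab_phantom <- function(shape, voxel_size = 2, x0, x1,
                         axis = c(1, 0, 0),
                         ev_in = c(1.7e-3, 0.2e-3, 0.2e-3),
                         ev_bg = rep(0.7e-3, 3)) {
  affine <- diag(c(rep(voxel_size, 3), 1))
  D <- array(0, c(shape, 6))
  iso6 <- c(ev_bg[1], 0, 0, ev_bg[2], 0, ev_bg[3])
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- pracma_cross(axis, ref); u <- u / sqrt(sum(u^2))
  v <- pracma_cross(axis, u)
  Din <- ev_in[1] * tcrossprod(axis) + ev_in[2] * tcrossprod(u) +
    ev_in[3] * tcrossprod(v)
  in6 <- c(Din[1, 1], Din[1, 2], Din[1, 3], Din[2, 2], Din[2, 3], Din[3, 3])
  for (i in seq_len(shape[1])) {
    x <- (i - 1) * voxel_size
    t6 <- if (x >= x0 && x <= x1) in6 else iso6
    for (c6 in 1:6) D[i, , , c6] <- t6[c6]
  }
  svdnet::tensor_volume(D, affine)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Closed-form FA from three eigenvalues (direct evaluation of the
# definition, independent of the package's component-based route).
fa_closed_form <- function(ev) {
  md <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - md)^2) / sum(ev^2))
}

# Where does the trilinearly interpolated FA cross `cutoff` between an
# in-slab voxel center and its isotropic neighbor? Returns the fraction
# (0..1) of the voxel gap, solved on the 1-D interpolation formula.
fa_crossing_fraction <- function(ev_in = c(1.7e-3, 0.2e-3, 0.2e-3),
                                 ev_bg = rep(0.7e-3, 3), cutoff = 0.15) {
  f <- function(u) {
    D <- (1 - u) * diag(ev_in) + u * diag(ev_bg)
    fa_closed_form(eigen(D, symmetric = TRUE, only.values = TRUE)$values) - cutoff
  }
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

# ---- graph oracles -----------------------------------------------------

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = no
# edge), written as the plain triple loop.
fw_distances <- function(L) {
  n <- nrow(L)
  d <- L
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

weights_to_lengths <- function(W) {
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  L
}

# Exhaustive simple-path enumeration shortest distances (n <= ~7).
enum_distances <- function(W) {
  n <- nrow(W)
  L <- weights_to_lengths(W)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(node, target, visited, acc) {
    if (node == target) {
      if (acc < best[start, target]) best[start, target] <<- acc
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(L[node, nxt])) {
        visited[nxt] <- TRUE
        dfs(nxt, target, visited, acc + L[node, nxt])
        visited[nxt] <- FALSE
      }
    }
  }
  for (start in seq_len(n)) {
    for (target in seq_len(n)) {
      if (start != target) {
        visited <- rep(FALSE, n)
        visited[start] <- TRUE
        dfs(start, target, visited, 0)
      }
    }
  }
  best
}

enum_global_efficiency <- function(W) {
  n <- nrow(W)
  d <- enum_distances(W)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

enum_local_efficiency <- function(W) {
  n <- nrow(W)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    enum_global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# All labeled connected graphs on n nodes as edge-set bitmasks.
connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  ne <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^ne) - 1L) {
    A <- matrix(0, n, n)
    bits <- bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0
    for (e in which(bits)) {
      A[pairs[e, 1], pairs[e, 2]] <- 1
      A[pairs[e, 2], pairs[e, 1]] <- 1
    }
    # BFS connectivity
    seen <- rep(FALSE, n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nbs <- which(A[v, ] > 0 & !seen)
      seen[nbs] <- TRUE
      queue <- c(queue, nbs)
    }
    if (all(seen)) out[[length(out) + 1L]] <- A
  }
  out
}

# ---- statistics oracles ------------------------------------------------

# Repeated-measures F statistics computed on the long table with explicit
# subject dummies (within-subject stratum), a different computational
# path from the package's per-subject Delta/mean reduction.
rm_long_oracle <- function(tbl) {
  tbl <- tbl[order(tbl$subject_id, tbl$timepoint), ]
  subj <- factor(tbl$subject_id)
  tt <- as.numeric(tbl$timepoint == "followup")
  site <- factor(tbl$site)
  g <- as.numeric(tbl$group == "intensive")
  Zsub <- stats::model.matrix(~ subj)                    # includes intercept
  Ssum <- if (nlevels(site) > 1) {
    contrasts(site) <- stats::contr.sum(nlevels(site))
    stats::model.matrix(~ site)[, -1, drop = FALSE]
  } else {
    matrix(0, nrow(tbl), 0)
  }
  y <- tbl$metric
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  fstat <- function(X_red, X_full) {
    r0 <- rss(X_red); r1 <- rss(X_full)
    df2 <- nrow(X_full) - qr(X_full)$rank
    ((r0 - r1) / 1) / (r1 / df2)
  }
  X_int_full <- cbind(Zsub, tt, tt * Ssum, tt * g)
  X_int_red <- cbind(Zsub, tt, tt * Ssum)
  X_time_full <- cbind(Zsub, tt, tt * Ssum)
  X_time_red <- cbind(Zsub, tt * Ssum)
  # between-subject group F: sequential aov with group added after site
  adat <- data.frame(metric = y, site = factor(tbl$site), group = tbl$group,
                     subject_id = subj)
  a <- summary(stats::aov(metric ~ site + group + Error(subject_id),
                          data = adat))
  btab <- a[["Error: subject_id"]][[1]]
  grow <- grep("^group", trimws(rownames(btab)))
  c(group = btab[grow, "F value"],
    time = fstat(X_time_red, X_time_full),
    interaction = fstat(X_int_red, X_int_full))
}

# Exact permutation p for the interaction by enumerating all group-label
# assignments with fixed arm sizes (single-site tables, n small).
exhaustive_interaction_p <- function(tbl) {
  st_ids <- unique(tbl$subject_id)
  n <- length(st_ids)
  grp <- tbl$group[match(st_ids, tbl$subject_id)]
  n_int <- sum(grp == "intensive")
  obs <- rm_ancova_stats(tbl)$F["interaction"]
  picks <- combn(n, n_int)
  fs <- apply(picks, 2, function(sel) {
    new_grp <- rep("standard", n)
    new_grp[sel] <- "intensive"
    tb <- tbl
    tb$group <- factor(new_grp[match(tb$subject_id, st_ids)],
                       levels = c("standard", "intensive"))
    rm_ancova_stats(tb)$F["interaction"]
  })
  mean(fs >= obs - 1e-12)
}
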