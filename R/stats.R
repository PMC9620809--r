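# Permutational repeated-measures ANCOVA for two-time-point trial tables.
#
# With exactly two time points the repeated-measures decomposition reduces
# exactly to per-subject summaries: the group-by-time interaction is the
# group effect on the within-subject change Delta = followup - baseline,
# the group main effect is the group effect on the subject mean, and the
# time main effect is the intercept of the Delta model. Site enters as a
# fixed covariate (sum-coded dummies); permutation inference shuffles
# whole subjects (both time points together), within site strata by
# default, or flips the sign of Delta for the time effect.

# Collapse a long cohort table to one row per subject; validates the
# two-time-point structure.
subject_table <- function(tbl) {
  need <- c("subject_id", "site", "group", "timepoint", "metric")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stopf("table lacks columns: %s", paste(miss, collapse = ", "))
  tbl$timepoint <- as.character(tbl$timepoint)
  ids <- unique(tbl$subject_id)
  b <- tbl[tbl$timepoint == "baseline", ]
  f <- tbl[tbl$timepoint == "followup", ]
  if (nrow(b) != length(ids) || nrow(f) != length(ids)) {
    stopf("each subject must have exactly one baseline and one followup row")
  }
  b <- b[match(ids, b$subject_id), ]
  f <- f[match(ids, f$subject_id), ]
  if (any(b$site != f$site) || any(as.character(b$group) != as.character(f$group))) {
    stopf("site and group must be constant within subject")
  }
  st <- data.frame(
    subject_id = ids,
    site = factor(b$site),
    group = factor(as.character(b$group), levels = c("standard", "intensive")),
    delta = f$metric - b$metric,
    mean = (f$metric + b$metric) / 2,
    stringsAsFactors = FALSE
  )
  if (any(is.na(st$group))) stopf("group must be 'standard' or 'intensive'")
  if ("wmh_load" %in% names(tbl)) {
    st$wmh_baseline <- b$wmh_load
    st$wmh_delta <- f$wmh_load - b$wmh_load
  }
  if ("adherent" %in% names(tbl)) st$adherent <- as.logical(b$adherent)
  tg <- table(st$group)
  if (any(tg < 2)) stopf("group '%s' has < 2 subjects", names(tg)[tg < 2][1])
  ts <- table(st$site)
  if (any(ts < 2)) stopf("site '%s' has < 2 subjects", names(ts)[ts < 2][1])
  st
}

# Sum-coded site design columns (n x (n_sites - 1); 0 columns for 1 site).
site_columns <- function(site) {
  site <- factor(site)
  if (nlevels(site) < 2L) return(matrix(0, length(site), 0L))
  contrasts(site) <- contr.sum(nlevels(site))
  stats::model.matrix(~site)[, -1, drop = FALSE]
}

# F statistic for adding column x to nuisance X0 (X0 may have 0 columns;
# an intercept must be included explicitly). Degenerate conventions,
# judged against the outcome's own scale `ref` (sum of squared y): a
# nuisance model that already fits perfectly gives F = 0; a zero residual
# with a real effect gives Inf (perfect separation).
f_from_ss <- function(ss, rss0, rss1, df2, ref) {
  eps <- 1e-12 * (ref + 1e-300)
  k <- max(length(ss), length(rss0), length(rss1))
  ss <- rep_len(ss, k)
  rss0 <- rep_len(rss0, k)
  rss1 <- rep_len(rss1, k)
  ifelse(rss0 <= eps, 0,
         ifelse(rss1 > eps, ss / (rss1 / df2),
                ifelse(ss > eps, Inf, 0)))
}

partial_F <- function(y, X0, x) {
  n <- length(y)
  if (ncol(X0)) {
    q0 <- qr(X0)
    ry <- qr.resid(q0, y)
    rx <- qr.resid(q0, x)
  } else {
    ry <- y
    rx <- x
  }
  rss0 <- sum(ry^2)
  d <- sum(rx^2)
  ss <- if (d > 1e-12 * (sum(x^2) + 1e-300)) sum(rx * ry)^2 / d else 0
  rss1 <- rss0 - ss
  df2 <- n - ncol(X0) - 1L
  if (df2 < 1L) stopf("not enough residual degrees of freedom")
  f_from_ss(ss, rss0, max(rss1, 0), df2, sum(y^2))
}

#' Repeated-measures ANCOVA F statistics for a two-time-point cohort
#'
#' Computes the three F statistics of the site-adjusted repeated-measures
#' model via the exact two-time-point reduction: the group-by-time
#' interaction F is the F for group in `Delta ~ group + site (+
#' covariates)`; the group main-effect F is the F for group in
#' `mean ~ group + site`; the time main-effect F is the intercept test in
#' `Delta ~ 1 + site` (site sum-coded, so the intercept is the
#' site-averaged mean change). Zero-residual models with a real effect
#' yield `Inf` and are flagged as perfect separation.
#'
#' @param tbl long cohort table (see [simulate_cohort()]).
#' @param covariates optional per-subject covariate matrix/data.frame
#'   (rows in subject order of the collapsed table) added to the
#'   interaction model's nuisance terms.
#' @return list with named `F` vector (`group`, `time`, `interaction`),
#'   residual dfs, and `perfect_separation` flags.
#' @export
rm_ancova_stats <- function(tbl, covariates = NULL) {
  st <- subject_table(tbl)
  n <- nrow(st)
  S <- site_columns(st$site)
  g <- as.numeric(st$group == "intensive")
  X0i <- cbind(1, S)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stopf("covariates must have one row per subject")
    X0i <- cbind(X0i, covariates)
  }
  Fi <- partial_F(st$delta, X0i, g)
  Fg <- partial_F(st$mean, cbind(1, S), g)
  Ft <- partial_F(st$delta, S, rep(1, n))
  Fv <- c(group = Fg, time = Ft, interaction = Fi)
  list(F = Fv,
       df = c(residual_interaction = n - ncol(X0i) - 1L,
              residual_group = n - ncol(S) - 2L,
              residual_time = n - ncol(S) - 1L),
       perfect_separation = is.infinite(Fv))
}

# B within-stratum permutations of indices 1..n (columns of a matrix).
strata_permutations <- function(strata, B) {
  n <- length(strata)
  groups <- split(seq_len(n), strata)
  idx <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    col <- integer(n)
    for (gr in groups) {
      col[gr] <- if (length(gr) > 1L) gr[sample.int(length(gr))] else gr
    }
    idx[, b] <- col
  }
  idx
}

# Vectorized permutation F for adding a (permuted) binary column to fixed
# nuisance X0: G is n x B of permuted test columns.
perm_F_labels <- function(y, X0, G) {
  n <- length(y)
  if (ncol(X0)) {
    Q0 <- qr.Q(qr(X0))
    ry <- y - Q0 %*% crossprod(Q0, y)
    Gt <- G - Q0 %*% crossprod(Q0, G)
  } else {
    ry <- y
    Gt <- G
  }
  rss0 <- sum(ry^2)
  d <- colSums(Gt^2)
  num <- as.numeric(crossprod(Gt, ry))
  ss <- ifelse(d > 1e-12 * (colSums(G^2) + 1e-300), num^2 / d, 0)
  rss1 <- pmax(rss0 - ss, 0)
  df2 <- n - ncol(X0) - 1L
  f_from_ss(ss, rss0, rss1, df2, sum(y^2))
}

#' Permutation tests for group, time, and group-by-time effects
#'
#' Permutation inference for the site-adjusted repeated-measures model of
#' [rm_ancova_stats()]. The permutation unit is the whole subject: for the
#' `group` and `interaction` effects, subjects' group labels are shuffled
#' (within site strata by default); for the `time` effect the sign of each
#' subject's within-subject change is flipped at random. p-values use the
#' add-one estimator `p = (1 + #(F_perm >= F_obs)) / (1 + B)`, which is
#' bounded below by `1/(B+1)` and counts ties as extreme.
#'
#' @param tbl long cohort table.
#' @param effects which effects to test (any of `"group"`, `"time"`,
#'   `"interaction"`).
#' @param B number of permutations (>= 99).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param stratify_by_site shuffle labels within site strata.
#' @return An object of class `permutation_result`: observed F statistics
#'   for all three effects, permutation p-values for the requested
#'   effects, `B`, and the seed.
#' @examples
#' tbl <- simulate_cohort(cohort_spec(n_per_arm = c(8, 8), n_sites = 2, seed = 3))
#' permutation_test(tbl, effects = "interaction", B = 199, seed = 1)
#' @export
permutation_test <- function(tbl, effects = c("group", "time", "interaction"),
                             B = 999L, seed = 1L, stratify_by_site = TRUE) {
  effects <- match.arg(effects, several.ok = TRUE)
  if (B < 99L) stopf("B must be >= 99")
  st <- subject_table(tbl)
  n <- nrow(st)
  S <- site_columns(st$site)
  g <- as.numeric(st$group == "intensive")
  obs <- rm_ancova_stats(tbl)$F
  strata <- if (stratify_by_site) st$site else rep(1L, n)

  p <- setNames(rep(NA_real_, length(effects)), effects)
  with_seed(seed, {
    if (any(c("group", "interaction") %in% effects)) {
      idx <- strata_permutations(strata, B)
      G <- matrix(g[idx], n, B)
      if ("interaction" %in% effects) {
        Fb <- perm_F_labels(st$delta, cbind(1, S), G)
        p["interaction"] <- (1 + sum(Fb >= obs["interaction"])) / (1 + B)
      }
      if ("group" %in% effects) {
        Fb <- perm_F_labels(st$mean, cbind(1, S), G)
        p["group"] <- (1 + sum(Fb >= obs["group"])) / (1 + B)
      }
    }
    if ("time" %in% effects) {
      y <- st$delta
      Sg <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
      M0 <- diag(n)
      if (ncol(S)) {
        Q0 <- qr.Q(qr(S))
        M0 <- M0 - tcrossprod(Q0)
      }
      Q1 <- qr.Q(qr(cbind(1, S)))
      M1 <- diag(n) - tcrossprod(Q1)
      yy <- tcrossprod(y)
      A0 <- M0 * yy
      A1 <- M1 * yy
      rss0 <- colSums(Sg * (A0 %*% Sg))
      rss1 <- pmax(colSums(Sg * (A1 %*% Sg)), 0)
      ss <- pmax(rss0 - rss1, 0)
      Fb <- f_from_ss(ss, rss0, rss1, n - ncol(S) - 1L, sum(y^2))
      p["time"] <- (1 + sum(Fb >= obs["time"])) / (1 + B)
    }
  })

  structure(list(F = obs, p = p, n_permutations = as.integer(B),
                 seed = as.integer(seed), stratified = stratify_by_site,
                 effects = effects),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> B = %d, seed = %d%s\n", x$n_permutations,
              x$seed, if (isTRUE(x$stratified)) ", site-stratified" else ""))
  for (e in x$effects) {
    cat(sprintf("  %-12s F = %-10.4g p = %.4g\n", e, x$F[e], x$p[e]))
  }
  invisible(x)
}

#' WMH-adjusted group-by-time permutation test
#'
#' Tests the group-by-time interaction with white-matter-hyperintensity
#' lesion load entered as covariates: the baseline load (intercept) and
#' its 2-year change (slope) join the nuisance terms of the Delta model.
#' Inference uses the Freedman-Lane scheme: the outcome is re-composed
#' from the nuisance-model fit plus permuted nuisance residuals (within
#' site strata by default) while covariates stay fixed. Zero-variance
#' covariates are dropped with a warning; if none remain the result
#' equals the unadjusted [permutation_test()].
#'
#' @param tbl long cohort table with a `wmh_load` column.
#' @param B,seed,stratify_by_site as in [permutation_test()].
#' @return A `permutation_result` for the interaction effect, with the
#'   names of the covariates actually used in `covariates_used`.
#' @export
wmh_adjusted_test <- function(tbl, B = 999L, seed = 1L,
                              stratify_by_site = TRUE) {
  if (!"wmh_load" %in% names(tbl)) stopf("table lacks a wmh_load column")
  if (any(is.na(tbl$wmh_load))) stopf("wmh_load contains missing values")
  if (B < 99L) stopf("B must be >= 99")
  st <- subject_table(tbl)
  covs <- cbind(wmh_baseline = st$wmh_baseline, wmh_delta = st$wmh_delta)
  keep <- apply(covs, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warnf("dropping zero-variance covariate(s): %s",
          paste(colnames(covs)[!keep], collapse = ", "))
  }
  covs <- covs[, keep, drop = FALSE]
  if (!ncol(covs)) {
    res <- permutation_test(tbl, effects = "interaction", B = B, seed = seed,
                            stratify_by_site = stratify_by_site)
    res$covariates_used <- character(0)
    return(res)
  }

  n <- nrow(st)
  S <- site_columns(st$site)
  g <- as.numeric(st$group == "intensive")
  y <- st$delta
  Z <- cbind(1, S, covs)
  obs_all <- rm_ancova_stats(tbl, covariates = covs)$F
  obs <- obs_all["interaction"]

  Qz <- qr.Q(qr(Z))
  fit <- as.numeric(Qz %*% crossprod(Qz, y))
  e <- y - fit
  gt <- g - as.numeric(Qz %*% crossprod(Qz, g))
  d <- sum(gt^2)
  df2 <- n - ncol(Z) - 1L
  strata <- if (stratify_by_site) st$site else rep(1L, n)

  p <- with_seed(seed, {
    idx <- strata_permutations(strata, B)
    E <- matrix(e[idx], n, B)
    Mz <- diag(n) - tcrossprod(Qz)
    rss0 <- colSums(E * (Mz %*% E))
    num <- as.numeric(crossprod(gt, E))  # gt is orthogonal to fit
    ss <- if (d > 1e-12 * sum(g^2)) num^2 / d else rep(0, B)
    rss1 <- pmax(rss0 - ss, 0)
    Fb <- f_from_ss(ss, rss0, rss1, df2, sum(y^2))
    (1 + sum(Fb >= obs)) / (1 + B)
  })

  structure(list(F = obs_all, p = c(interaction = p),
                 n_permutations = as.integer(B), seed = as.integer(seed),
                 stratified = stratify_by_site, effects = "interaction",
                 covariates_used = colnames(covs)),
            class = "permutation_result")
}

#' Per-protocol subset of a cohort table
#'
#' Restricts the table to subjects flagged as protocol-adherent (e.g.
#' those reaching the blood-pressure target), keeping both time points of
#' each retained subject.
#'
#' @param tbl long cohort table with an `adherent` column.
#' @return The filtered table.
#' @export
per_protocol_subset <- function(tbl) {
  if (!"adherent" %in% names(tbl)) stopf("table lacks an adherent column")
  out <- tbl[as.logical(tbl$adherent), , drop = FALSE]
  remaining <- table(factor(unique(out[c("subject_id", "group")])$group,
                            levels = c("standard", "intensive")))
  if (any(remaining == 0)) {
    stopf("per-protocol filtering emptied group '%s'",
          names(remaining)[remaining == 0][1])
  }
  rownames(out) <- NULL
  out
}
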