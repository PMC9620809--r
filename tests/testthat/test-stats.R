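test_that("Delta-model F statistics equal the long-format repeated-measures oracle", {
  for (s in c(5L, 9L, 23L)) {
    tbl <- simulate_cohort(cohort_spec(seed = s, slope_intensive = 0.02))
    imp <- rm_ancova_stats(tbl)$F
    ora <- rm_long_oracle(tbl)
    expect_equal(unname(imp), unname(ora[names(imp)]), tolerance = 1e-8)
  }
})

test_that("noise-free cohorts give the degenerate F values", {
  base <- cohort_spec(n_per_arm = c(6, 6), n_sites = 2, baseline_sd = 0,
                      subject_sd = 0, site_sd = 0, residual_sd = 0, seed = 1)
  # opposite slopes, zero residual: perfect separation
  sp <- base
  sp$slope_standard <- -1
  sp$slope_intensive <- 1
  r <- rm_ancova_stats(simulate_cohort(sp))
  expect_true(is.infinite(r$F["interaction"]))
  expect_true(r$perfect_separation["interaction"])
  # identical slopes, zero residual: interaction F = 0
  sp2 <- base
  sp2$slope_standard <- sp2$slope_intensive <- 0.5
  expect_equal(unname(rm_ancova_stats(simulate_cohort(sp2))$F["interaction"]), 0)
})

test_that("a constant metric yields F = 0 and p = 1", {
  tbl <- simulate_cohort(cohort_spec(n_per_arm = c(6, 6), n_sites = 2, seed = 4))
  tbl$metric <- 0.5
  r <- permutation_test(tbl, B = 199, seed = 7)
  expect_equal(unname(r$F), c(0, 0, 0))
  expect_equal(unname(r$p), c(1, 1, 1))
})

test_that("site-constant shifts are absorbed by the covariate", {
  tbl <- simulate_cohort(cohort_spec(seed = 13, slope_intensive = 0.03))
  shifted <- tbl
  shifted$metric[shifted$site == 3] <- shifted$metric[shifted$site == 3] + 5
  expect_equal(rm_ancova_stats(shifted)$F, rm_ancova_stats(tbl)$F,
               tolerance = 1e-8)
})

test_that("permutation p-values are bounded, reproducible, and seed-sensitive", {
  tbl <- simulate_cohort(cohort_spec(seed = 17, slope_intensive = 0.02))
  r1 <- permutation_test(tbl, B = 499, seed = 3)
  r2 <- permutation_test(tbl, B = 499, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_true(all(r1$p >= 1 / 500 & r1$p <= 1))
  expect_error(permutation_test(tbl, B = 50), "B must be")
})

test_that("Monte-Carlo p matches exhaustive enumeration on a small cohort", {
  spec <- cohort_spec(n_per_arm = c(5, 5), n_sites = 1, seed = 29,
                      slope_intensive = 0.02)
  tbl <- simulate_cohort(spec)
  p_exact <- exhaustive_interaction_p(tbl)      # all C(10, 5) assignments
  B <- 1999L
  p_mc <- permutation_test(tbl, effects = "interaction", B = B, seed = 11,
                           stratify_by_site = FALSE)$p[["interaction"]]
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B)
})

test_that("group- or site-degenerate tables are rejected with the level named", {
  tbl <- simulate_cohort(cohort_spec(n_per_arm = c(6, 6), n_sites = 2, seed = 2))
  one_std <- tbl[!(tbl$group == "standard" &
                     tbl$subject_id != tbl$subject_id[1]), ]
  expect_error(rm_ancova_stats(one_std), "standard")
  lone_site <- tbl
  lone_site$site[lone_site$subject_id == "S001"] <- 9
  expect_error(rm_ancova_stats(lone_site), "9")
})

test_that("per-protocol subsetting keeps adherent subjects only", {
  tbl <- simulate_cohort(cohort_spec(n_per_arm = c(8, 8), n_sites = 2, seed = 6))
  tbl$adherent <- TRUE
  expect_equal(per_protocol_subset(tbl), tbl, ignore_attr = TRUE)
  # drop three specific subjects
  tbl$adherent[tbl$subject_id %in% c("S001", "S009", "S010")] <- FALSE
  sub <- per_protocol_subset(tbl)
  expect_equal(length(unique(sub$subject_id)), 13L)
  expect_true(all(table(sub$subject_id) == 2L))
  # a group emptied by filtering errors
  tbl$adherent[tbl$group == "intensive"] <- FALSE
  expect_error(per_protocol_subset(tbl), "intensive")
  expect_error(per_protocol_subset(tbl[, setdiff(names(tbl), "adherent")]),
               "adherent")
})

test_that("subset sizes follow the arm adherence probabilities", {
  n_rep <- 200L
  sizes <- matrix(0, n_rep, 2)
  for (r in seq_len(n_rep)) {
    tbl <- simulate_cohort(cohort_spec(seed = 1000L + r))
    sub <- per_protocol_subset(tbl)
    base <- sub[sub$timepoint == "baseline", ]
    sizes[r, ] <- as.vector(table(base$group))
  }
  # binomial expectations 40 * 0.875 = 35 and 42 * 2/3 = 28
  expect_lt(abs(mean(sizes[, 1]) - 35), 3 * sd(sizes[, 1]) / sqrt(n_rep))
  expect_lt(abs(mean(sizes[, 2]) - 28), 3 * sd(sizes[, 2]) / sqrt(n_rep))
})

test_that("zero-variance WMH covariates fall back to the unadjusted test", {
  tbl <- simulate_cohort(cohort_spec(n_per_arm = c(8, 8), n_sites = 2, seed = 21))
  tbl$wmh_load <- 3.4                      # no variance in either covariate
  expect_warning(adj <- wmh_adjusted_test(tbl, B = 299, seed = 5),
                 "zero-variance")
  una <- permutation_test(tbl, effects = "interaction", B = 299, seed = 5)
  expect_equal(adj$p[["interaction"]], una$p[["interaction"]])
  expect_equal(adj$covariates_used, character(0))
  expect_error(wmh_adjusted_test(tbl[, setdiff(names(tbl), "wmh_load")]),
               "wmh_load")
})

test_that("WMH-driven metrics do not fool the adjusted test", {
  # metric fully determined by lesion load, no group effect: the adjusted
  # interaction test should reject at close to the nominal rate only
  n_rep <- 100L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    tbl <- simulate_cohort(cohort_spec(n_per_arm = c(15, 15), n_sites = 3,
                                       seed = 5000L + r))
    tbl$metric <- 0.1 * tbl$wmh_load
    p <- wmh_adjusted_test(tbl, B = 199, seed = r)$p[["interaction"]]
    rej <- rej + (p <= 0.05)
  }
  expect_gte(n_rep - rej, 0.95 * n_rep - 3)  # non-significant in >= ~95%
})

test_that("adjusted and unadjusted tests agree when WMH is independent", {
  set.seed(61)
  pu <- pa <- numeric(40)
  for (r in 1:40) {
    tbl <- simulate_cohort(cohort_spec(n_per_arm = c(15, 15), n_sites = 3,
                                       seed = 7000L + r,
                                       slope_intensive = 0.02))
    pu[r] <- permutation_test(tbl, effects = "interaction", B = 499,
                              seed = r)$p[["interaction"]]
    pa[r] <- wmh_adjusted_test(tbl, B = 499, seed = r)$p[["interaction"]]
  }
  expect_gt(cor(pu, pa), 0.9)
  expect_lt(mean(abs(pu - pa)), 0.1)
})
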