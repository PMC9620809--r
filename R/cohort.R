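#' Specify a simulated two-arm longitudinal cohort
#'
#' Describes a two-arm (standard vs intensive), two-time-point
#' (baseline, 2-year follow-up) trial cohort with subjects distributed
#' round-robin across sites. The metric model per subject s at time t
#' (t = 0 baseline, 1 follow-up) is
#' `metric = baseline_mean + site_effect + subject_intercept +
#'  slope_arm * t + residual`, with the subject intercept the sum of two
#' independent zero-mean Gaussian components (`baseline_sd` and
#' `subject_sd`), site effects drawn once per site from
#' `N(0, site_sd)`, and i.i.d. residuals `N(0, residual_sd)` per
#' observation. WMH lesion load (% of brain volume) is simulated per
#' subject with a Gaussian baseline and a Gaussian 2-year change, both
#' truncated at 0. A per-subject protocol-adherence flag is drawn with an
#' arm-specific probability.
#'
#' Defaults emulate the trial structure this pipeline targets: arms of
#' 40 and 42 subjects over 6 sites, lesion load 3.4% +/- 2.3 at baseline,
#' and adherence probabilities 35/40 and 28/42.
#'
#' @param n_per_arm integer pair: subjects in the standard / intensive arm.
#' @param n_sites number of study sites.
#' @param baseline_mean,baseline_sd grand mean and stable between-subject
#'   SD of the metric at baseline.
#' @param subject_sd additional subject random-intercept SD.
#' @param site_sd SD of the per-site shift.
#' @param residual_sd per-observation residual SD.
#' @param slope_standard,slope_intensive mean 2-year change per arm
#'   (metric units per 2 years).
#' @param wmh_baseline_mean,wmh_slope_mean,wmh_sd WMH lesion-load model (%).
#' @param adherence_prob_per_arm pair of probabilities in `[0, 1]`.
#' @param seed integer seed; all cohort randomness flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = c(40L, 42L),
                        n_sites = 6L,
                        baseline_mean = 0.70,
                        baseline_sd = 0.05,
                        subject_sd = 0.03,
                        site_sd = 0.02,
                        residual_sd = 0.025,
                        slope_standard = 0,
                        slope_intensive = 0,
                        wmh_baseline_mean = 3.4,
                        wmh_slope_mean = 0.4,
                        wmh_sd = 2.3,
                        adherence_prob_per_arm = c(35 / 40, 28 / 42),
                        seed = 1L) {
  n_per_arm <- as.integer(n_per_arm)
  if (length(n_per_arm) != 2L || any(n_per_arm < 2L)) {
    stopf("n_per_arm must be two integers >= 2")
  }
  if (n_sites < 1L) stopf("n_sites must be >= 1")
  sds <- c(baseline_sd, subject_sd, site_sd, residual_sd, wmh_sd)
  if (any(sds < 0)) stopf("all SDs must be >= 0")
  if (any(adherence_prob_per_arm < 0 | adherence_prob_per_arm > 1)) {
    stopf("adherence probabilities must lie in [0, 1]")
  }
  structure(list(n_per_arm = n_per_arm, n_sites = as.integer(n_sites),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 subject_sd = subject_sd, site_sd = site_sd,
                 residual_sd = residual_sd,
                 slope_standard = slope_standard,
                 slope_intensive = slope_intensive,
                 wmh_baseline_mean = wmh_baseline_mean,
                 wmh_slope_mean = wmh_slope_mean, wmh_sd = wmh_sd,
                 adherence_prob_per_arm = as.numeric(adherence_prob_per_arm),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a longitudinal cohort table
#'
#' Draws one cohort from a [cohort_spec()]: one row per subject and time
#' point, in long format. Bit-reproducible for a fixed spec seed; arm
#' sizes and round-robin site assignment are deterministic.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with columns `subject_id`, `site`, `group`
#'   (`standard` / `intensive`), `timepoint` (`baseline` / `followup`),
#'   `metric`, `wmh_load`, `adherent`.
#' @examples
#' tbl <- simulate_cohort(cohort_spec(n_per_arm = c(6, 6), n_sites = 2, seed = 7))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_std <- spec$n_per_arm[1]
  n_int <- spec$n_per_arm[2]
  n <- n_std + n_int
  group <- rep(c("standard", "intensive"), c(n_std, n_int))
  # round-robin site assignment within each arm keeps arms balanced over sites
  site <- integer(n)
  site[group == "standard"] <- ((seq_len(n_std) - 1L) %% spec$n_sites) + 1L
  site[group == "intensive"] <- ((seq_len(n_int) - 1L) %% spec$n_sites) + 1L
  slope <- ifelse(group == "standard", spec$slope_standard, spec$slope_intensive)
  adh_p <- ifelse(group == "standard", spec$adherence_prob_per_arm[1],
                  spec$adherence_prob_per_arm[2])

  with_seed(spec$seed, {
    site_eff <- rnorm(spec$n_sites, 0, spec$site_sd)
    intercept <- rnorm(n, 0, spec$baseline_sd) + rnorm(n, 0, spec$subject_sd)
    resid <- matrix(rnorm(2L * n, 0, spec$residual_sd), n, 2L)
    wmh_b <- pmax(0, rnorm(n, spec$wmh_baseline_mean, spec$wmh_sd))
    wmh_f <- pmax(0, wmh_b + rnorm(n, spec$wmh_slope_mean, spec$wmh_sd / 2))
    adherent <- rbinom(n, 1L, adh_p) == 1L

    level <- spec$baseline_mean + site_eff[site] + intercept
    metric_b <- level + resid[, 1]
    metric_f <- level + slope + resid[, 2]

    data.frame(
      subject_id = rep(sprintf("S%03d", seq_len(n)), each = 2L),
      site = rep(site, each = 2L),
      group = factor(rep(group, each = 2L), levels = c("standard", "intensive")),
      timepoint = factor(rep(c("baseline", "followup"), n),
                         levels = c("baseline", "followup")),
      metric = as.numeric(rbind(metric_b, metric_f)),
      wmh_load = as.numeric(rbind(wmh_b, wmh_f)),
      adherent = rep(adherent, each = 2L),
      stringsAsFactors = FALSE
    )
  })
}

#' Read/write cohort tables as TSV
#'
#' @param tbl a cohort `data.frame` as produced by [simulate_cohort()].
#' @param file path to a tab-separated file.
#' @return `read_cohort_tsv` returns the table with factor columns
#'   restored; `write_cohort_tsv` returns `file` invisibly.
#' @export
write_cohort_tsv <- function(tbl, file) {
  write.table(tbl, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(file) {
  tbl <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tbl$group <- factor(tbl$group, levels = c("standard", "intensive"))
  tbl$timepoint <- factor(tbl$timepoint, levels = c("baseline", "followup"))
  tbl$adherent <- as.logical(tbl$adherent)
  tbl
}
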