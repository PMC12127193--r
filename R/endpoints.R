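# Clinical endpoint computation: percent change from baseline, EASI50
# responder labels, within-arm and between-arm tests with Shapiro-Wilk
# normality gating, one-way ANOVA baseline balance, and subgroup filters.

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`; negative values indicate
#' improvement. Vectorized; the baseline must be strictly positive.
#'
#' @param baseline,followup scores (baseline > 0).
#' @return percent change.
#' @export
#' @examples
#' pct_change(8, 4)   # -50
pct_change <- function(baseline, followup) {
  .assert(all(baseline > 0, na.rm = TRUE),
          "percent change is undefined for baseline <= 0")
  100 * (followup - baseline) / baseline
}

#' EASI50 responder label
#'
#' A patient is an EASI50 responder iff the week-4 percent change in EASI is
#' at most -50 (boundary inclusive: exactly -50% counts as response).
#'
#' @param pct percent change from baseline.
#' @return logical flag (NA propagates).
#' @export
#' @examples
#' label_easi50(c(-50, -49.9, -100))
label_easi50 <- function(pct) pct <= -50

#' Per-patient endpoint table
#'
#' Computes week-2/week-4 percent changes in EASI and IGA (the ordinal IGA
#' grade is treated as numeric for percent change) and the EASI50 responder
#' flag at week 4. Missing follow-ups give missing endpoints (complete-case
#' logic downstream).
#'
#' @param cohort clinical table as produced by [generate_cohort()] (or user
#'   data with the same columns).
#' @return data.frame with one row per patient.
#' @export
compute_endpoints <- function(cohort) {
  need <- c("patient_id", "arm", "easi_baseline", "easi_wk2", "easi_wk4",
            "iga_baseline", "iga_wk2", "iga_wk4")
  .assert(all(need %in% names(cohort)),
          paste("cohort is missing columns:",
                paste(setdiff(need, names(cohort)), collapse = ", ")))
  p4 <- pct_change(cohort$easi_baseline, cohort$easi_wk4)
  data.frame(
    patient_id = cohort$patient_id,
    arm = cohort$arm,
    pct_easi_wk2 = pct_change(cohort$easi_baseline, cohort$easi_wk2),
    pct_easi_wk4 = p4,
    pct_iga_wk2 = pct_change(cohort$iga_baseline, cohort$iga_wk2),
    pct_iga_wk4 = pct_change(cohort$iga_baseline, cohort$iga_wk4),
    easi50_wk4 = label_easi50(p4),
    stringsAsFactors = FALSE)
}

#' Within-arm change test with normality gating
#'
#' Tests whether percent changes within one arm differ from zero. The change
#' vector is first gated by a Shapiro-Wilk normality test at `shapiro_alpha`:
#' if normality is not rejected a one-sample t test is used, otherwise the
#' Wilcoxon signed-rank test. An all-zero change vector is degenerate and
#' reported as p = 1 with `test_used = "none"`; a non-zero constant vector
#' falls through to the signed-rank test (the t statistic is undefined at
#' zero variance).
#'
#' @param pct_changes numeric vector of percent changes (n >= 3; NAs dropped).
#' @param shapiro_alpha gate level for the normality test (default 0.05).
#' @return list with `p_value` and `test_used` (`"t"`, `"wilcoxon"` or
#'   `"none"`).
#' @export
within_arm_change_test <- function(pct_changes, shapiro_alpha = 0.05) {
  x <- pct_changes[!is.na(pct_changes)]
  .assert(length(x) >= 3, "at least 3 observations are required")
  if (all(x == 0)) return(list(p_value = 1, test_used = "none"))
  if (stats::sd(x) == 0) {
    p <- suppressWarnings(stats::wilcox.test(x)$p.value)
    return(list(p_value = p, test_used = "wilcoxon"))
  }
  normal <- stats::shapiro.test(x)$p.value >= shapiro_alpha
  if (normal) list(p_value = stats::t.test(x)$p.value, test_used = "t")
  else list(p_value = suppressWarnings(stats::wilcox.test(x)$p.value),
            test_used = "wilcoxon")
}

#' Between-arm contrast of percent changes
#'
#' Two-sided two-sample t test of the mean difference (active - placebo)
#' with a 95% confidence interval. Welch's unequal-variance form is the
#' default; set `var_equal = TRUE` for the pooled-variance (classical
#' Student) form. Degenerate zero-variance input yields the exact mean
#' difference with an infinite CI and a missing p-value instead of an error.
#'
#' @param active,placebo numeric vectors of percent changes (NAs dropped,
#'   n >= 2 each).
#' @param var_equal pool the variances? Default FALSE (Welch).
#' @param conf_level confidence level (default 0.95).
#' @return list with `mean_diff`, `ci_low`, `ci_high`, `p_value`,
#'   `test_used`, `n_per_group`.
#' @export
#' @examples
#' between_arm_contrast(c(-60, -50, -70), c(-5, 0, 5))
between_arm_contrast <- function(active, placebo, var_equal = FALSE,
                                 conf_level = 0.95) {
  a <- active[!is.na(active)]
  p <- placebo[!is.na(placebo)]
  .assert(length(a) >= 2 && length(p) >= 2,
          "both groups need at least 2 non-missing observations")
  md <- mean(a) - mean(p)
  tt <- tryCatch(
    stats::t.test(a, p, var.equal = var_equal, conf.level = conf_level),
    error = function(e) NULL)
  if (is.null(tt)) {  # constant data: report the difference, no inference
    return(list(mean_diff = md, ci_low = -Inf, ci_high = Inf,
                p_value = NA_real_, test_used = "t",
                n_per_group = c(active = length(a), placebo = length(p))))
  }
  list(mean_diff = md, ci_low = unname(tt$conf.int[1]),
       ci_high = unname(tt$conf.int[2]), p_value = tt$p.value,
       test_used = "t",
       n_per_group = c(active = length(a), placebo = length(p)))
}

#' One-way ANOVA balance check across arms
#'
#' Classical (pooled-variance) one-way analysis of variance of a baseline
#' variable across treatment arms; returns the F-test p-value.
#'
#' @param values_by_arm named list of numeric vectors, one per arm.
#' @return p-value.
#' @export
#' @examples
#' baseline_balance(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
baseline_balance <- function(values_by_arm) {
  values_by_arm <- lapply(values_by_arm, function(x) x[!is.na(x)])
  ns <- lengths(values_by_arm)
  .assert(sum(ns >= 2) >= 2, "at least two arms with n >= 2 are required")
  v <- unlist(values_by_arm, use.names = FALSE)
  g <- factor(rep(names(values_by_arm), ns))
  stats::oneway.test(v ~ g, var.equal = TRUE)$p.value
}

#' Subgroup filter on a cohort
#'
#' Selects cohort rows by one of the stated subgroup rules: a baseline-EASI
#' interval (left-open, right-closed, so `easi_range = c(7, 21)` means
#' 7 < EASI <= 21), a baseline IGA level, an enrollment-date window
#' (inclusive), or a season.
#'
#' @param cohort clinical table.
#' @param easi_range length-2 numeric `(lo, hi]` interval on baseline EASI.
#' @param iga_level baseline IGA grade to keep.
#' @param enrollment length-2 Date (or coercible) window, inclusive.
#' @param season `"spring_summer"` or `"fall_winter"`.
#' @return the matching rows; an empty result is allowed but flagged with a
#'   warning.
#' @export
#' @examples
#' co <- generate_cohort(trial_config(seed = 1))
#' nrow(subgroup_filter(co, easi_range = c(7, 21)))
subgroup_filter <- function(cohort, easi_range = NULL, iga_level = NULL,
                            enrollment = NULL, season = NULL) {
  given <- !c(is.null(easi_range), is.null(iga_level), is.null(enrollment),
              is.null(season))
  .assert(sum(given) == 1, "specify exactly one subgroup rule")
  keep <- if (!is.null(easi_range)) {
    .assert(length(easi_range) == 2 && easi_range[1] < easi_range[2],
            "easi_range must be an increasing (lo, hi] pair")
    cohort$easi_baseline > easi_range[1] & cohort$easi_baseline <= easi_range[2]
  } else if (!is.null(iga_level)) {
    cohort$iga_baseline == iga_level
  } else if (!is.null(enrollment)) {
    w <- as.Date(enrollment)
    .assert(length(w) == 2 && w[1] <= w[2], "enrollment must be a date window")
    as.Date(cohort$enrollment_date) >= w[1] & as.Date(cohort$enrollment_date) <= w[2]
  } else {
    cohort$season == season
  }
  out <- cohort[which(keep), , drop = FALSE]
  if (nrow(out) == 0) warning("subgroup filter matched no patients")
  out
}
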