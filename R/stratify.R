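# Single-marker predictive-biomarker engine: AUROC, Youden-optimal cut-offs
# with direction selection, the AUROC > 0.7 screen for differentially
# expressed proteins (DEPs), hi/lo stratification with 2x2 confusion
# metrics, odds ratios with the Haldane-Anscombe zero-cell correction, the
# dual-endpoint benefit indicator, and per-stratum reports.

#' Area under the ROC curve
#'
#' Empirical AUROC of a continuous marker against a binary responder label,
#' computed through the rank-sum identity (equivalent to the trapezoidal
#' area): ties between a responder and a non-responder contribute 1/2.
#'
#' @param levels numeric marker values.
#' @param responder_flags logical (or 0/1) labels; both classes must be
#'   present.
#' @return AUROC in \[0, 1\] (probability that a random responder exceeds a
#'   random non-responder).
#' @export
#' @examples
#' auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # 1
auroc <- function(levels, responder_flags) {
  y <- as.logical(responder_flags)
  ok <- !is.na(levels) & !is.na(y)
  x <- levels[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  .assert(n1 > 0 && n0 > 0,
          "AUROC is undefined unless both classes are present")
  r <- rank(x)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cut-off for a single marker
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' marker values. Both directions are evaluated - `"hi"` (level >= cut-off
#' predicts response) and `"lo"` (level <= cut-off predicts response) - and
#' the direction/threshold pair maximizing the Youden index
#' J = sensitivity + specificity - 1 is returned. Ties are broken in favor
#' of `"hi"`, then the smaller cut-off, so the result is deterministic.
#' Constant marker values are degenerate: J = 0 with an undefined direction.
#'
#' @inheritParams auroc
#' @return list of class `cutoff_result` with `direction` (`"hi"`, `"lo"` or
#'   `NA`), `cutoff`, `J`, `sensitivity`, `specificity` and `auroc` (the
#'   direction-adjusted area, `max(a, 1 - a)`).
#' @export
#' @examples
#' youden_optimal_cutoff(c(1, 2, 10, 12), c(FALSE, FALSE, TRUE, TRUE))
youden_optimal_cutoff <- function(levels, responder_flags) {
  y <- as.logical(responder_flags)
  ok <- !is.na(levels) & !is.na(y)
  x <- levels[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  .assert(n1 > 0 && n0 > 0,
          "cut-off selection requires both classes to be present")
  a <- auroc(x, y)
  u <- sort(unique(x))
  if (length(u) < 2) {
    return(structure(list(direction = NA_character_, cutoff = NA_real_,
                          J = 0, sensitivity = NA_real_, specificity = NA_real_,
                          auroc = max(a, 1 - a)),
                     class = "cutoff_result"))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- list(J = -Inf)
  for (t in cand) {
    for (dir in c("hi", "lo")) {
      pred <- if (dir == "hi") x >= t else x <= t
      sens <- sum(pred & y) / n1
      spec <- sum(!pred & !y) / n0
      J <- sens + spec - 1
      better <- J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && dir == "hi" && !identical(best$direction, "hi")) ||
        (abs(J - best$J) <= 1e-12 && identical(dir, best$direction) && t < best$cutoff)
      if (better)
        best <- list(direction = dir, cutoff = t, J = J,
                     sensitivity = sens, specificity = spec)
    }
  }
  structure(c(best[c("direction", "cutoff", "J", "sensitivity", "specificity")],
              list(auroc = max(a, 1 - a))),
            class = "cutoff_result")
}

#' Screen a quantification matrix for predictive proteins
#'
#' Computes a direction-adjusted AUROC (`max(a, 1 - a)`) per protein against
#' the responder labels (typically within the active arm only) and keeps
#' proteins whose AUROC strictly exceeds `auroc_min`, attaching each kept
#' protein's Youden-optimal cut-off. Results are sorted by AUROC descending
#' with ties broken by protein id.
#'
#' @param matrix patients x proteins abundance matrix (active-arm rows).
#' @param responder_flags logical labels aligned with the rows.
#' @param auroc_min selection threshold (default 0.7, strict).
#' @return data.frame with columns `protein_id`, `auroc`, `direction`,
#'   `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
select_deps <- function(matrix, responder_flags, auroc_min = 0.7) {
  .assert(is.matrix(matrix) && !is.null(colnames(matrix)),
          "a matrix with protein ids as column names is required")
  .assert(nrow(matrix) == length(responder_flags),
          "responder_flags must align with matrix rows")
  res <- lapply(colnames(matrix), function(id) {
    cr <- youden_optimal_cutoff(matrix[, id], responder_flags)
    data.frame(protein_id = id, auroc = cr$auroc,
               direction = cr$direction, cutoff = cr$cutoff, J = cr$J,
               sensitivity = cr$sensitivity, specificity = cr$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$auroc > auroc_min, , drop = FALSE]
  out <- out[order(-out$auroc, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify by a cut-off and tabulate the 2x2 confusion
#'
#' The favorable stratum is the hi side of the cut-off for direction `"hi"`
#' and the lo side for `"lo"`; a value exactly equal to the cut-off is
#' assigned to the favorable side. Cells are `a` (favorable responders),
#' `b` (favorable non-responders), `c` (unfavorable responders), `d`
#' (unfavorable non-responders); PPV = a/(a+b), NPV = d/(c+d). An empty
#' stratum leaves the corresponding predictive value missing.
#'
#' @param levels marker values.
#' @param cutoff a `cutoff_result` (or list with `direction` and `cutoff`).
#' @param responder_flags logical labels.
#' @return list with `table` (named vector a, b, c, d), `ppv`, `npv` and
#'   `favorable` (logical membership vector).
#' @export
#' @examples
#' cr <- list(direction = "hi", cutoff = 5)
#' stratify_and_confusion(c(6, 7, 4, 3), cr, c(TRUE, TRUE, FALSE, FALSE))
stratify_and_confusion <- function(levels, cutoff, responder_flags) {
  .assert(!is.na(cutoff$direction), "cut-off has no defined direction")
  y <- as.logical(responder_flags)
  fav <- if (cutoff$direction == "hi") levels >= cutoff$cutoff
         else levels <= cutoff$cutoff
  a <- sum(fav & y); b <- sum(fav & !y)
  c_ <- sum(!fav & y); d <- sum(!fav & !y)
  list(table = c(a = a, b = b, c = c_, d = d),
       ppv = if (a + b > 0) a / (a + b) else NA_real_,
       npv = if (c_ + d > 0) d / (c_ + d) else NA_real_,
       favorable = fav)
}

.check_table <- function(table) {
  tab <- unlist(table)[c("a", "b", "c", "d")]
  if (anyNA(tab)) tab <- unlist(table)[1:4]
  .assert(length(tab) == 4 && all(is.finite(tab)) && all(tab >= 0) &&
            all(tab == round(tab)),
          "a 2x2 table of non-negative integer counts (a, b, c, d) is required")
  stats::setNames(as.numeric(tab), c("a", "b", "c", "d"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Standard two-sided convention: the p-value sums the hypergeometric
#' probabilities (margins fixed) of every table at most as probable as the
#' observed one. Computed with [stats::fisher.test()].
#'
#' @param table 2x2 counts `c(a, b, c, d)` (rows: favorable/unfavorable,
#'   columns: responder/non-responder).
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact(c(4, 0, 1, 15))  # ~0.00103
fisher_exact <- function(table) {
  tab <- .check_table(table)
  stats::fisher.test(matrix(tab, 2, 2, byrow = TRUE))$p.value
}

#' Odds ratio with the Haldane-Anscombe zero-cell correction
#'
#' If any cell of the 2x2 table is zero, 0.5 is added to all four cells
#' before forming the cross-ratio OR = a'd'/(b'c'). The 95% CI is the Wald
#' interval on the log odds ratio, SE = sqrt(sum of reciprocal corrected
#' cells), using the exact normal 0.975 quantile (1.959964...). The p-value
#' is the two-sided Fisher exact test on the *uncorrected* table; the
#' correction affects only the OR and its CI.
#'
#' The OR is undefined when a margin is empty (no responders or no
#' non-responders at all); this raises an error.
#'
#' @inheritParams fisher_exact
#' @param conf_level confidence level (default 0.95).
#' @return list with `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `corrected`.
#' @export
#' @examples
#' odds_ratio_ha(c(4, 0, 1, 15))  # OR 93.0, CI [3.2, 2699.7]
#' odds_ratio_ha(c(4, 1, 1, 14))  # OR 56.0, CI [2.8, 1109.4], uncorrected
odds_ratio_ha <- function(table, conf_level = 0.95) {
  tab <- .check_table(table)
  .assert(tab["a"] + tab["c"] > 0 && tab["b"] + tab["d"] > 0,
          "odds ratio undefined: a responder and a non-responder margin are required")
  corrected <- any(tab == 0)
  p <- fisher_exact(tab)
  if (corrected) tab <- tab + 0.5
  or <- unname(tab["a"] * tab["d"] / (tab["b"] * tab["c"]))
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = p,
       corrected = corrected)
}

#' Dual-endpoint benefit indicator
#'
#' A stratum shows treatment benefit iff the between-arm (active vs placebo)
#' p-values for both the EASI and the IGA percent-change contrasts are
#' strictly below 0.05. Missing p-values (e.g. a stratum lacking one arm)
#' give `FALSE`.
#'
#' @param delta_easi_p,delta_iga_p p-values in \[0, 1\] (or NA).
#' @return logical flag.
#' @export
#' @examples
#' benefit_indicator(0.003, 0.004)  # TRUE
#' benefit_indicator(0.05, 0.01)    # FALSE (strict)
benefit_indicator <- function(delta_easi_p, delta_iga_p) {
  .assert(all(c(delta_easi_p, delta_iga_p) >= 0 &
                c(delta_easi_p, delta_iga_p) <= 1, na.rm = TRUE),
          "p-values must lie in [0, 1]")
  isTRUE(delta_easi_p < 0.05) && isTRUE(delta_iga_p < 0.05)
}

#' Per-stratum clinical report for one marker
#'
#' Builds the row a stratified-markers table is made of: within the
#' favorable stratum, the active-vs-placebo contrasts of week-4 percent
#' change in EASI and IGA; the stratum's share of the biomarker analysis set
#' (%BAS); the marker's AUROC against responder status within the active arm
#' with a rank-sum significance p; PPV/NPV from the active-arm confusion
#' table; and the benefit indicator. A stratum lacking either arm yields
#' missing contrasts and benefit `FALSE`.
#'
#' @param cohort clinical table (rows define the analysis set).
#' @param endpoints endpoint table from [compute_endpoints()], aligned by
#'   `patient_id`.
#' @param levels marker values named by `patient_id` (or aligned with
#'   `cohort` rows).
#' @param cutoff a `cutoff_result` with defined direction.
#' @param active_arm,placebo_arm arm labels contrasted within the stratum.
#' @param var_equal passed to [between_arm_contrast()].
#' @return list of class `stratum_report`.
#' @export
stratum_report <- function(cohort, endpoints, levels, cutoff,
                           active_arm = "high_dose", placebo_arm = "placebo",
                           var_equal = FALSE) {
  .assert(!is.na(cutoff$direction), "cut-off has no defined direction")
  if (!is.null(names(levels))) levels <- levels[cohort$patient_id]
  .assert(length(levels) == nrow(cohort),
          "levels must align with (or be named by) the cohort")
  ep <- endpoints[match(cohort$patient_id, endpoints$patient_id), ]

  fav <- if (cutoff$direction == "hi") levels >= cutoff$cutoff
         else levels <= cutoff$cutoff
  pct_bas <- 100 * sum(fav) / nrow(cohort)

  contrast_in <- function(col) {
    act <- ep[[col]][fav & cohort$arm == active_arm]
    pla <- ep[[col]][fav & cohort$arm == placebo_arm]
    if (sum(!is.na(act)) < 2 || sum(!is.na(pla)) < 2)
      return(list(mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p_value = NA_real_, test_used = "t",
                  n_per_group = c(active = sum(!is.na(act)),
                                  placebo = sum(!is.na(pla)))))
    between_arm_contrast(act, pla, var_equal = var_equal)
  }
  d_easi <- contrast_in("pct_easi_wk4")
  d_iga <- contrast_in("pct_iga_wk4")

  act_rows <- cohort$arm == active_arm & !is.na(ep$easi50_wk4)
  auc <- NA_real_; auc_p <- NA_real_; ppv <- NA_real_; npv <- NA_real_
  conf <- NULL
  if (any(ep$easi50_wk4[act_rows]) && any(!ep$easi50_wk4[act_rows])) {
    auc <- max(auroc(levels[act_rows], ep$easi50_wk4[act_rows]),
               1 - auroc(levels[act_rows], ep$easi50_wk4[act_rows]))
    auc_p <- suppressWarnings(
      stats::wilcox.test(levels[act_rows][ep$easi50_wk4[act_rows]],
                         levels[act_rows][!ep$easi50_wk4[act_rows]])$p.value)
    conf <- stratify_and_confusion(levels[act_rows], cutoff,
                                   ep$easi50_wk4[act_rows])
    ppv <- conf$ppv; npv <- conf$npv
  }

  structure(list(
    direction = cutoff$direction, cutoff = cutoff$cutoff,
    delta_easi = d_easi, delta_iga = d_iga,
    pct_bas = pct_bas, auroc = auc, auroc_p = auc_p,
    ppv = ppv, npv = npv, confusion = conf,
    benefit = benefit_indicator(d_easi$p_value, d_iga$p_value)),
    class = "stratum_report")
}

#' Stratified-marker summary table
#'
#' One row per selected protein: the favorable-stratum label
#' (`<id>^hi`/`<id>^lo`), the EASI and IGA between-arm contrasts with CIs
#' and p-values, %BAS, AUROC and its p, PPV, NPV, the odds ratio with
#' Haldane-Anscombe handling and Fisher p on the active-arm confusion table,
#' and the benefit flag.
#'
#' @param cohort,endpoints as in [stratum_report()].
#' @param matrix patients x proteins abundance matrix (rows named by
#'   patient id, covering the cohort).
#' @param deps selection table from [select_deps()].
#' @inheritParams stratum_report
#' @return data.frame, one row per marker.
#' @export
marker_table <- function(cohort, endpoints, matrix, deps,
                         active_arm = "high_dose", placebo_arm = "placebo",
                         var_equal = FALSE) {
  .assert(all(cohort$patient_id %in% rownames(matrix)),
          "matrix must cover every cohort patient")
  rows <- lapply(seq_len(nrow(deps)), function(i) {
    d <- deps[i, ]
    cr <- list(direction = d$direction, cutoff = d$cutoff)
    lv <- matrix[cohort$patient_id, d$protein_id]
    names(lv) <- cohort$patient_id
    rp <- stratum_report(cohort, endpoints, lv, cr,
                         active_arm = active_arm, placebo_arm = placebo_arm,
                         var_equal = var_equal)
    or <- if (!is.null(rp$confusion) &&
              rp$confusion$table[["a"]] + rp$confusion$table[["c"]] > 0 &&
              rp$confusion$table[["b"]] + rp$confusion$table[["d"]] > 0)
      odds_ratio_ha(rp$confusion$table)
    else list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, corrected = NA)
    data.frame(
      stratum = paste0(d$protein_id, "^", d$direction),
      protein_id = d$protein_id, direction = d$direction, cutoff = d$cutoff,
      delta_easi = rp$delta_easi$mean_diff,
      delta_easi_ci_low = rp$delta_easi$ci_low,
      delta_easi_ci_high = rp$delta_easi$ci_high,
      delta_easi_p = rp$delta_easi$p_value,
      delta_iga = rp$delta_iga$mean_diff,
      delta_iga_ci_low = rp$delta_iga$ci_low,
      delta_iga_ci_high = rp$delta_iga$ci_high,
      delta_iga_p = rp$delta_iga$p_value,
      pct_bas = rp$pct_bas, auroc = rp$auroc, auroc_p = rp$auroc_p,
      ppv = rp$ppv, npv = rp$npv,
      odds_ratio = or$odds_ratio, or_ci_low = or$ci_low,
      or_ci_high = or$ci_high, or_p = or$p_value,
      benefit = rp$benefit,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
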