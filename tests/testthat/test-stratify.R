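# The single-marker stratification engine against brute-force oracles and
# the worked contingency examples.

test_that("auroc equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_error(auroc(1:4, rep(TRUE, 4)), "both classes")
  for (s in 1:200) {
    inst <- random_instance(sample(4:30, 1), seed = s)
    expect_equal(auroc(inst$levels, inst$labels),
                 oracle_auroc_pairs(inst$levels, inst$labels))
  }
})

test_that("auroc agrees with pROC on a tied instance", {
  skip_if_not_installed("pROC")
  inst <- random_instance(25, seed = 77)
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(inst$labels, inst$levels,
                                   direction = "<", quiet = TRUE))))
  expect_equal(auroc(inst$levels, inst$labels), ref)
})

test_that("Youden cut-off dominates a brute-force threshold scan", {
  cr <- youden_optimal_cutoff(c(1, 2, 10, 12), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cr$J, 1)
  expect_equal(cr$direction, "hi")
  expect_equal(cr$sensitivity + cr$specificity - 1, cr$J)

  for (s in 1:200) {
    inst <- random_instance(sample(4:25, 1), seed = 1000 + s)
    cr <- youden_optimal_cutoff(inst$levels, inst$labels)
    expect_equal(cr$J, oracle_youden_scan(inst$levels, inst$labels),
                 tolerance = 1e-10)
    expect_gte(cr$J, 0)
  }
})

test_that("sign-flipping the marker flips direction but preserves J", {
  inst <- random_instance(20, seed = 5)
  a <- youden_optimal_cutoff(inst$levels, inst$labels)
  b <- youden_optimal_cutoff(-inst$levels, inst$labels)
  expect_equal(a$J, b$J)
  if (!is.na(a$direction) && a$J > 0)
    expect_true(a$direction != b$direction)
  # constant marker: degenerate, J = 0, direction undefined
  cst <- youden_optimal_cutoff(rep(3, 8), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(cst$J, 0)
  expect_true(is.na(cst$direction))
})

test_that("DEP screen recovers a strong planted marker and ranks deterministically", {
  hits <- sapply(1:10, function(s) {
    cfg <- trial_config(n_per_arm = c(25, 3, 20), n_proteins = 40,
                        planted_markers = list(planted_marker("P0007", "lo", 0.3, 3)),
                        seed = s)
    co <- generate_cohort(cfg)
    qm <- generate_proteome(cfg, co)
    ep <- compute_endpoints(co)
    act <- co$arm == "high_dose"
    if (!any(ep$easi50_wk4[act]) || all(ep$easi50_wk4[act])) return(NA)
    deps <- select_deps(qm[act, ], ep$easi50_wk4[act])
    "P0007" %in% deps$protein_id &&
      deps$direction[deps$protein_id == "P0007"] == "lo"
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.8)

  # strictly-greater-than selection and ordering
  m <- cbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(1, 3, 2, 4))
  y <- c(FALSE, FALSE, TRUE, TRUE)
  deps <- select_deps(m, y, auroc_min = 0.99)
  expect_equal(deps$protein_id, c("A", "B"))  # both AUROC 1, tie by id
  expect_equal(nrow(select_deps(m, y, auroc_min = 1.0)), 0)
})

test_that("false-selection count on pure noise matches a permutation oracle", {
  n_act <- 20; n_prot <- 150
  count_sel <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(n_act * n_prot), n_act,
                dimnames = list(NULL, protein_ids(n_prot)))
    y <- rep(c(TRUE, FALSE), c(5, 15))
    nrow(select_deps(m, y))
  }
  obs <- sapply(1:30, count_sel)
  # oracle: same screen under label permutation of a fixed matrix
  set.seed(999)
  m <- matrix(rnorm(n_act * n_prot), n_act,
              dimnames = list(NULL, protein_ids(n_prot)))
  perm <- sapply(1:30, function(i) {
    y <- sample(rep(c(TRUE, FALSE), c(5, 15)))
    nrow(select_deps(m, y))
  })
  se <- sqrt(var(obs) / length(obs) + var(perm) / length(perm))
  expect_lt(abs(mean(obs) - mean(perm)), 2.5 * se)
})

test_that("confusion metrics reproduce the worked stratification tables", {
  # favorable stratum of 4 holding 4 of the 5 responders among 20 patients
  lv <- c(10, 9, 8, 7, rep(1, 16))
  y <- c(TRUE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 15))
  cr <- list(direction = "hi", cutoff = 5)
  sc <- stratify_and_confusion(lv, cr, y)
  expect_equal(unname(sc$table), c(4, 0, 1, 15))
  expect_equal(sc$ppv, 1.000)
  expect_equal(round(sc$npv, 3), 0.938)

  sc2 <- stratify_and_confusion(c(10, 9, 8, 7, 6, rep(1, 15)), cr,
                                c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                                  rep(FALSE, 14)))
  expect_equal(unname(sc2$table), c(4, 1, 1, 14))
  expect_equal(sc2$ppv, 0.800)
  expect_equal(round(sc2$npv, 3), 0.933)

  # boundary value goes to the favorable side
  sb <- stratify_and_confusion(c(5, 4), cr, c(TRUE, FALSE))
  expect_equal(unname(sb$table), c(1, 0, 0, 1))
  expect_equal(sb$ppv, 1)
  expect_equal(sb$npv, 1)
})

test_that("confusion metrics satisfy the algebraic identities", {
  for (s in 1:20) {
    inst <- random_instance(15, seed = 3000 + s)
    cr <- youden_optimal_cutoff(inst$levels, inst$labels)
    if (is.na(cr$direction)) next
    sc <- stratify_and_confusion(inst$levels, cr, inst$labels)
    tb <- sc$table
    expect_equal(sum(tb), 15)
    expect_equal(cr$sensitivity, tb[["a"]] / (tb[["a"]] + tb[["c"]]))
    expect_equal(cr$specificity, tb[["d"]] / (tb[["b"]] + tb[["d"]]))
    if (tb[["a"]] + tb[["b"]] > 0) expect_equal(sc$ppv, tb[["a"]] / (tb[["a"]] + tb[["b"]]))
  }
})

test_that("Haldane-Anscombe odds ratio reproduces the printed worked examples", {
  or1 <- odds_ratio_ha(c(4, 0, 1, 15))
  expect_true(or1$corrected)
  expect_equal(or1$odds_ratio, 93.0)
  expect_equal(round(or1$ci_low, 1), 3.2)
  expect_equal(round(or1$ci_high, 1), 2699.7)

  or2 <- odds_ratio_ha(c(4, 1, 1, 14))
  expect_false(or2$corrected)
  expect_equal(or2$odds_ratio, 56.0)
  expect_equal(round(or2$ci_low, 1), 2.8)
  expect_equal(round(or2$ci_high, 1), 1109.4)

  expect_equal(odds_ratio_ha(c(1, 1, 1, 1))$odds_ratio, 1.0)
  # an all-positive table is never corrected: plain cross-ratio
  expect_equal(odds_ratio_ha(c(3, 4, 5, 6))$odds_ratio, 3 * 6 / (4 * 5))
  expect_false(odds_ratio_ha(c(3, 4, 5, 6))$corrected)
  expect_error(odds_ratio_ha(c(0, 3, 0, 5)), "undefined")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(c(1, 1, 1, 1)), 1.0)
  expect_equal(fisher_exact(c(4, 0, 1, 15)), oracle_fisher_enum(4, 0, 1, 15))
  expect_equal(round(fisher_exact(c(4, 0, 1, 15)), 5), 0.00103)
  for (s in 1:50) {
    set.seed(s)
    tb <- as.vector(stats::rmultinom(1, sample(4:12, 1), rep(0.25, 4)))
    if (sum(tb[c(1, 3)]) == 0 || sum(tb[c(2, 4)]) == 0 ||
        sum(tb[1:2]) == 0 || sum(tb[3:4]) == 0) next
    expect_equal(fisher_exact(tb), oracle_fisher_enum(tb[1], tb[2], tb[3], tb[4]))
  }
})

test_that("benefit indicator requires both p-values strictly below 0.05", {
  expect_true(benefit_indicator(0.003, 0.004))
  expect_false(benefit_indicator(0.049, 0.051))
  expect_false(benefit_indicator(0.05, 0.01))
  expect_false(benefit_indicator(NA, 0.01))
  expect_error(benefit_indicator(1.2, 0.5), "\\[0, 1\\]")
})

test_that("stratum report assembles contrasts, %BAS and predictive values", {
  cfg <- trial_config(n_proteins = 30, seed = 12)
  co <- generate_cohort(cfg)
  ep <- compute_endpoints(co)
  lv <- setNames(generate_proteome(cfg, co)[, "P0001"], co$patient_id)
  cr <- youden_optimal_cutoff(lv[co$arm == "high_dose"],
                              ep$easi50_wk4[co$arm == "high_dose"])
  rp <- stratum_report(co, ep, lv, cr)
  expect_s3_class(rp, "stratum_report")
  expect_true(rp$pct_bas > 0 && rp$pct_bas <= 100)
  expect_equal(rp$benefit,
               benefit_indicator(rp$delta_easi$p_value, rp$delta_iga$p_value))
  # stratum = everyone
  all_cr <- list(direction = "hi", cutoff = min(lv))
  expect_equal(stratum_report(co, ep, lv, all_cr)$pct_bas, 100)
  # stratum missing the placebo arm: no contrast, benefit FALSE
  lv2 <- lv
  lv2[co$arm != "high_dose"] <- 0
  hi_cr <- list(direction = "hi", cutoff = 1e-6)
  lv3 <- lv2; lv3[co$arm == "high_dose"] <- 1
  rp3 <- stratum_report(co, ep, lv3, hi_cr)
  expect_true(is.na(rp3$delta_easi$p_value))
  expect_false(rp3$benefit)
})
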