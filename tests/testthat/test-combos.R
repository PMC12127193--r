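# Logistic combination models, predicted-probability thresholds and union
# strata.

make_logit_data <- function(n, beta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("m", seq_along(beta))))
  eta <- -0.3 + drop(x %*% beta)
  y <- runif(n) < plogis(eta)
  list(x = x, y = y)
}

test_that("IRLS fit matches glm on well-behaved data", {
  d <- make_logit_data(120, c(0.8, -0.6), seed = 2)
  fit <- fit_combo_logistic(d$x, d$y)
  ref <- glm(d$y ~ d$x, family = binomial)
  expect_false(fit$separation_detected)
  expect_true(fit$converged)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[-1, 2]),
               tolerance = 1e-4)
  expect_equal(fit$fitted_pp, unname(fitted(ref)), tolerance = 1e-6)
})

test_that("coefficients recover the simulating truth within 2 SE", {
  beta <- c(1.0, -0.7)
  d <- make_logit_data(500, beta, seed = 11)
  fit <- fit_combo_logistic(d$x, d$y)
  expect_true(all(abs(fit$coefficients - beta) <= 2 * fit$se))
})

test_that("separation is detected and the ridge fallback keeps pp usable", {
  y <- rep(c(FALSE, TRUE), each = 10)
  x <- cbind(m = as.numeric(y) + rnorm(20, 0, 1e-4))
  fit <- suppressWarnings(fit_combo_logistic(x, y))
  expect_true(fit$separation_detected)
  # pp remains monotone in the separating predictor
  expect_true(all(fit$fitted_pp[y] > max(fit$fitted_pp[!y]) - 1e-6))
  ppt <- pp_threshold(fit, y)
  expect_true(ppt$defined)
  expect_equal(ppt$auc, 1)
})

test_that("constant columns are dropped with a warning", {
  d <- make_logit_data(60, c(0.5), seed = 3)
  x <- cbind(d$x, const = 1)
  expect_warning(fit <- fit_combo_logistic(x, d$y), "constant")
  expect_equal(fit$protein_ids, "m1")
  expect_error(suppressWarnings(fit_combo_logistic(cbind(c = rep(2, 60)), d$y)),
               "no informative")
  expect_error(fit_combo_logistic(d$x, rep(TRUE, 60)), "both responders")
})

test_that("pp is invariant to affine rescaling of predictors", {
  d <- make_logit_data(150, c(0.6, -0.4), seed = 7)
  f1 <- fit_combo_logistic(d$x, d$y)
  x2 <- d$x
  x2[, 1] <- 1000 * x2[, 1] + 5
  x2[, 2] <- 0.01 * x2[, 2] - 3
  f2 <- fit_combo_logistic(x2, d$y)
  expect_equal(f1$fitted_pp, f2$fitted_pp, tolerance = 1e-6)
})

test_that("log-transform flags act on the design and predict_pp round-trips", {
  set.seed(9)
  x <- cbind(m1 = exp(rnorm(80)), m2 = rnorm(80))
  y <- runif(80) < plogis(log(x[, 1]))
  fit <- fit_combo_logistic(x, y, log_transform = c(TRUE, FALSE))
  ref <- glm(y ~ log(x[, 1]) + x[, 2], family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]), tolerance = 1e-5)
  expect_equal(predict_pp(fit, x), fit$fitted_pp, tolerance = 1e-10)
  expect_error(fit_combo_logistic(cbind(m1 = c(-1, rep(1, 19))),
                                  rep(c(TRUE, FALSE), 10), log_transform = TRUE),
               "non-positive")
})

test_that("pp threshold uses the midpoint rule and reports the pp AUC", {
  # pp identical to the labels: midpoint rule must return 0.5, AUC 1
  model <- structure(list(fitted_pp = c(1, 1, 0, 0, 0)), class = "combo_model")
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  ppt <- pp_threshold(model, y)
  expect_equal(ppt$pp_cutoff, 0.5)
  expect_equal(ppt$auc, 1)
  # degenerate pp
  flat <- structure(list(fitted_pp = rep(0.4, 5)), class = "combo_model")
  expect_false(pp_threshold(flat, y)$defined)
})

test_that("single-predictor pp ranking equals the marker ranking", {
  set.seed(21)
  x <- cbind(m = rnorm(40, 5, 2))
  y <- runif(40) < plogis(1.2 * (x[, 1] - 5))
  fit <- fit_combo_logistic(x, y)
  expect_equal(auroc(fit$fitted_pp, y),
               max(auroc(x[, 1], y), 1 - auroc(x[, 1], y)))
  # the logistic link is monotone: pp stratification = level stratification
  ppt <- pp_threshold(fit, y)
  pp_strat <- fit$fitted_pp >= ppt$pp_cutoff
  cr <- youden_optimal_cutoff(x[, 1], y)
  lvl_strat <- if (cr$direction == "hi") x[, 1] >= cr$cutoff else x[, 1] <= cr$cutoff
  expect_equal(pp_strat, lvl_strat)
})

test_that("union stratification is a clause-wise OR and is monotone", {
  m <- cbind(P1 = c(1, 5, 9, 2), P2 = c(9, 5, 1, 8))
  rownames(m) <- paste0("S", 1:4)
  r1 <- data.frame(protein_id = "P1", side = "hi", cutoff = 8)
  r2 <- data.frame(protein_id = "P2", side = "lo", cutoff = 2)
  expect_equal(unname(union_stratify(m, r1)), c(FALSE, FALSE, TRUE, FALSE))
  both <- union_stratify(m, rbind(r1, r2))
  expect_equal(unname(both), c(FALSE, FALSE, TRUE, FALSE))  # same patient twice
  # disjoint clauses: sizes add
  r3 <- data.frame(protein_id = "P2", side = "hi", cutoff = 8.5)
  expect_equal(sum(union_stratify(m, rbind(r1, r3))), 2)
  # adding a clause never shrinks the stratum
  for (s in 1:10) {
    set.seed(s)
    mm <- matrix(runif(60), 20, dimnames = list(NULL, c("A", "B", "C")))
    ra <- data.frame(protein_id = "A", side = "hi", cutoff = runif(1))
    rb <- rbind(ra, data.frame(protein_id = "B", side = "lo", cutoff = runif(1)))
    expect_true(all(union_stratify(mm, ra) <= union_stratify(mm, rb)))
  }
})

test_that("combination enumeration reports every pair deterministically", {
  cfg <- trial_config(n_per_arm = c(25, 3, 20), n_proteins = 20, seed = 31)
  co <- generate_cohort(cfg)
  qm <- generate_proteome(cfg, co)
  ep <- compute_endpoints(co)
  act <- co$arm == "high_dose"
  deps <- head(select_deps(qm[act, ], ep$easi50_wk4[act], auroc_min = 0.6), 5)
  tab <- enumerate_and_report(qm, deps, ep, co, k = 2)
  expect_equal(nrow(tab), choose(nrow(deps), 2))
  expect_true(!is.unsorted(tab$or_p, na.rm = TRUE))
  # k = 1 degenerates to the single-marker confusion metrics
  tab1 <- enumerate_and_report(qm, deps[1, ], ep, co, k = 1)
  single <- marker_table(co, ep, qm, deps[1, ])
  expect_equal(tab1$ppv, single$ppv)
  expect_equal(tab1$npv, single$npv)
  expect_equal(tab1$odds_ratio, single$odds_ratio)
  expect_equal(tab1$pct_bas, single$pct_bas)
  # enumeration budget is enforced with guidance
  expect_error(enumerate_and_report(qm, deps, ep, co, k = 2, max_combos = 3),
               "budget")
})
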