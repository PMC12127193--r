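# Multi-marker combination search: logistic benefit models on 2-3 baseline
# markers, Youden-optimal predicted-probability (pp) thresholds, boolean
# union strata built from single-marker cut-offs, and combination summary
# tables.

# Design matrix for a combo model: optional natural-log transform per marker,
# constant columns dropped with a warning (rank deficiency).
.combo_design <- function(x, log_transform) {
  x <- as.matrix(x)
  .assert(!is.null(colnames(x)), "marker columns must be named")
  log_transform <- rep_len(log_transform, ncol(x))
  for (j in which(log_transform)) {
    .assert(all(x[, j] > 0), sprintf(
      "log transform requested for %s but it has non-positive values",
      colnames(x)[j]))
    x[, j] <- log(x[, j])
  }
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant marker column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    log_transform <- log_transform[!const]
  }
  .assert(ncol(x) >= 1, "no informative marker columns remain")
  list(x = x, log_transform = log_transform)
}

# One IRLS pass to convergence on the log-likelihood; `lambda` adds an L2
# penalty on the (standardized-scale) slopes, never the intercept.
.irls_logistic <- function(X, y, lambda = 0, tol = 1e-8, maxit = 100) {
  n <- nrow(X); k <- ncol(X)
  beta <- rep(0, k)
  ll_old <- -Inf
  converged <- FALSE
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X + pen, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      lambda / 2 * sum(beta[-1]^2)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(beta = beta, converged = converged, fitted = stats::plogis(drop(X %*% beta)))
}

#' Fit a logistic benefit model on baseline markers
#'
#' Maximum-likelihood logistic regression of responder status on 1-3
#' baseline marker levels, fitted by iteratively reweighted least squares
#' (convergence tolerance 1e-8 on the log-likelihood, at most 100
#' iterations). With the small samples typical of a biomarker analysis set,
#' strong markers frequently separate the classes perfectly; separation is
#' detected (non-convergence or diverging standardized coefficients) and the
#' model is then refitted with a tiny ridge penalty (`ridge`, default 1e-4,
#' applied on the standardized-predictor scale) so predicted probabilities
#' remain usable for thresholding.
#'
#' @param x matrix (patients x markers) of baseline levels, columns named.
#' @param responder_flags logical labels; both classes required.
#' @param log_transform logical per marker: natural-log transform before
#'   inclusion (the convention for right-skewed abundances).
#' @param ridge ridge penalty used only in the separation fallback.
#' @param tol,maxit IRLS convergence controls.
#' @return list of class `combo_model` with `protein_ids`, `log_transform`,
#'   `intercept`, `coefficients` (log-odds per unit of the possibly
#'   log-transformed marker), `fitted_pp`, `converged`,
#'   `separation_detected`, and standard errors `se` (from the unpenalized
#'   information when available).
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(m1 = rnorm(60), m2 = rnorm(60))
#' y <- runif(60) < plogis(x[, 1] - x[, 2])
#' fit_combo_logistic(x, y)$coefficients
fit_combo_logistic <- function(x, responder_flags, log_transform = FALSE,
                               ridge = 1e-4, tol = 1e-8, maxit = 100) {
  y <- as.numeric(as.logical(responder_flags))
  .assert(any(y == 1) && any(y == 0),
          "both responders and non-responders are required")
  d <- .combo_design(x, log_transform)
  .assert(nrow(d$x) == length(y), "labels must align with rows")
  .assert(length(y) >= ncol(d$x) + 2,
          "need at least predictors + 2 observations")
  # standardize for numerical stability; coefficients mapped back after
  ctr <- colMeans(d$x)
  scl <- apply(d$x, 2, stats::sd)
  Xs <- scale(d$x, center = ctr, scale = scl)
  X <- cbind(1, Xs)

  fit <- .irls_logistic(X, y, lambda = 0, tol = tol, maxit = maxit)
  separated <- !fit$converged || max(abs(fit$beta[-1])) > 20
  se_std <- rep(NA_real_, ncol(X))
  if (!separated) {
    mu <- fit$fitted
    w <- mu * (1 - mu)
    info <- t(X * w) %*% X
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cov)) se_std <- sqrt(diag(cov))
  } else {
    fit <- .irls_logistic(X, y, lambda = ridge, tol = tol, maxit = maxit)
  }
  b_std <- fit$beta
  slopes <- b_std[-1] / scl
  intercept <- b_std[1] - sum(b_std[-1] * ctr / scl)
  se <- c(NA_real_, se_std[-1] / scl)

  structure(list(protein_ids = colnames(d$x),
                 log_transform = d$log_transform,
                 intercept = unname(intercept),
                 coefficients = stats::setNames(slopes, colnames(d$x)),
                 se = stats::setNames(se[-1], colnames(d$x)),
                 fitted_pp = unname(fit$fitted),
                 converged = fit$converged,
                 separation_detected = separated),
            class = "combo_model")
}

#' Predicted probabilities from a combo model
#'
#' @param model a `combo_model`.
#' @param newx matrix of marker levels with the model's columns.
#' @return vector of predicted response probabilities.
#' @export
predict_pp <- function(model, newx) {
  newx <- as.matrix(newx)[, model$protein_ids, drop = FALSE]
  for (j in which(model$log_transform)) newx[, j] <- log(newx[, j])
  stats::plogis(model$intercept + drop(newx %*% model$coefficients))
}

#' Youden-optimal threshold on predicted probabilities
#'
#' Computes the ROC AUC of the model's fitted predicted probabilities (pp)
#' against the responder labels and the pp threshold maximizing the Youden
#' index, using the same midpoint candidate rule as the single-marker
#' cut-off search. Degenerate pp (all equal) yields an undefined threshold.
#'
#' @param model a fitted `combo_model`.
#' @param responder_flags the labels the model was fitted to.
#' @return list with `pp_cutoff` (NA if undefined), `auc`, `direction`,
#'   `defined`.
#' @export
pp_threshold <- function(model, responder_flags) {
  pp <- model$fitted_pp
  y <- as.logical(responder_flags)
  if (length(unique(pp)) < 2)
    return(list(pp_cutoff = NA_real_, auc = 0.5, direction = NA_character_,
                defined = FALSE))
  cr <- youden_optimal_cutoff(pp, y)
  list(pp_cutoff = cr$cutoff, auc = auroc(pp, y), direction = cr$direction,
       defined = TRUE)
}

#' Boolean-union stratification from single-marker cut-offs
#'
#' A patient belongs to the favorable stratum iff ANY clause holds: for side
#' `"hi"`, marker level >= cut-off; for side `"lo"`, level <= cut-off.
#' Clause cut-offs are the single-marker Youden cut-offs.
#'
#' @param matrix patients x proteins abundance matrix.
#' @param rule data.frame with columns `protein_id`, `side` (`"hi"`/`"lo"`),
#'   `cutoff`; one row per clause.
#' @return logical membership vector (named by row names of `matrix`).
#' @export
#' @examples
#' m <- cbind(P1 = c(1, 5, 9), P2 = c(9, 5, 1))
#' rule <- data.frame(protein_id = c("P1", "P2"), side = c("hi", "lo"),
#'                    cutoff = c(8, 2))
#' union_stratify(m, rule)
union_stratify <- function(matrix, rule) {
  .assert(is.data.frame(rule) && nrow(rule) >= 1 &&
            all(c("protein_id", "side", "cutoff") %in% names(rule)),
          "rule needs >= 1 clause with protein_id, side and cutoff")
  .assert(all(rule$side %in% c("hi", "lo")), "clause side must be hi or lo")
  .assert(all(rule$protein_id %in% colnames(matrix)),
          "every clause protein must be a matrix column")
  fav <- rep(FALSE, nrow(matrix))
  for (i in seq_len(nrow(rule))) {
    lv <- matrix[, rule$protein_id[i]]
    fav <- fav | if (rule$side[i] == "hi") lv >= rule$cutoff[i]
                 else lv <= rule$cutoff[i]
  }
  stats::setNames(fav, rownames(matrix))
}

#' Enumerate k-marker combinations and report each one
#'
#' For every k-subset of the selected proteins (k = 1, 2 or 3), fits a
#' logistic combination on active-arm baseline levels, finds the
#' Youden-optimal pp threshold, builds the boolean-union stratum from the
#' single-marker cut-offs, and emits one summary row: the stratum label
#' (e.g. `"P0001^hi or P0002^lo"`), EASI and IGA between-arm contrasts
#' within the union stratum, %BAS, the pp AUC, PPV/NPV and the odds ratio
#' (with zero-cell correction and Fisher p) from the active-arm union
#' confusion. Rows are ordered by OR p-value, then AUC descending, then
#' label, so the ranking is deterministic.
#'
#' @param matrix patients x proteins abundance matrix covering the cohort.
#' @param deps selection table from [select_deps()] (supplies the clause
#'   sides and cut-offs).
#' @param endpoints,cohort as in [stratum_report()].
#' @param k subset size, 1-3.
#' @param log_transform named logical vector: markers to log-transform in
#'   the logistic fit (defaults to none).
#' @param max_combos refuse to enumerate more than this many subsets
#'   (guards the cubic blow-up of a 3-way search; shortlist `deps` instead).
#' @param active_arm,placebo_arm,var_equal as in [stratum_report()].
#' @return data.frame, one row per combination.
#' @export
enumerate_and_report <- function(matrix, deps, endpoints, cohort, k = 2,
                                 log_transform = NULL, max_combos = 2000,
                                 active_arm = "high_dose",
                                 placebo_arm = "placebo", var_equal = FALSE) {
  .assert(k %in% 1:3, "k must be 1, 2 or 3")
  m <- nrow(deps)
  .assert(m >= k, "fewer selected proteins than the requested subset size")
  n_comb <- choose(m, k)
  .assert(n_comb <= max_combos, sprintf(
    "%d combinations exceed the budget of %d; shortlist the DEP table or raise max_combos",
    n_comb, max_combos))
  subsets <- utils::combn(seq_len(m), k, simplify = FALSE)

  ep <- endpoints[match(cohort$patient_id, endpoints$patient_id), ]
  act <- cohort$arm == active_arm & !is.na(ep$easi50_wk4)
  y_act <- ep$easi50_wk4[act]
  mat_co <- matrix[cohort$patient_id, , drop = FALSE]

  rows <- lapply(subsets, function(idx) {
    d <- deps[idx, ]
    lt <- if (is.null(log_transform)) rep(FALSE, k)
          else unname(log_transform[d$protein_id]) %in% TRUE
    x_act <- mat_co[act, d$protein_id, drop = FALSE]
    model <- tryCatch(
      fit_combo_logistic(x_act, y_act, log_transform = lt),
      error = function(e) NULL, warning = function(w) NULL)
    ppt <- if (is.null(model)) list(auc = NA_real_, pp_cutoff = NA_real_,
                                    defined = FALSE)
           else pp_threshold(model, y_act)

    rule <- data.frame(protein_id = d$protein_id, side = d$direction,
                       cutoff = d$cutoff, stringsAsFactors = FALSE)
    fav <- union_stratify(mat_co, rule)
    label <- paste(paste0(d$protein_id, "^", d$direction), collapse = " or ")

    contrast_in <- function(col) {
      a <- ep[[col]][fav & cohort$arm == active_arm]
      p <- ep[[col]][fav & cohort$arm == placebo_arm]
      if (sum(!is.na(a)) < 2 || sum(!is.na(p)) < 2)
        return(list(mean_diff = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_))
      between_arm_contrast(a, p, var_equal = var_equal)
    }
    d_easi <- contrast_in("pct_easi_wk4")
    d_iga <- contrast_in("pct_iga_wk4")

    fa <- fav[act]
    a_ <- sum(fa & y_act); b_ <- sum(fa & !y_act)
    c_ <- sum(!fa & y_act); d_ <- sum(!fa & !y_act)
    or <- if ((a_ + c_ > 0) && (b_ + d_ > 0))
      odds_ratio_ha(c(a = a_, b = b_, c = c_, d = d_))
    else list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, corrected = NA)

    data.frame(
      stratum = label,
      proteins = paste(d$protein_id, collapse = "+"),
      delta_easi = d_easi$mean_diff, delta_easi_ci_low = d_easi$ci_low,
      delta_easi_ci_high = d_easi$ci_high, delta_easi_p = d_easi$p_value,
      delta_iga = d_iga$mean_diff, delta_iga_ci_low = d_iga$ci_low,
      delta_iga_ci_high = d_iga$ci_high, delta_iga_p = d_iga$p_value,
      pct_bas = 100 * sum(fav) / nrow(cohort),
      auc = ppt$auc, pp_cutoff = ppt$pp_cutoff,
      ppv = if (a_ + b_ > 0) a_ / (a_ + b_) else NA_real_,
      npv = if (c_ + d_ > 0) d_ / (c_ + d_) else NA_real_,
      odds_ratio = or$odds_ratio, or_ci_low = or$ci_low,
      or_ci_high = or$ci_high, or_p = or$p_value,
      benefit = benefit_indicator(d_easi$p_value, d_iga$p_value),
      separation = if (is.null(model)) NA else model$separation_detected,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$or_p, -out$auc, out$stratum, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
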