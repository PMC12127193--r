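# Transition-level QC and absolute quantification for targeted MRM-MS with
# stable-isotope-labeled internal standards (SIS). The endogenous amount of a
# target is the peak area ratio (PAR, endogenous/SIS) times the spiked SIS
# amount; transitions are screened on SIS intensity, co-elution and peak
# symmetry, and calibration series on a PAR window and linearity.

#' Collision energy for a precursor ion
#'
#' Linear ramp in precursor m/z with charge-specific parameters:
#' `0.031 * mz + 1` for doubly charged and `0.036 * mz - 4.8` for triply
#' charged precursors. Other charge states raise an error rather than
#' silently defaulting.
#'
#' @param precursor_mz precursor m/z (> 0); vectorized.
#' @param charge precursor charge, 2 or 3; recycled against `precursor_mz`.
#' @return collision energy in volts.
#' @export
#' @examples
#' collision_energy(500, 2)  # 16.5
#' collision_energy(600, 3)  # 16.8
collision_energy <- function(precursor_mz, charge) {
  .assert(all(precursor_mz > 0), "precursor m/z must be positive")
  .assert(all(charge %in% c(2L, 3L)),
          "unsupported charge state: collision energy is defined for charge 2 or 3")
  ifelse(charge == 2, 0.031 * precursor_mz + 1, 0.036 * precursor_mz - 4.8)
}

#' Filter transition records on intensity, co-elution and peak symmetry
#'
#' A record is kept iff its SIS peak intensity is at least 100 counts
#' (strictly below 100 is excluded), the SIS peak co-elutes with the
#' endogenous peptide, and the elution peak is symmetric. Each excluded
#' record is attributed to the first failing rule in that order, so the
#' per-rule tally is deterministic.
#'
#' @param records data.frame with columns `sis_intensity`, `coeluted`,
#'   `symmetric` (0/1 or logical).
#' @param min_intensity intensity threshold in counts (default 100).
#' @return list with `kept` (the surviving rows) and `tally` (named counts of
#'   exclusions: `low_intensity`, `not_coeluted`, `asymmetric`).
#' @export
#' @examples
#' rpt <- generate_transition_report(n_clean = 2, n_low_intensity = 1, seed = 1)
#' filter_transitions(rpt)$tally
filter_transitions <- function(records, min_intensity = 100) {
  .assert(is.data.frame(records) &&
            all(c("sis_intensity", "coeluted", "symmetric") %in% names(records)),
          "records must have sis_intensity, coeluted and symmetric columns")
  .assert(all(records$sis_intensity >= 0), "intensities must be >= 0")
  low <- records$sis_intensity < min_intensity
  noco <- !low & !as.logical(records$coeluted)
  asym <- !low & !noco & !as.logical(records$symmetric)
  keep <- !(low | noco | asym)
  list(kept = records[keep, , drop = FALSE],
       tally = c(low_intensity = sum(low), not_coeluted = sum(noco),
                 asymmetric = sum(asym)))
}

#' Absolute quantification from PAR and spiked SIS amount
#'
#' Endogenous target amount (fmol) = PAR x SIS injected (fmol), exactly.
#'
#' @param par peak area ratio(s), endogenous / SIS; must be >= 0.
#' @param sis_injected spiked SIS amount(s) in fmol; must be > 0.
#' @return endogenous amount in fmol.
#' @export
#' @examples
#' quantify_fmol(0.5, 100)  # 50
quantify_fmol <- function(par, sis_injected) {
  .assert(all(par >= 0), "PAR must be non-negative")
  .assert(all(sis_injected > 0), "SIS injected amount must be positive")
  par * sis_injected
}

#' Calibration-series linearity check
#'
#' A peptide's spike series (50/100/200/400 fmol by default) passes iff every
#' PAR lies strictly inside (0.1, 1) and the squared Pearson correlation of
#' PAR against spike level is at least `r2_min`. A zero-variance PAR series
#' has undefined correlation and fails the R-squared criterion.
#'
#' @param par_at_level PAR at each spike level, or a data.frame with columns
#'   `spike_fmol` and `par` (one peptide).
#' @param levels spike levels in fmol, strictly increasing.
#' @param r2_min minimum squared correlation (default 0.9).
#' @return logical flag.
#' @export
#' @examples
#' linearity_pass(c(0.15, 0.3, 0.6, 0.95))          # TRUE
#' linearity_pass(c(0.1, 0.2, 0.4, 0.8))            # FALSE: 0.1 not inside
linearity_pass <- function(par_at_level, levels = c(50, 100, 200, 400),
                           r2_min = 0.9) {
  if (is.data.frame(par_at_level)) {
    ord <- order(par_at_level$spike_fmol)
    .assert(identical(as.numeric(par_at_level$spike_fmol[ord]), as.numeric(levels)),
            "series is missing a spike level")
    par_at_level <- par_at_level$par[ord]
  }
  .assert(length(par_at_level) == length(levels),
          "series is missing a spike level")
  .assert(all(diff(levels) > 0), "spike levels must be strictly increasing")
  .assert(all(is.finite(par_at_level)), "PAR values must be finite")
  if (!all(par_at_level > 0.1 & par_at_level < 1)) return(FALSE)
  if (stats::sd(par_at_level) == 0) return(FALSE)
  r2 <- stats::cor(par_at_level, levels)^2
  r2 >= r2_min
}

#' Apply the calibration-linearity filter to a transition report
#'
#' Convenience wrapper: splits a (QC-filtered) transition report by peptide
#' and keeps peptides whose complete spike series passes [linearity_pass()].
#'
#' @param records transition report rows (one row per peptide x spike level).
#' @inheritParams linearity_pass
#' @return character vector of passing peptide ids.
#' @export
linearity_filter <- function(records, levels = c(50, 100, 200, 400),
                             r2_min = 0.9) {
  by_pep <- split(records, records$peptide_id)
  ok <- vapply(by_pep, function(d) {
    if (nrow(d) != length(levels)) return(FALSE)
    linearity_pass(d[, c("spike_fmol", "par")], levels = levels, r2_min = r2_min)
  }, logical(1))
  names(by_pep)[ok]
}

#' Dynamic range of a quantification matrix in orders of magnitude
#'
#' The overall range is log10 of the ratio between the largest and smallest
#' per-protein median abundance; the per-protein spread is computed likewise
#' over patients. Only positive values enter the medians; proteins with no
#' positive value are excluded with a warning.
#'
#' @param matrix patients x proteins abundance matrix (fmol).
#' @return list with `overall` (scalar, orders of magnitude) and
#'   `per_protein` (named vector of within-protein spreads).
#' @export
#' @examples
#' m <- cbind(a = c(1, 1), b = c(1e7, 1e7))
#' dynamic_range_orders(m)$overall  # 7
dynamic_range_orders <- function(matrix) {
  .assert(is.matrix(matrix) && ncol(matrix) >= 1, "a matrix is required")
  pos_median <- apply(matrix, 2, function(x) {
    x <- x[is.finite(x) & x > 0]
    if (!length(x)) NA_real_ else stats::median(x)
  })
  if (anyNA(pos_median))
    warning(sum(is.na(pos_median)),
            " protein(s) without positive values excluded from dynamic range")
  med <- pos_median[!is.na(pos_median)]
  .assert(length(med) >= 1, "no protein has positive values")
  spread <- apply(matrix, 2, function(x) {
    x <- x[is.finite(x) & x > 0]
    if (!length(x)) NA_real_ else log10(max(x) / min(x))
  })
  list(overall = log10(max(med) / min(med)), per_protein = spread)
}
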