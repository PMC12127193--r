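# Seeded synthetic three-arm trial generator. The generator reproduces the
# statistical structure the downstream biomarker analysis assumes: stratified
# block randomization by site, a truncated-normal baseline severity score,
# percent-change outcomes whose distribution depends on arm and on a latent
# "marker-matched" stratum, and a log-normal plasma proteome in which planted
# markers separate the latent strata.

.ARMS <- c("placebo", "low_dose", "high_dose")

#' Describe a planted predictive marker
#'
#' A planted marker encodes the structure of a predictive biomarker: one side
#' of a cut-off (direction `"hi"` or `"lo"`) identifies a favorable stratum
#' that responds to active treatment. The latent stratum occupies
#' `favorable_fraction` of the cohort, and the marker's abundance is separated
#' between strata by `effect_size` standard deviations (on the log scale) in
#' the stated direction.
#'
#' @param protein_id protein identifier, e.g. `"P0001"`.
#' @param direction `"hi"` if high abundance predicts response, `"lo"` if low.
#' @param favorable_fraction proportion of the cohort in the favorable
#'   stratum, strictly between 0 and 1.
#' @param effect_size standardized mean separation between favorable and
#'   unfavorable strata (>= 0).
#' @return a `planted_marker` list.
#' @export
#' @examples
#' planted_marker("P0001", "hi", 0.20, 2.5)
planted_marker <- function(protein_id, direction = c("hi", "lo"),
                           favorable_fraction, effect_size) {
  direction <- match.arg(direction)
  .assert(is.character(protein_id) && length(protein_id) == 1,
          "protein_id must be a single string")
  .assert(is.numeric(favorable_fraction) && length(favorable_fraction) == 1 &&
            favorable_fraction > 0 && favorable_fraction < 1,
          "favorable_fraction must lie strictly in (0, 1)")
  .assert(is.numeric(effect_size) && length(effect_size) == 1 && effect_size >= 0,
          "effect_size must be >= 0")
  structure(list(protein_id = protein_id, direction = direction,
                 favorable_fraction = favorable_fraction,
                 effect_size = effect_size),
            class = "planted_marker")
}

#' Default planted markers
#'
#' Three markers mirroring the hi/lo/lo structure and stratum sizes typically
#' seen in a predictive-biomarker screen: a high-abundance marker covering
#' 20% of the cohort, and two low-abundance markers covering 37% and 54%.
#' Strata are nested through a shared latent uniform, so the 20% stratum is
#' the treatment-responsive core contained in every favorable stratum.
#'
#' @return list of [planted_marker()] objects.
#' @export
default_planted_markers <- function() {
  list(planted_marker("P0001", "hi", 0.20, 2.5),
       planted_marker("P0002", "lo", 0.37, 2.0),
       planted_marker("P0003", "lo", 0.54, 1.8))
}

#' Configure a synthetic trial
#'
#' Defaults describe a three-arm topical-drug trial in mild-to-moderate
#' atopic dermatitis: 27/27/26 patients over 5 sites randomized in blocks of
#' 3 and 6, baseline EASI 8.27 +/- 4.36 truncated to (0, 72], baseline IGA
#' grade 3 in 40.5% of patients (grade 2 otherwise), and 469 quantified
#' plasma proteins. Week-4 percent change in EASI is drawn from a normal
#' distribution per (arm, marker-match) cell; the cell means are calibrated
#' so arm-level means approximate -2.9% (placebo), -12.2% (low dose) and
#' -11.9% (high dose), with the high-dose benefit concentrated in the
#' marker-matched stratum.
#'
#' @param n_per_arm named integer vector of arm sizes
#'   (placebo/low_dose/high_dose).
#' @param n_sites number of recruiting sites.
#' @param block_sizes permuted-block sizes; multiples of the number of arms.
#' @param baseline_easi_mean,baseline_easi_sd truncated-normal parameters for
#'   baseline EASI (score units).
#' @param iga3_fraction probability of baseline IGA grade 3 (else grade 2).
#' @param n_proteins number of quantified proteins.
#' @param planted_markers list of [planted_marker()]; may be empty.
#' @param response_rates list with elements `placebo`, `low_dose`,
#'   `active_nonmatched`, `active_matched`, each `c(mean = , sd = )` percent
#'   change at week 4.
#' @param iga_easi_correlation coupling between the EASI and IGA percent
#'   responses through a single latent responsiveness variable, in \[0, 1\].
#' @param dropout named per-arm probability that all post-baseline efficacy
#'   assessments are missing.
#' @param biomarker_consent_rate probability a patient consents to plasma
#'   biomarker analysis.
#' @param seed integer master seed; identical config + seed gives
#'   byte-identical output.
#' @return a validated `trial_config` list.
#' @export
#' @examples
#' cfg <- trial_config(seed = 7)
#' cfg$n_per_arm
trial_config <- function(n_per_arm = c(placebo = 27L, low_dose = 27L, high_dose = 26L),
                         n_sites = 5L,
                         block_sizes = c(3L, 6L),
                         baseline_easi_mean = 8.27,
                         baseline_easi_sd = 4.36,
                         iga3_fraction = 0.405,
                         n_proteins = 469L,
                         planted_markers = default_planted_markers(),
                         response_rates = list(
                           placebo = c(mean = -2.9, sd = 40),
                           low_dose = c(mean = -12.2, sd = 40),
                           active_nonmatched = c(mean = 4, sd = 35),
                           active_matched = c(mean = -75, sd = 25)),
                         iga_easi_correlation = 0.6,
                         dropout = c(placebo = 0, low_dose = 0, high_dose = 0),
                         biomarker_consent_rate = 0.9,
                         seed = 1L) {
  n_per_arm <- as.integer(n_per_arm)
  if (is.null(names(n_per_arm)) || !all(names(n_per_arm) == .ARMS))
    names(n_per_arm) <- .ARMS
  .assert(length(n_per_arm) == 3 && all(n_per_arm >= 2),
          "n_per_arm must give >= 2 patients in each of the three arms")
  .assert(iga3_fraction >= 0 && iga3_fraction <= 1,
          "iga3_fraction must lie in [0, 1]")
  .assert(all(block_sizes %% length(.ARMS) == 0),
          "block sizes must be multiples of the number of arms (3)")
  .assert(baseline_easi_mean > 0 && baseline_easi_sd > 0,
          "baseline EASI mean and sd must be positive")
  .assert(n_proteins >= 1, "n_proteins must be >= 1")
  .assert(all(vapply(planted_markers, inherits, logical(1), "planted_marker")),
          "planted_markers must be a list of planted_marker objects")
  needed <- c("placebo", "low_dose", "active_nonmatched", "active_matched")
  .assert(all(needed %in% names(response_rates)),
          "response_rates must name placebo, low_dose, active_nonmatched, active_matched")
  for (nm in needed)
    .assert(all(c("mean", "sd") %in% names(response_rates[[nm]])) &&
              response_rates[[nm]]["sd"] >= 0,
            sprintf("response_rates$%s needs a mean and a non-negative sd", nm))
  .assert(iga_easi_correlation >= 0 && iga_easi_correlation <= 1,
          "iga_easi_correlation must lie in [0, 1]")
  dropout <- rep_len(dropout, 3); names(dropout) <- .ARMS
  .assert(all(dropout >= 0 & dropout <= 1), "dropout probabilities must lie in [0, 1]")
  .assert(biomarker_consent_rate >= 0 && biomarker_consent_rate <= 1,
          "biomarker_consent_rate must lie in [0, 1]")
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single integer")
  ids <- protein_ids(n_proteins)
  for (m in planted_markers)
    .assert(m$protein_id %in% ids,
            sprintf("planted protein %s is outside the %d generated proteins",
                    m$protein_id, n_proteins))
  structure(list(n_per_arm = n_per_arm, n_sites = as.integer(n_sites),
                 block_sizes = as.integer(block_sizes),
                 baseline_easi_mean = baseline_easi_mean,
                 baseline_easi_sd = baseline_easi_sd,
                 iga3_fraction = iga3_fraction,
                 n_proteins = as.integer(n_proteins),
                 planted_markers = planted_markers,
                 response_rates = response_rates,
                 iga_easi_correlation = iga_easi_correlation,
                 dropout = dropout,
                 biomarker_consent_rate = biomarker_consent_rate,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Protein identifiers used by the generator
#' @param n number of proteins.
#' @return character vector `P0001`, `P0002`, ...
#' @export
protein_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Stratified permuted-block randomization
#'
#' Within each site, arms are assigned in randomly chosen permuted blocks so
#' that every completed block contains equal counts of each arm. The last
#' block at a site may be truncated, so per-site arm imbalance is bounded by
#' the largest block size minus one.
#'
#' @param n_per_site integer vector of patients per site.
#' @param block_sizes block sizes; each must be a multiple of the number of
#'   arms.
#' @param ratio allocation ratio; only 1:1:1 is supported.
#' @param seed integer seed.
#' @return data.frame with columns `site` and `arm`.
#' @export
#' @examples
#' table(generate_randomization(c(6, 6), seed = 1)$arm)
generate_randomization <- function(n_per_site, block_sizes = c(3L, 6L),
                                   ratio = c(1, 1, 1), seed = 1L) {
  .assert(length(ratio) == length(.ARMS) && all(ratio == ratio[1]),
          "only a 1:1:1 allocation ratio is supported")
  .assert(all(block_sizes %% length(.ARMS) == 0),
          "block size not a multiple of the number of arms")
  .assert(all(n_per_site >= 0), "n_per_site must be non-negative")
  with_seed(seed, {
    out <- lapply(seq_along(n_per_site), function(s) {
      n <- n_per_site[s]
      arms <- character(0)
      while (length(arms) < n) {
        b <- if (length(block_sizes) == 1) block_sizes else sample(block_sizes, 1)
        arms <- c(arms, sample(rep(.ARMS, b / length(.ARMS))))
      }
      data.frame(site = rep.int(s, n), arm = arms[seq_len(n)],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Truncated-normal draw on (lo, hi] by rejection; the truncation region always
# holds most of the mass for the baseline-EASI defaults.
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Marker-matched (treatment-responsive) stratum: nested favorable strata are
# driven by one latent uniform; the responsive core is the intersection of all
# favorable strata, i.e. u < min(favorable_fraction).
.matched_fraction <- function(config) {
  if (!length(config$planted_markers)) return(0)
  min(vapply(config$planted_markers, `[[`, numeric(1), "favorable_fraction"))
}

#' Generate a synthetic trial cohort
#'
#' Draws one patient-level clinical table under a [trial_config()]:
#' randomized arms, demographics, baseline EASI/IGA/NRS, and week-2/week-4
#' follow-up scores whose percent change depends on arm and latent
#' marker-match status. The latent uniform (`latent_u`) and the derived
#' `matched` flag are kept in the table so tests can check recovery against
#' the generator's own truth; they are not part of the clinical surface.
#'
#' Arm totals are enforced exactly: after per-site block randomization, a
#' seeded adjustment pass reassigns the minimal number of patients from
#' over- to under-allocated arms.
#'
#' @param config a [trial_config()].
#' @return data.frame of patient records (one row per patient).
#' @export
#' @examples
#' co <- generate_cohort(trial_config(seed = 1))
#' mean(co$easi_baseline)
generate_cohort <- function(config) {
  .assert(inherits(config, "trial_config"), "config must be a trial_config")
  n <- sum(config$n_per_arm)
  with_seed(split_seed(config$seed, 0), {
    site_sizes <- rep(n %/% config$n_sites, config$n_sites)
    extra <- n %% config$n_sites
    if (extra > 0) site_sizes[seq_len(extra)] <- site_sizes[seq_len(extra)] + 1
    rand <- generate_randomization(site_sizes, config$block_sizes,
                                   seed = split_seed(config$seed, 1))
    # exact-total adjustment: flip surplus assignments, chosen at random
    tab <- table(factor(rand$arm, levels = .ARMS))
    diff <- as.integer(tab) - as.integer(config$n_per_arm)
    names(diff) <- .ARMS
    while (any(diff > 0)) {
      over <- names(diff)[which.max(diff)]
      under <- names(diff)[which.min(diff)]
      i <- sample(which(rand$arm == over), 1)
      rand$arm[i] <- under
      diff[over] <- diff[over] - 1L
      diff[under] <- diff[under] + 1L
    }

    arm <- rand$arm
    u <- stats::runif(n)
    matched <- u < .matched_fraction(config)

    easi0 <- .rtruncnorm(n, config$baseline_easi_mean, config$baseline_easi_sd,
                         lo = 0, hi = 72)
    iga0 <- 2L + stats::rbinom(n, 1, config$iga3_fraction)
    nrs0 <- pmin(10L, pmax(0L, round(stats::rnorm(n, 4.8, 2.1))))

    rr <- config$response_rates
    cell <- ifelse(arm == "placebo", "placebo",
            ifelse(arm == "low_dose", "low_dose",
            ifelse(matched, "active_matched", "active_nonmatched")))
    mu <- vapply(cell, function(k) rr[[k]]["mean"], numeric(1))
    sdv <- vapply(cell, function(k) rr[[k]]["sd"], numeric(1))
    pct4 <- stats::rnorm(n, mu, sdv)
    pct4 <- pmax(pct4, -100)                       # EASI cannot drop below 0
    pct4 <- pmin(pct4, 100 * (72 - easi0) / easi0) # ...or rise above 72
    frac2 <- stats::runif(n, 0.4, 0.8)             # partial effect at week 2
    easi4 <- easi0 * (1 + pct4 / 100)
    easi2 <- easi0 * (1 + frac2 * pct4 / 100)

    # IGA response shares a latent responsiveness with EASI; grade change is
    # bounded to {-2, ..., +1} and grades stay in 0..4
    rho <- config$iga_easi_correlation
    riga <- rho * pct4 + sqrt(1 - rho^2) * stats::rnorm(n, 0, 30)
    dgrade <- pmax(-2L, pmin(1L, as.integer(round(iga0 * riga / 100))))
    iga4 <- pmax(0L, pmin(4L, iga0 + dgrade))
    iga2 <- pmax(0L, pmin(4L, iga0 + as.integer(trunc(dgrade * frac2))))

    start <- as.Date("2020-08-26")
    enroll <- start + sort(sample.int(378, n, replace = TRUE)) - 1L
    mo <- as.integer(format(enroll, "%m"))
    season <- ifelse(mo >= 3 & mo <= 8, "spring_summer", "fall_winter")

    sex <- ifelse(stats::rbinom(n, 1, 0.48) == 1, "M", "F")
    age <- as.integer(round(.rtruncnorm(n, 29, 9, lo = 18.5, hi = 65.5)))

    adherence <- pmin(100, pmax(0, 100 - stats::rexp(n, 1 / 6)))
    dropped <- stats::rbinom(n, 1, config$dropout[arm]) == 1
    consent <- stats::rbinom(n, 1, config$biomarker_consent_rate) == 1

    co <- data.frame(
      patient_id = sprintf("S%03d", seq_len(n)),
      site = rand$site,
      arm = arm,
      sex = sex,
      age = age,
      enrollment_date = enroll,
      season = season,
      easi_baseline = easi0,
      easi_wk2 = ifelse(dropped, NA_real_, easi2),
      easi_wk4 = ifelse(dropped, NA_real_, easi4),
      iga_baseline = iga0,
      iga_wk2 = ifelse(dropped, NA_integer_, iga2),
      iga_wk4 = ifelse(dropped, NA_integer_, iga4),
      nrs_baseline = nrs0,
      dosed = TRUE,
      adherence_pct = adherence,
      completed = !dropped & adherence >= 80,
      biomarker_consent = consent,
      latent_u = u,
      matched = matched,
      stringsAsFactors = FALSE)
    co
  })
}

#' Generate a synthetic baseline plasma proteome
#'
#' Per-protein abundances are log-normal: each protein's log10 median is
#' drawn uniformly over 6.5 orders of magnitude (so the across-protein
#' dynamic range spans >= 5 orders), with a per-protein log10 spread of
#' 0.15-0.35. Planted markers are shifted by `effect_size` within-protein
#' standard deviations between the latent favorable and unfavorable strata,
#' on the stated side. Abundances are independent of arm, so the baseline is
#' arm-balanced by construction.
#'
#' @param config a [trial_config()].
#' @param cohort the cohort produced by [generate_cohort()] under the same
#'   config (its `latent_u` column defines the strata).
#' @return numeric matrix, patients x proteins (fmol), with patient ids as
#'   row names and protein ids as column names.
#' @export
#' @examples
#' cfg <- trial_config(n_proteins = 50, seed = 1)
#' qm <- generate_proteome(cfg, generate_cohort(cfg))
#' dim(qm)
generate_proteome <- function(config, cohort) {
  .assert(inherits(config, "trial_config"), "config must be a trial_config")
  .assert(is.data.frame(cohort) && "latent_u" %in% names(cohort),
          "cohort must come from generate_cohort()")
  n <- nrow(cohort)
  p <- config$n_proteins
  ids <- protein_ids(p)
  with_seed(split_seed(config$seed, 2), {
    mu10 <- stats::runif(p, 0, 6.5)
    sd10 <- stats::runif(p, 0.15, 0.35)
    z <- matrix(stats::rnorm(n * p), n, p)
    for (m in config$planted_markers) {
      j <- match(m$protein_id, ids)
      fav <- cohort$latent_u < m$favorable_fraction
      shift <- if (m$direction == "hi") m$effect_size else -m$effect_size
      z[, j] <- z[, j] + shift * fav
    }
    mat <- 10^(matrix(mu10, n, p, byrow = TRUE) +
                 matrix(sd10, n, p, byrow = TRUE) * z)
    dimnames(mat) <- list(cohort$patient_id, ids)
    mat
  })
}

#' Generate a transition-level MRM report with known QC violations
#'
#' Constructs a Skyline-style transition report in which the number of
#' records violating each exclusion rule is exactly as requested, so the QC
#' filter's kept/excluded counts are fully predictable. Each peptide carries
#' a four-point spike series at 50/100/200/400 fmol: clean peptides have a
#' linear peak-area-ratio (PAR) response strictly inside (0.1, 1);
#' `n_nonlinear` peptides have scrambled PARs; `n_out_of_range` peptides
#' include a PAR at or below 0.1.
#'
#' @param n_clean peptides passing every rule.
#' @param n_low_intensity peptides with SIS peak intensity below 100 counts.
#' @param n_noncoeluting peptides whose SIS peak fails to co-elute.
#' @param n_asymmetric peptides with an asymmetric elution peak.
#' @param n_nonlinear peptides whose spike series is non-linear.
#' @param n_out_of_range peptides with a PAR outside (0.1, 1).
#' @param seed integer seed.
#' @return data.frame with one row per peptide x spike level and columns
#'   `peptide_id`, `protein_id`, `precursor_mz`, `charge`, `sis_intensity`,
#'   `endo_intensity`, `coeluted`, `symmetric`, `spike_fmol`, `par`.
#' @export
#' @examples
#' rpt <- generate_transition_report(n_clean = 3, n_low_intensity = 1, seed = 1)
#' table(rpt$sis_intensity >= 100)
generate_transition_report <- function(n_clean = 10L, n_low_intensity = 0L,
                                       n_noncoeluting = 0L, n_asymmetric = 0L,
                                       n_nonlinear = 0L, n_out_of_range = 0L,
                                       seed = 1L) {
  counts <- c(clean = n_clean, low = n_low_intensity, noco = n_noncoeluting,
              asym = n_asymmetric, nonlin = n_nonlinear, range = n_out_of_range)
  .assert(all(counts >= 0), "peptide counts must be non-negative")
  n_pep <- sum(counts)
  .assert(n_pep > 0, "at least one peptide must be requested")
  kind <- rep(names(counts), counts)
  levels_fmol <- c(50, 100, 200, 400)
  with_seed(seed, {
    rows <- lapply(seq_len(n_pep), function(i) {
      k <- kind[i]
      par <- switch(k,
        range = c(0.05, 0.1, 0.2, 0.4),
        nonlin = pmin(0.95, pmax(0.12,  # zig-zag: R^2 ~ 0 by construction
                 c(0.5, 0.2, 0.9, 0.3) + stats::runif(4, -0.05, 0.05))),
        {  # linear series strictly inside (0.1, 1)
          p50 <- stats::runif(1, 0.12, 0.2)
          p400 <- stats::runif(1, 0.6, 0.95)
          p50 + (p400 - p50) * (levels_fmol - 50) / 350
        })
      sis <- if (k == "low") stats::runif(4, 10, 99) else stats::runif(4, 500, 5000)
      data.frame(
        peptide_id = sprintf("PEP%03d", i),
        protein_id = sprintf("PRT%03d", i),
        precursor_mz = round(stats::runif(4, 400, 1200), 2),
        charge = sample(2:3, 4, replace = TRUE),
        sis_intensity = round(sis, 1),
        endo_intensity = round(par * sis, 1),
        coeluted = as.integer(k != "noco"),
        symmetric = as.integer(k != "asym"),
        spike_fmol = levels_fmol,
        par = round(par, 4),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
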