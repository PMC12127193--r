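# Orchestration: analysis-set construction, run configuration, file I/O and
# the end-to-end pipeline with a reproducibility manifest.

#' Build the nested analysis sets
#'
#' Applies the standard membership rules: SAS (safety analysis set) =
#' randomized and received at least one dose; FAS (full analysis set) = SAS
#' with at least one post-dose efficacy assessment; PPS (per-protocol set) =
#' FAS who completed the trial with adherence >= 80%; BAS (biomarker
#' analysis set) = FAS with biomarker consent and available baseline
#' biomarker data. The sets nest by construction: PPS and BAS are subsets of
#' FAS, FAS of SAS.
#'
#' @param cohort clinical table with logical columns `dosed`, `completed`,
#'   `biomarker_consent`, a numeric `adherence_pct`, and the week-2/week-4
#'   efficacy columns (an assessment is "present" when non-missing).
#' @param biomarker_ids patient ids with available biomarker data (default:
#'   everyone, i.e. availability is governed by consent alone).
#' @param min_adherence PPS adherence bound in percent (default 80).
#' @return list of class `analysis_sets` with `SAS`, `FAS`, `PPS`, `BAS`
#'   patient-id vectors.
#' @export
build_analysis_sets <- function(cohort, biomarker_ids = cohort$patient_id,
                                min_adherence = 80) {
  need <- c("patient_id", "dosed", "completed", "adherence_pct",
            "biomarker_consent", "easi_wk2", "easi_wk4")
  .assert(all(need %in% names(cohort)),
          paste("cohort is missing columns:",
                paste(setdiff(need, names(cohort)), collapse = ", ")))
  has_eff <- !is.na(cohort$easi_wk2) | !is.na(cohort$easi_wk4)
  bad <- which(!cohort$dosed & (has_eff | cohort$completed))
  .assert(length(bad) == 0,
          paste("contradictory flags (efficacy or completion without dosing) in rows:",
                paste(bad, collapse = ", ")))
  sas <- cohort$patient_id[cohort$dosed]
  fas <- cohort$patient_id[cohort$dosed & has_eff]
  pps <- cohort$patient_id[cohort$dosed & has_eff & cohort$completed &
                             cohort$adherence_pct >= min_adherence]
  bas <- intersect(cohort$patient_id[cohort$dosed & has_eff &
                                       cohort$biomarker_consent],
                   biomarker_ids)
  structure(list(SAS = sas, FAS = fas, PPS = pps, BAS = bas),
            class = "analysis_sets")
}

#' Configure a pipeline run
#'
#' Bundles every tunable of the pipeline into one serializable object. With
#' no input paths the run is fully synthetic: the trial generator produces
#' the clinical table and proteome under `trial` (a [trial_config()]).
#' Supplying `clinical_csv`/`proteome_tsv` ingests user data with the same
#' layout instead. Every stochastic stage draws its seed from the master
#' `seed` through [split_seed()], so reruns with an identical config are
#' byte-identical.
#'
#' @param out_dir output directory for report CSVs and the manifest.
#' @param seed master seed.
#' @param trial a [trial_config()] (its own seed is overridden by `seed`).
#' @param clinical_csv,proteome_tsv,transition_csv,gmt optional input paths.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "quant", "endpoints", "strat", "combos", "explore")`.
#' @param auroc_min DEP selection threshold.
#' @param r2_min calibration-linearity threshold.
#' @param shapiro_alpha normality-gate level for within-arm tests.
#' @param var_equal pooled-variance between-arm t test (default FALSE =
#'   Welch).
#' @param ridge separation fallback penalty for combo models.
#' @param combo_k combination size (1-3).
#' @param combo_shortlist take at most this many top-AUROC DEPs into the
#'   combination search.
#' @param max_combos enumeration budget.
#' @param log_transform named logical vector of markers to log-transform in
#'   combo models.
#' @param n_perm GSEA permutations.
#' @param active_arm,placebo_arm arm labels for contrasts.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, trial = trial_config(),
                       clinical_csv = NULL, proteome_tsv = NULL,
                       transition_csv = NULL, gmt = NULL,
                       stages = c("simulate", "quant", "endpoints", "strat",
                                  "combos", "explore"),
                       auroc_min = 0.7, r2_min = 0.9, shapiro_alpha = 0.05,
                       var_equal = FALSE, ridge = 1e-4, combo_k = 2,
                       combo_shortlist = 10, max_combos = 2000,
                       log_transform = NULL, n_perm = 1000,
                       active_arm = "high_dose", placebo_arm = "placebo") {
  all_stages <- c("simulate", "quant", "endpoints", "strat", "combos",
                  "explore")
  .assert(all(stages %in% all_stages),
          paste("unknown stage(s):",
                paste(setdiff(stages, all_stages), collapse = ", ")))
  .assert(inherits(trial, "trial_config"), "trial must be a trial_config")
  .assert(combo_k %in% 1:3, "combo_k must be 1, 2 or 3")
  trial$seed <- as.integer(split_seed(seed, 100))
  structure(list(out_dir = out_dir, seed = as.integer(seed), trial = trial,
                 clinical_csv = clinical_csv, proteome_tsv = proteome_tsv,
                 transition_csv = transition_csv, gmt = gmt,
                 stages = stages, auroc_min = auroc_min, r2_min = r2_min,
                 shapiro_alpha = shapiro_alpha, var_equal = var_equal,
                 ridge = ridge, combo_k = combo_k,
                 combo_shortlist = combo_shortlist, max_combos = max_combos,
                 log_transform = log_transform, n_perm = n_perm,
                 active_arm = active_arm, placebo_arm = placebo_arm),
            class = "run_config")
}

#' Read / write the standard file formats
#'
#' The clinical table travels as CSV (one row per patient, ISO dates), the
#' proteome as TSV with patients in rows and protein ids in columns (first
#' column `patient_id`), transition reports as CSV.
#'
#' @param path file path.
#' @name predstrat-io
NULL

#' @rdname predstrat-io
#' @param cohort clinical table.
#' @export
write_clinical_csv <- function(cohort, path) {
  out <- cohort
  out$enrollment_date <- format(as.Date(out$enrollment_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname predstrat-io
#' @export
read_clinical_csv <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("enrollment_date" %in% names(co))
    co$enrollment_date <- as.Date(co$enrollment_date)
  co
}

#' @rdname predstrat-io
#' @param matrix quantification matrix (patients x proteins).
#' @export
write_proteome_tsv <- function(matrix, path) {
  df <- data.frame(patient_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname predstrat-io
#' @export
read_proteome_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname predstrat-io
#' @param col_map optional named character vector mapping the canonical
#'   column names (`peptide_id`, `sis_intensity`, `par`, ...) to the names
#'   used in the file, for vendor reports with different headers.
#' @export
read_transition_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    .assert(all(col_map %in% names(df)),
            paste("mapped column(s) absent from file:",
                  paste(setdiff(col_map, names(df)), collapse = ", ")))
    names(df)[match(col_map, names(df))] <- names(col_map)
  }
  df
}

.write_report <- function(df, dir, name) {
  path <- file.path(dir, name)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order - simulate (or ingest), transition
#' quant/QC, endpoints, single-marker stratification, combination search,
#' exploratory analytics - writing each stage's report CSV into
#' `config$out_dir` together with a `manifest.json` recording the
#' configuration, per-stage seeds, record counts, and an MD5 content hash of
#' every output file. Rerunning with an identical config reproduces
#' byte-identical outputs. A stage whose upstream is disabled fails with a
#' dependency error naming both stages.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory tables and the manifest.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(out_dir = tempfile(), seed = 1,
#'                   trial = trial_config(n_proteins = 60),
#'                   stages = c("simulate", "endpoints", "strat"))
#' res <- run_pipeline(cfg)
#' names(res$tables)
#' }
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  need <- function(stage, upstream, have) {
    .assert(have, sprintf(
      "stage '%s' requires stage '%s' (or the matching input file)",
      stage, upstream))
  }
  tables <- list()
  files <- character(0)
  counts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- NULL; qm <- NULL
  if ("simulate" %in% st) {
    run_stage("simulate", {
      cohort <- generate_cohort(config$trial)
      qm <- generate_proteome(config$trial, cohort)
      files["clinical"] <- write_clinical_csv(cohort,
        file.path(config$out_dir, "clinical.csv"))
      files["proteome"] <- write_proteome_tsv(qm,
        file.path(config$out_dir, "proteome.tsv"))
    })
  } else {
    if (!is.null(config$clinical_csv)) cohort <- read_clinical_csv(config$clinical_csv)
    if (!is.null(config$proteome_tsv)) qm <- read_proteome_tsv(config$proteome_tsv)
  }
  if (!is.null(cohort)) counts$patients <- nrow(cohort)

  if ("quant" %in% st && !is.null(config$transition_csv)) {
    run_stage("quant", {
      rpt <- read_transition_csv(config$transition_csv)
      flt <- filter_transitions(rpt)
      lin <- linearity_filter(flt$kept, r2_min = config$r2_min)
      qc <- data.frame(rule = c(names(flt$tally), "nonlinear", "kept_peptides"),
                       n = c(unname(flt$tally),
                             length(unique(flt$kept$peptide_id)) - length(lin),
                             length(lin)))
      tables$qc <- qc
      files["qc"] <- .write_report(qc, config$out_dir, "transition_qc.csv")
      counts$transitions_in <- nrow(rpt)
      counts$peptides_kept <- length(lin)
    })
  }

  sets <- NULL; ep <- NULL
  if ("endpoints" %in% st) {
    need("endpoints", "simulate", !is.null(cohort))
    run_stage("endpoints", {
      sets <- build_analysis_sets(cohort)
      fas <- cohort[cohort$patient_id %in% sets$FAS, , drop = FALSE]
      ep <- compute_endpoints(fas)
      arms <- split(ep$pct_easi_wk4, ep$arm)
      within <- lapply(arms, within_arm_change_test,
                       shapiro_alpha = config$shapiro_alpha)
      contr <- lapply(setdiff(names(arms), config$placebo_arm), function(a) {
        bc <- between_arm_contrast(arms[[a]], arms[[config$placebo_arm]],
                                   var_equal = config$var_equal)
        data.frame(arm = a, mean_pct = mean(arms[[a]], na.rm = TRUE),
                   diff_vs_placebo = bc$mean_diff, ci_low = bc$ci_low,
                   ci_high = bc$ci_high, p_value = bc$p_value,
                   within_arm_p = within[[a]]$p_value,
                   within_arm_test = within[[a]]$test_used,
                   stringsAsFactors = FALSE)
      })
      arm_tab <- do.call(rbind, contr)
      tables$endpoints <- ep
      tables$arm_contrasts <- arm_tab
      files["endpoints"] <- .write_report(ep, config$out_dir, "endpoints.csv")
      files["arm_contrasts"] <- .write_report(arm_tab, config$out_dir,
                                               "arm_contrasts.csv")
      counts$fas <- nrow(fas); counts$bas <- length(sets$BAS)
    })
  }

  deps <- NULL; bas_cohort <- NULL
  if ("strat" %in% st) {
    need("strat", "endpoints", !is.null(ep))
    need("strat", "simulate", !is.null(qm))
    run_stage("strat", {
      bas_cohort <- cohort[cohort$patient_id %in% sets$BAS, , drop = FALSE]
      ep_bas <- ep[ep$patient_id %in% sets$BAS, , drop = FALSE]
      act <- bas_cohort$patient_id[bas_cohort$arm == config$active_arm]
      y <- ep_bas$easi50_wk4[match(act, ep_bas$patient_id)]
      deps <- select_deps(qm[act, , drop = FALSE], y,
                          auroc_min = config$auroc_min)
      mk <- marker_table(bas_cohort, ep_bas, qm, deps,
                         active_arm = config$active_arm,
                         placebo_arm = config$placebo_arm,
                         var_equal = config$var_equal)
      tables$deps <- deps
      tables$markers <- mk
      files["deps"] <- .write_report(deps, config$out_dir, "deps.csv")
      files["markers"] <- .write_report(mk, config$out_dir, "marker_table.csv")
      counts$deps_selected <- nrow(deps)
    })
  }

  if ("combos" %in% st) {
    need("combos", "strat", !is.null(deps))
    run_stage("combos", {
      short <- utils::head(deps, config$combo_shortlist)
      ep_bas <- ep[ep$patient_id %in% bas_cohort$patient_id, , drop = FALSE]
      combo <- enumerate_and_report(qm, short, ep_bas, bas_cohort,
                                    k = config$combo_k,
                                    log_transform = config$log_transform,
                                    max_combos = config$max_combos,
                                    active_arm = config$active_arm,
                                    placebo_arm = config$placebo_arm,
                                    var_equal = config$var_equal)
      tables$combos <- combo
      files["combos"] <- .write_report(combo, config$out_dir,
                                        "combo_table.csv")
      counts$combos_evaluated <- nrow(combo)
    })
  }

  if ("explore" %in% st) {
    need("explore", "strat", !is.null(deps))
    run_stage("explore", {
      ep_bas <- ep[ep$patient_id %in% bas_cohort$patient_id, , drop = FALSE]
      act <- bas_cohort$patient_id[bas_cohort$arm == config$active_arm]
      y <- ep_bas$easi50_wk4[match(act, ep_bas$patient_id)]
      panel <- qm[act, deps$protein_id, drop = FALSE]
      vol <- volcano(panel, y)
      tables$volcano <- vol
      files["volcano"] <- .write_report(vol, config$out_dir, "volcano.csv")
      if (nrow(deps) >= 2) {
        hc <- hcluster(panel)
        pc <- pca_biomarkers(panel)
        pca_tab <- data.frame(patient_id = rownames(panel),
                              pc1 = pc$scores[, 1],
                              pc2 = if (ncol(pc$scores) >= 2)
                                pc$scores[, 2] else NA_real_,
                              responder = y, stringsAsFactors = FALSE)
        tables$pca <- pca_tab
        files["pca"] <- .write_report(pca_tab, config$out_dir, "pca.csv")
        tables$hcluster <- hc
      }
      if (!is.null(config$gmt)) {
        sets_gmt <- read_gmt(config$gmt)
        scores <- stats::setNames(vol$log2_fc, vol$protein_id)
        scores <- scores[!is.na(scores)]
        gs <- gsea_preranked(scores, sets_gmt, n_perm = config$n_perm,
                             seed = split_seed(config$seed, 6))
        gs$leading_edge <- vapply(gs$leading_edge, paste, character(1),
                                  collapse = ";")
        tables$gsea <- gs
        files["gsea"] <- .write_report(gs, config$out_dir, "gsea.csv")
      }
    })
  }

  manifest <- list(
    config = .serializable_config(config),
    stage_seeds = stats::setNames(
      as.list(vapply(0:6, function(i) split_seed(config$seed, i), numeric(1))),
      c("cohort", "randomization", "proteome", "reserved3", "reserved4",
        "reserved5", "gsea")),
    counts = counts,
    files = lapply(stats::setNames(files, names(files)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(tables = tables, files = files, manifest = manifest,
                 analysis_sets = sets))
}

# run_config stripped to plain types for JSON/YAML round-tripping
.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$trial <- unclass(cfg$trial)
  cfg$trial$planted_markers <- lapply(cfg$trial$planted_markers, unclass)
  cfg$trial$response_rates <- lapply(cfg$trial$response_rates, as.list)
  cfg
}
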