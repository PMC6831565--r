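#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end frailty-metabotype
#' pipeline with its default. Unknown keys are rejected by name, so a typo in
#' a config file fails loudly rather than being silently ignored.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_subjects,n_items Cohort size and deficit-panel length.
#' @param min_items Minimum answered items for FI inclusion.
#' @param edges FI class bin edges.
#' @param qc_interval,n_features,drift_model,drift_amplitude,missing_rate
#'   Feature-table run design (see [run_design()]).
#' @param planted_effect Log2 shift per frailty-class step for planted
#'   features.
#' @param rsd_threshold QC RSD filter threshold (percent).
#' @param sig_p Feature-significance threshold feeding pathway enrichment.
#' @param tol_ppm Annotation mass tolerance.
#' @param evidence_cutoff Activity-network evidence cutoff.
#' @param n_perm_enrich,n_perm_class Permutation counts for enrichment and
#'   for the classification null.
#' @param perm_top Number of top univariate features carried into the
#'   permutation-null classification screen.
#' @param top_k,mccv_reps,n_lv Multivariate ROC settings.
#' @param mr_n_snps,mr_true_beta,mr_r2_cutoff,mr_change Mendelian
#'   randomization settings.
#' @param run_permutation Toggle for the (slowest) permutation-null stage.
#' @param ... Reserved; any unknown key raises an error naming it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_subjects = 300,
                            n_items = 60,
                            min_items = 30,
                            edges = c(0.1, 0.2, 0.3),
                            qc_interval = 10,
                            n_features = 120,
                            drift_model = "linear",
                            drift_amplitude = 0.3,
                            missing_rate = 0.02,
                            planted_effect = 0.8,
                            rsd_threshold = 20,
                            sig_p = 1e-4,
                            tol_ppm = 10,
                            evidence_cutoff = 3,
                            n_perm_enrich = 199,
                            n_perm_class = 99,
                            perm_top = 20,
                            top_k = 12,
                            mccv_reps = 100,
                            n_lv = 7,
                            mr_n_snps = 4,
                            mr_true_beta = -0.5,
                            mr_r2_cutoff = 0.8,
                            mr_change = -0.10,
                            run_permutation = TRUE,
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(names(extra), collapse = ", ")))
  }
  cfg <- mget(setdiff(names(formals()), "..."))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param path Path to a YAML file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the frailty-metabotype pipeline end-to-end
#'
#' Executes every stage in dependency order on a synthetic cohort: cohort
#' generation, frailty-index scoring and stratification, FI ~ age robust
#' regression, feature-table generation, QC drift correction, RSD filtering,
#' log2 transform, univariate panels, pathway enrichment and activity
#' network, PC-DFA, double-CV RUSBoost with permutation null, multivariate
#' ROC, and Mendelian randomization. Every artifact is written as delimited
#' text into `dir` and listed (with its MD5 checksum) in `manifest.csv`;
#' rerunning with the same config reproduces the checksums.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("frailmet_run_")) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- character()
  put <- function(x, name) {
    p <- file.path(dir, name)
    write_stage_table(x, p, seed = seed)
    artifacts <<- c(artifacts, p)
    p
  }

  inform("stage 1/8: cohort generation")
  cohort <- generate_cohort(cohort_config(n_subjects = config$n_subjects,
                                          n_items = config$n_items, seed = seed))
  put(cohort$deficits, "deficits.csv")
  put(cohort$subjects, "subjects.csv")

  inform("stage 2/8: frailty index")
  frailty <- compute_fi(cohort$deficits, min_items = config$min_items,
                        edges = config$edges)
  put(frailty, "frailty.csv")
  fidat <- inner_join(frailty, cohort$subjects, by = "subject_id")
  fi_fit <- fit_fi_regression(fidat)
  put(glance(fi_fit), "fi_regression.csv")
  put(fi_distribution_summary(frailty$fi, edges = config$edges), "fi_summary.csv")

  inform("stage 3/8: feature table")
  planted <- default_planted_features(effect = config$planted_effect,
                                      n_features = config$n_features)
  design <- run_design(n_samples = nrow(frailty),
                       qc_interval = config$qc_interval,
                       n_features = config$n_features,
                       drift_model = config$drift_model,
                       drift_amplitude = config$drift_amplitude,
                       missing_rate = config$missing_rate,
                       planted = planted, seed = seed)
  raw <- generate_feature_table(frailty, design)
  put(raw, "features_raw.csv")

  inform("stage 4/8: preprocessing")
  corrected <- qc_spline_correct(raw)
  filtered <- rsd_filter(corrected, threshold_pct = config$rsd_threshold)
  put(attr(filtered, "removal_report"), "rsd_report.csv")
  logt <- log2_transform(filtered)
  put(logt, "features_processed.csv")

  samples <- logt[logt$sample_type == "sample", ]
  Xs <- samples[feature_cols(samples)]
  cls <- frailty$fi_class[match(samples$sample_id, frailty$subject_id)]
  frail <- cls >= 3   # FI >= 0.2

  inform("stage 5/8: univariate panels")
  kw <- kruskal_panel(Xs, cls)
  mw <- mann_whitney_panel(Xs, factor(frail, levels = c(FALSE, TRUE),
                                      labels = c("nonfrail", "frail")))
  put(kw, "kruskal_panel.csv")
  put(mw, "mann_whitney_panel.csv")

  inform("stage 6/8: pathway enrichment")
  reference <- load_toy_reference()
  hits <- annotate_mz(logt, reference, tol_ppm = config$tol_ppm)
  sig_features <- kw$feature[!is.na(kw$p) & kw$p < config$sig_p]
  scores <- score_pathways(hits, sig_features, feature_cols(logt), reference,
                           n_perm = config$n_perm_enrich, seed = seed)
  network <- build_activity_network(hits, scores, reference,
                                    evidence_cutoff = config$evidence_cutoff)
  put(scores$scores, "pathway_scores.csv")
  put(scores$evidence, "metabolite_evidence.csv")
  put(network$members, "network_modules.csv")

  inform("stage 7/8: chemometrics and multivariate ROC")
  Xi <- Xs
  for (f in names(Xi)) Xi[[f]][is.na(Xi[[f]])] <- stats::median(Xi[[f]], na.rm = TRUE)
  dfa <- pc_dfa(Xi, cls)
  put(dfa$scores, "pcdfa_scores.csv")
  cv_rep <- rusboost_2cv(Xi, cls, seed = seed)
  put(tidy(cv_rep), "confusion_matrix.csv")
  null_dist <- NULL
  if (isTRUE(config$run_permutation)) {
    keep_top <- kw$feature[order(kw$p)][seq_len(min(config$perm_top, ncol(Xi)))]
    null_dist <- permutation_null(Xi[keep_top], cls,
                                  n_perm = config$n_perm_class, seed = seed)
    put(tibble(observed = null_dist$observed, p_value = null_dist$p_value,
               null_mean = mean(null_dist$null)), "permutation_null.csv")
  }
  mroc <- mccv_roc(Xi, frail, top_k = config$top_k, reps = config$mccv_reps,
                   n_lv = config$n_lv, seed = seed)
  put(glance(mroc), "mroc_summary.csv")
  put(mroc$mean_curve, "mroc_curve.csv")
  put(mroc$selection_freq, "mroc_selection_freq.csv")

  inform("stage 8/8: Mendelian randomization")
  mr_stats <- generate_mr_summary(mr_sim_config(n_snps = config$mr_n_snps,
                                                true_causal_beta = config$mr_true_beta,
                                                seed = seed))
  put(mr_stats, "mr_summary_stats.csv")
  mr_est <- mr_run(mr_stats, r2_cutoff = config$mr_r2_cutoff,
                   change = config$mr_change)
  put(glance(mr_est), "mr_estimate.csv")

  manifest <- tibble(file = basename(artifacts),
                     md5 = unname(tools::md5sum(artifacts)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))

  invisible(list(dir = dir, manifest = manifest, frailty = frailty,
                 fi_fit = fi_fit, kruskal = kw, mann_whitney = mw,
                 pathway_scores = scores, network = network, pc_dfa = dfa,
                 classification = cv_rep, permutation = null_dist,
                 mroc = mroc, mr = mr_est))
}

#' One-command synthetic demonstration run
#'
#' Runs [run_pipeline()] with the default configuration at demonstration
#' scale and prints where the artifacts were written.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @export
demo_pipeline <- function(dir = tempfile("frailmet_demo_"), seed = 1L) {
  res <- run_pipeline(pipeline_config(seed = seed), dir = dir)
  inform(sprintf("demo complete: %d artifacts in %s", nrow(res$manifest), res$dir))
  res
}
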