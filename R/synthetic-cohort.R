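#' Configuration for a synthetic ageing cohort
#'
#' Defines the generative model behind [generate_cohort()]: each subject has a
#' uniformly distributed age, a latent frailty liability, and answers a panel
#' of binary-coded health-deficit items. The probability of exhibiting item
#' `i` follows a logistic model
#' \deqn{p_{ij} = \mathrm{logit}^{-1}(\alpha_i + b_j + \beta_{age} (age_j - 70))}
#' with per-item intercepts \eqn{\alpha_i}, a per-subject liability
#' \eqn{b_j \sim N(0, \sigma_b^2)}, and a common age slope. This is the
#' simplest mechanism that yields a right-skewed, unimodal deficit-accumulation
#' frailty index with a positive age correlation, the structure observed in
#' population frailty surveys. Default values are calibrated so that the four
#' standard index categories (<0.1, 0.1-0.2, 0.2-0.3, >0.3) are populated in
#' roughly the proportions reported for community cohorts (about 26/48/18/8%).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Length-2 numeric, min < max, in years.
#' @param n_items Number of deficit items.
#' @param item_weights Deficit value attributed when an item is present; each
#'   in \[0, 1\].
#' @param age_effect Logit-scale slope of deficit probability per year of age.
#' @param base_logit Mean item intercept on the logit scale.
#' @param item_sd Standard deviation of item intercepts.
#' @param subject_sd Standard deviation of the subject frailty liability.
#' @param nonresponse_rate Probability an individual item goes unanswered.
#' @param heavy_nonresponse Fraction of subjects answering fewer than half the
#'   items, to exercise minimum-response exclusion downstream.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 400,
                          age_range = c(50, 90),
                          n_items = 60,
                          item_weights = rep(1, n_items),
                          age_effect = 0.035,
                          base_logit = -1.8,
                          item_sd = 0.7,
                          subject_sd = 0.45,
                          nonresponse_rate = 0.02,
                          heavy_nonresponse = 0.01,
                          seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  n_items <- check_count(n_items, "n_items")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("`age_range` must be (min, max) with min < max")
  }
  if (length(item_weights) != n_items || any(item_weights < 0 | item_weights > 1)) {
    abort("`item_weights` must have one value in [0, 1] per item")
  }
  check_fraction(nonresponse_rate, "nonresponse_rate")
  check_fraction(heavy_nonresponse, "heavy_nonresponse")
  structure(list(
    n_subjects = n_subjects, age_range = as.numeric(age_range),
    n_items = n_items, item_weights = as.numeric(item_weights),
    age_effect = age_effect, base_logit = base_logit, item_sd = item_sd,
    subject_sd = subject_sd, nonresponse_rate = nonresponse_rate,
    heavy_nonresponse = heavy_nonresponse, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic deficit-questionnaire cohort
#'
#' Draws ages, per-subject frailty liabilities and per-item deficit responses
#' under the model described in [cohort_config()]. A small fraction of item
#' responses is masked at random (unanswered, recorded as `NA`), and a small
#' fraction of subjects is given heavy non-response so that downstream
#' minimum-response filtering has something to exclude.
#'
#' @param config A [cohort_config()].
#' @return A list with `deficits` (tibble: `subject_id` plus one `item_*`
#'   column per deficit item, values in \[0,1\] or `NA`) and `subjects`
#'   (tibble: `subject_id`, `age`, `sex`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_subjects
  p <- config$n_items
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  alpha <- stats::rnorm(p, config$base_logit, config$item_sd)
  b <- stats::rnorm(n, 0, config$subject_sd)
  eta <- outer(b + config$age_effect * (age - 70), alpha, "+")
  present <- matrix(stats::runif(n * p) < stats::plogis(eta), n, p)
  values <- sweep(present * 1, 2, config$item_weights, "*")
  # item non-response: MCAR plus a few heavy non-responders
  mask <- matrix(stats::runif(n * p) < config$nonresponse_rate, n, p)
  heavy <- stats::runif(n) < config$heavy_nonresponse
  if (any(heavy)) {
    for (j in which(heavy)) {
      mask[j, sample.int(p, ceiling(0.6 * p))] <- TRUE
    }
  }
  values[mask] <- NA_real_
  colnames(values) <- sprintf("item_%02d", seq_len(p))
  ids <- sprintf("S%04d", seq_len(n))
  list(
    deficits = bind_cols(tibble(subject_id = ids), as_tibble(values)),
    subjects = tibble(subject_id = ids, age = age, sex = sex)
  )
}

#' Design of a synthetic LC-MS run
#'
#' Describes an injection sequence with interleaved pooled-QC injections,
#' multiplicative intensity drift over injection order, and a set of planted
#' features whose log2 abundance shifts monotonically across frailty classes
#' (downward for carnitine/vitamin-E-like features, upward for
#' tryptophan-pathway-like features). Planted features carry the \[M+H\]+
#' m/z of reference metabolites so that pathway annotation can recover them.
#'
#' @param n_samples Number of biological samples (must match the frailty
#'   assignment passed to [generate_feature_table()]).
#' @param qc_interval Number of biological samples between QC injections.
#' @param n_features Total number of features.
#' @param drift_model One of "linear", "spline", "none".
#' @param drift_amplitude Peak relative drift over the run (0.3 = 30%).
#' @param batch_count Number of contiguous batches.
#' @param planted Tibble with columns `feature` (index), `direction`
#'   ("down"/"up"), `effect` (log2 units per frailty-class step) and `mass`
#'   (neutral monoisotopic mass, Da). `NULL` plants nothing.
#' @param noise_sd Biological + technical log2 SD for study samples.
#' @param qc_noise_sd Technical log2 SD for QC reinjections.
#' @param missing_rate MCAR missingness fraction in \[0, 1).
#' @param seed Integer seed.
#' @return A `run_design` list.
#' @export
run_design <- function(n_samples,
                       qc_interval = 10,
                       n_features = 200,
                       drift_model = c("linear", "spline", "none"),
                       drift_amplitude = 0.3,
                       batch_count = 1,
                       planted = NULL,
                       noise_sd = 0.8,
                       qc_noise_sd = 0.1,
                       missing_rate = 0.02,
                       seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  qc_interval <- check_count(qc_interval, "qc_interval")
  n_features <- check_count(n_features, "n_features")
  batch_count <- check_count(batch_count, "batch_count")
  check_fraction(missing_rate, "missing_rate")
  drift_model <- match.arg(drift_model)
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("feature", "direction", "effect", "mass") %in% names(planted)))
    if (any(!planted$direction %in% c("down", "up"))) abort("direction must be 'down' or 'up'")
    if (any(!is.finite(planted$effect))) abort("planted effect sizes must be finite")
    if (any(planted$feature < 1 | planted$feature > n_features)) {
      abort("planted feature indices out of range")
    }
  }
  structure(list(
    n_samples = n_samples, qc_interval = qc_interval, n_features = n_features,
    drift_model = drift_model, drift_amplitude = drift_amplitude,
    batch_count = batch_count, planted = planted, noise_sd = noise_sd,
    qc_noise_sd = qc_noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "run_design")
}

#' Default planted features for the demonstration cohort
#'
#' Places six reference metabolites into a feature table: carnitine-shuttle
#' and vitamin-E species decreasing with frailty class, kynurenine-pathway
#' species increasing, mirroring the directionality reported for frail
#' metabotypes.
#'
#' @param reference A [pathway_reference()]; defaults to the bundled toy set.
#' @param effect Log2 shift per frailty-class step (absolute value).
#' @param n_features Total features in the design (indices are spread evenly).
#' @return Tibble suitable for the `planted` argument of [run_design()].
#' @export
default_planted_features <- function(reference = load_toy_reference(),
                                     effect = 0.8, n_features = 200) {
  picks <- tibble(
    metabolite = c("carnitine", "acetylcarnitine", "palmitoylcarnitine",
                   "alpha-tocotrienol", "gamma-tocotrienol",
                   "kynurenine", "tryptophan"),
    direction = c("down", "down", "down", "down", "down", "up", "up")
  )
  mets <- reference$metabolites
  picks <- left_join(picks, mets[, c("metabolite", "neutral_mass")], by = "metabolite")
  if (anyNA(picks$neutral_mass)) abort("reference lacks a default planted metabolite")
  tibble(
    feature = round(seq(1, n_features, length.out = nrow(picks))),
    direction = picks$direction,
    effect = effect,
    mass = picks$neutral_mass,
    metabolite = picks$metabolite
  )
}

#' Generate a synthetic untargeted MS feature table
#'
#' Builds an injection sequence in which a pooled QC sample is injected first,
#' after every `qc_interval` study samples, and last within each batch. Every
#' feature has a latent base intensity; QC injections share that base exactly
#' (plus technical noise), study samples add biological noise and any planted
#' frailty-class effect, and the whole run is modulated by a multiplicative
#' drift curve shared across features with per-feature amplitude jitter.
#'
#' @param frailty Tibble with `subject_id` and `fi_class` covering every
#'   biological sample (one row per sample), e.g. from [compute_fi()] +
#'   [stratify_fi()].
#' @param design A [run_design()]; `design$n_samples` must equal `nrow(frailty)`.
#' @return A feature-table tibble with columns `sample_id`, `injection_order`,
#'   `batch`, `sample_type` and one intensity column per feature named
#'   `mz_<m/z>_rt_<rt>`.
#' @export
generate_feature_table <- function(frailty, design) {
  if (!inherits(design, "run_design")) abort("`design` must be a run_design")
  frailty <- as_tibble(frailty)
  if (!all(c("subject_id", "fi_class") %in% names(frailty))) {
    abort("`frailty` needs columns subject_id and fi_class")
  }
  if (nrow(frailty) != design$n_samples) {
    abort(sprintf("dimension mismatch: design expects %d samples, frailty has %d",
                  design$n_samples, nrow(frailty)))
  }
  set.seed(derive_seed(design$seed, 2L))
  p <- design$n_features

  # feature identities: planted features take reference [M+H]+ m/z
  mz <- stats::runif(p, 100, 1000)
  rt <- stats::runif(p, 30, 900)
  planted <- design$planted
  dir_sign <- effect <- rep(0, p)
  if (!is.null(planted)) {
    mz[planted$feature] <- planted$mass + 1.007276
    dir_sign[planted$feature] <- ifelse(planted$direction == "down", -1, 1)
    effect[planted$feature] <- planted$effect
  }
  fnames <- sprintf("mz_%.4f_rt_%.1f", mz, rt)

  base_log2 <- stats::runif(p, 14, 22)

  # injection layout: batches are contiguous; QC leads, trails and
  # punctuates each batch every qc_interval study injections
  batch_of <- rep(seq_len(design$batch_count), length.out = design$n_samples)
  batch_of <- sort(batch_of)
  rows <- list()
  for (b in seq_len(design$batch_count)) {
    s_idx <- which(batch_of == b)
    seq_b <- c("QC")
    for (k in seq_along(s_idx)) {
      seq_b <- c(seq_b, paste0("S", s_idx[k]))
      if (k %% design$qc_interval == 0 && k < length(s_idx)) seq_b <- c(seq_b, "QC")
    }
    seq_b <- c(seq_b, "QC")
    rows[[b]] <- tibble(slot = seq_b, batch = sprintf("B%02d", b))
  }
  layout <- bind_rows(rows)
  layout$injection_order <- seq_len(nrow(layout))
  n_inj <- nrow(layout)

  # drift curve shared across features, per-feature amplitude jitter
  tgrid <- (layout$injection_order - 1) / max(1, n_inj - 1)
  shape <- switch(design$drift_model,
    none = rep(0, n_inj),
    linear = tgrid,
    spline = {
      s <- sin(2 * pi * (stats::runif(1, 0.5, 1.5) * tgrid + stats::runif(1)))
      s / max(abs(s))
    })
  amp <- design$drift_amplitude * stats::runif(p, 0.5, 1.5)
  drift <- 1 + outer(shape, amp)          # n_inj x p, multiplicative

  is_qc <- layout$slot == "QC"
  class_of <- integer(n_inj)
  class_of[!is_qc] <- frailty$fi_class[as.integer(sub("^S", "", layout$slot[!is_qc]))]

  log2m <- matrix(rep(base_log2, each = n_inj), n_inj, p)
  shift <- outer(class_of - 1, dir_sign * effect)   # zero on QC rows
  noise <- matrix(0, n_inj, p)
  noise[is_qc, ] <- stats::rnorm(sum(is_qc) * p, 0, design$qc_noise_sd)
  noise[!is_qc, ] <- stats::rnorm(sum(!is_qc) * p, 0, design$noise_sd)
  intens <- 2^(log2m + shift + noise) * drift

  if (design$missing_rate > 0) {
    intens[matrix(stats::runif(n_inj * p) < design$missing_rate, n_inj, p)] <- NA_real_
  }
  colnames(intens) <- fnames

  sample_id <- character(n_inj)
  sample_id[is_qc] <- sprintf("QC%03d", seq_len(sum(is_qc)))
  sample_id[!is_qc] <- frailty$subject_id[as.integer(sub("^S", "", layout$slot[!is_qc]))]

  out <- bind_cols(
    tibble(sample_id = sample_id,
           injection_order = layout$injection_order,
           batch = layout$batch,
           sample_type = ifelse(is_qc, "QC", "sample")),
    as_tibble(intens)
  )
  attr(out, "planted_features") <- if (is.null(planted)) character() else fnames[planted$feature]
  out
}

#' Configuration for simulated two-sample MR summary statistics
#'
#' @param n_snps Number of instruments.
#' @param true_causal_beta Causal effect (log-odds of outcome per unit of
#'   log-exposure).
#' @param instrument_strengths True per-SNP exposure effects; recycled to
#'   `n_snps`.
#' @param exposure_se,outcome_se Standard errors (scalar or per SNP), > 0.
#' @param ld_pairs Optional tibble `(snp_a, snp_b, r2)` of pairwise LD.
#' @param seed Integer seed.
#' @export
mr_sim_config <- function(n_snps = 4,
                          true_causal_beta = -0.5,
                          instrument_strengths = seq(0.1, 0.25, length.out = n_snps),
                          exposure_se = 0.01,
                          outcome_se = 0.05,
                          ld_pairs = NULL,
                          seed = 1L) {
  n_snps <- check_count(n_snps, "n_snps")
  exposure_se <- rep_len(exposure_se, n_snps)
  outcome_se <- rep_len(outcome_se, n_snps)
  if (any(exposure_se <= 0) || any(outcome_se <= 0)) abort("standard errors must be > 0")
  instrument_strengths <- rep_len(instrument_strengths, n_snps)
  if (!is.null(ld_pairs)) {
    ld_pairs <- as_tibble(ld_pairs)
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_pairs)))
    if (any(ld_pairs$r2 < 0 | ld_pairs$r2 > 1)) abort("r2 must be in [0, 1]")
  }
  structure(list(
    n_snps = n_snps, true_causal_beta = true_causal_beta,
    instrument_strengths = instrument_strengths,
    exposure_se = exposure_se, outcome_se = outcome_se,
    ld_pairs = ld_pairs, seed = as.integer(seed)
  ), class = "mr_sim_config")
}

#' Simulate per-SNP GWAS summary statistics under a causal model
#'
#' Exposure effects are the configured instrument strengths observed with
#' error; outcome effects are `true_causal_beta` times the true exposure
#' effect plus noise at `outcome_se`.
#'
#' @param config An [mr_sim_config()].
#' @return Tibble `(snp, beta_exp, se_exp, beta_out, se_out)` with the LD
#'   pair list attached as attribute `"ld"`.
#' @export
generate_mr_summary <- function(config = mr_sim_config()) {
  if (!inherits(config, "mr_sim_config")) abort("`config` must be an mr_sim_config")
  set.seed(derive_seed(config$seed, 3L))
  k <- config$n_snps
  gamma <- config$instrument_strengths
  out <- tibble(
    snp = sprintf("rs%07d", sample.int(9999999L, k)),
    beta_exp = gamma + stats::rnorm(k, 0, config$exposure_se),
    se_exp = config$exposure_se,
    beta_out = config$true_causal_beta * gamma + stats::rnorm(k, 0, config$outcome_se),
    se_out = config$outcome_se
  )
  ld <- config$ld_pairs
  if (!is.null(ld)) {
    ld$snp_a <- out$snp[ld$snp_a]
    ld$snp_b <- out$snp[ld$snp_b]
  }
  attr(out, "ld") <- ld
  out
}

#' Write a feature table (or any pipeline tibble) as delimited text
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param seed Optional seed recorded as a `# seed:` header comment.
#' @export
write_stage_table <- function(x, path, seed = NULL) {
  if (!is.null(seed)) {
    con <- file(path, "w")
    writeLines(sprintf("# seed: %d", as.integer(seed)), con)
    close(con)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Read a table written by [write_stage_table()]
#' @param path Input path.
#' @export
read_stage_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
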