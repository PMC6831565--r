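# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# Default synthetic study: n = 400 cohort, 200-feature run with planted
# carnitine/vitamin-E (down) and kynurenine-pathway (up) features, linear
# drift, corrected + filtered + log2-transformed.
default_run <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  cohort <- generate_cohort(cohort_config(n_subjects = 400, seed = 20L))
  frailty <- compute_fi(cohort$deficits)
  design <- run_design(n_samples = nrow(frailty),
                       planted = default_planted_features(n_features = 200),
                       n_features = 200, drift_model = "linear",
                       drift_amplitude = 0.3, seed = 20L)
  raw <- generate_feature_table(frailty, design)
  corrected <- qc_spline_correct(raw)
  filtered <- rsd_filter(corrected)
  logt <- log2_transform(filtered)
  samples <- logt[logt$sample_type == "sample", ]
  cls <- frailty$fi_class[match(samples$sample_id, frailty$subject_id)]
  X <- samples[feature_cols(samples)]
  Ximp <- X
  for (f in names(Ximp)) {
    Ximp[[f]][is.na(Ximp[[f]])] <- stats::median(Ximp[[f]], na.rm = TRUE)
  }
  .fixture_env$run <- list(
    cohort = cohort, frailty = frailty, design = design, raw = raw,
    corrected = corrected, logt = logt, X = X, Ximp = Ximp, cls = cls,
    frail = cls >= 3, planted = attr(raw, "planted_features")
  )
  .fixture_env$run
}

# Small two-class Gaussian instance used in several classifier tests.
two_class_toy <- function(n = 40, sep = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- tibble::tibble(
    f1 = stats::rnorm(n) + ifelse(y == "b", sep, 0),
    f2 = stats::rnorm(n)
  )
  list(X = X, y = y)
}
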