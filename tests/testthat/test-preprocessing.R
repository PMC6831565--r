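# A minimal hand-built feature table: explicit QC bracketing, one batch.
toy_table <- function(qc_vals, sample_vals, feature = "mz_200.0000_rt_100.0") {
  n_qc <- length(qc_vals); n_s <- length(sample_vals)
  tibble::tibble(
    sample_id = c(sprintf("QC%02d", seq_len(n_qc)), sprintf("S%02d", seq_len(n_s))),
    injection_order = seq_len(n_qc + n_s),
    batch = "B01",
    sample_type = c(rep("QC", n_qc), rep("sample", n_s)),
    !!feature := c(qc_vals, sample_vals)
  )
}

test_that("a flat QC profile leaves sample intensities unchanged", {
  tab <- tibble::tibble(
    sample_id = sprintf("X%02d", 1:12),
    injection_order = 1:12,
    batch = "B01",
    sample_type = rep(c("QC", "sample", "sample"), 4),
    mz_200.0000_rt_100.0 = ifelse(rep(c(TRUE, FALSE, FALSE), 4), 1000, 500)
  )
  out <- qc_spline_correct(tab)
  expect_equal(out$mz_200.0000_rt_100.0[tab$sample_type == "sample"],
               rep(500, 8), tolerance = 1e-8)
  expect_equal(out$mz_200.0000_rt_100.0[tab$sample_type == "QC"],
               rep(1000, 4), tolerance = 1e-8)
})

test_that("drift correction lowers QC RSD for nearly all features", {
  fr <- tibble::tibble(subject_id = sprintf("S%03d", 1:100),
                       fi = runif(100, 0, 0.4), fi_class = rep(1:4, 25))
  des <- run_design(n_samples = 100, n_features = 200, drift_model = "linear",
                    drift_amplitude = 0.3, missing_rate = 0, seed = 13)
  ft <- generate_feature_table(fr, des)
  out <- qc_spline_correct(ft)
  pre <- qc_rsd(ft)$rsd_pct
  post <- qc_rsd(out)$rsd_pct
  expect_gte(mean(post < pre, na.rm = TRUE), 0.95)
  # rescaling convention: corrected QC median equals the original QC median
  qc_pre <- ft[ft$sample_type == "QC", feature_cols(ft)]
  qc_post <- out[out$sample_type == "QC", feature_cols(out)]
  meds_pre <- vapply(qc_pre, stats::median, numeric(1))
  meds_post <- vapply(qc_post, stats::median, numeric(1))
  expect_equal(meds_post, meds_pre, tolerance = 1e-8)
})

test_that("features unseen in QCs are flagged and left unchanged", {
  tab <- tibble::tibble(
    sample_id = sprintf("X%02d", 1:10),
    injection_order = 1:10,
    batch = "B01",
    sample_type = rep(c("QC", "sample"), 5),
    mz_200.0000_rt_100.0 = c(NA, 500, NA, 510, NA, 490, NA, 505, NA, 495)
  )
  out <- qc_spline_correct(tab)
  expect_equal(out$mz_200.0000_rt_100.0, tab$mz_200.0000_rt_100.0)
  expect_match(attr(out, "uncorrected"), "mz_200.0000_rt_100.0")
})

test_that("RSD filter removes exactly the features crossing the threshold", {
  # constructed QC sets with known RSD: 5%, 19%, 25%
  mk <- function(rsd) {
    m <- 1000; s <- rsd / 100 * m
    # two-point set has SD |a-b|/sqrt(2); build symmetric pair exactly
    c(m - s / sqrt(2) * 1, m + s / sqrt(2) * 1)
  }
  tab <- tibble::tibble(
    sample_id = c("QC01", "QC02", "S01"),
    injection_order = 1:3, batch = "B01",
    sample_type = c("QC", "QC", "sample"),
    mz_100.0000_rt_10.0 = c(mk(5), 1),
    mz_200.0000_rt_20.0 = c(mk(19), 2),
    mz_300.0000_rt_30.0 = c(mk(25), 3)
  )
  expect_equal(qc_rsd(tab)$rsd_pct, c(5, 19, 25), tolerance = 1e-10)
  out <- rsd_filter(tab, threshold_pct = 20)
  expect_setequal(feature_cols(out),
                  c("mz_100.0000_rt_10.0", "mz_200.0000_rt_20.0"))
  rep_ <- attr(out, "removal_report")
  expect_equal(rep_$feature, "mz_300.0000_rt_30.0")
  expect_equal(rep_$rsd_pct, 25, tolerance = 1e-10)
  # bookkeeping: removed + retained = input
  expect_equal(nrow(rep_) + length(feature_cols(out)), 3)
  # vacuous threshold removes nothing
  expect_equal(length(feature_cols(rsd_filter(tab, threshold_pct = 100))), 3)
  # zero-variance QC feature is retained (RSD 0)
  tab$mz_300.0000_rt_30.0 <- c(100, 100, 1)
  expect_equal(length(feature_cols(rsd_filter(tab, 20))), 3)
})

test_that("log2 transform handles zeros by half-minimum and guards reapplication", {
  tab <- toy_table(c(8, 8, 8, 8), c(8, 1, 0))
  out <- log2_transform(tab)
  f <- feature_cols(tab)
  v <- out[[f]][out$sample_type == "sample"]
  expect_equal(v[1], 3)
  expect_equal(v[2], 0)
  expect_equal(v[3], log2(0.5))   # half of the smallest positive value (1)
  expect_error(log2_transform(out), "already")
  tab[[f]][2] <- -1
  expect_error(log2_transform(tab), "negative")
})

test_that("z-scoring is exact, idempotent and flags constants", {
  z <- zscore(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(zscore(z)$a, z$a)
  set.seed(2)
  z2 <- zscore(tibble::tibble(x = rnorm(50, 10, 3), label = letters[1:50 %% 26 + 1]))
  expect_lt(abs(mean(z2$x)), 1e-12)
  expect_lt(abs(stats::sd(z2$x) - 1), 1e-12)
  expect_identical(z2$label, letters[1:50 %% 26 + 1])
  zc <- zscore(tibble::tibble(a = rep(4, 5), b = 1:5))
  expect_equal(zc$a, rep(0, 5))
  expect_equal(attr(zc, "constant_columns"), "a")
})

test_that("chained-equations imputation is seeded and beats mean imputation", {
  full <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  expect_identical(impute_missing(full, seed = 1), full)

  mk_data <- function(seed) {
    set.seed(seed)
    n <- 80
    z <- rnorm(n)
    X <- tibble::tibble(a = z + rnorm(n, 0, 0.3), b = -z + rnorm(n, 0, 0.3),
                        c = 2 * z + rnorm(n, 0, 0.3))
    miss <- matrix(runif(n * 3) < 0.1, n, 3)
    Xm <- X
    for (j in 1:3) Xm[[j]][miss[, j]] <- NA
    list(X = X, Xm = Xm, miss = miss)
  }
  d <- mk_data(5)
  i1 <- impute_missing(d$Xm, seed = 42)
  i2 <- impute_missing(d$Xm, seed = 42)
  expect_identical(i1, i2)
  expect_false(identical(i1, impute_missing(d$Xm, seed = 43)))

  # over replicates, pooled PMM beats column-mean imputation in RMSE
  rmse <- function(imp, d) {
    sqrt(mean((as.matrix(imp)[d$miss] - as.matrix(d$X)[d$miss])^2))
  }
  wins <- vapply(1:100, function(i) {
    d <- mk_data(i)
    imp <- impute_missing(d$Xm, seed = i)
    mimp <- d$Xm
    for (j in 1:3) mimp[[j]][d$miss[, j]] <- mean(d$Xm[[j]], na.rm = TRUE)
    rmse(imp, d) < rmse(mimp, d)
  }, logical(1))
  expect_gt(mean(wins), 0.8)

  expect_error(impute_missing(tibble::tibble(a = rep(NA_real_, 4), b = 1:4)),
               "entirely missing")
})

test_that("Pearson panel flags correlated biomarkers with calibrated type I error", {
  fi <- seq(0, 1, length.out = 20)
  pp <- pearson_panel(tibble::tibble(up = 2 * fi + 1, down = -fi,
                                     flat = rep(1, 20)), fi)
  expect_equal(pp$r[pp$biomarker == "up"], 1, tolerance = 1e-12)
  expect_equal(pp$r[pp$biomarker == "down"], -1, tolerance = 1e-12)
  expect_true(is.na(pp$r[pp$biomarker == "flat"]))

  set.seed(14)
  hits <- vapply(1:1000, function(i) {
    pearson_panel(tibble::tibble(x = rnorm(100)), rnorm(100))$significant
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})
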