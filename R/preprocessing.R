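#' QC-based robust-spline signal drift correction
#'
#' For every feature within every batch, a cubic smoothing spline is fitted to
#' the pooled-QC intensities against injection order (smoothing chosen by
#' leave-one-out cross-validation over the QC points, bounded away from pure
#' interpolation). Each intensity in the batch is divided by the spline value
#' at its injection order and rescaled so that the batch QC median of the
#' feature is unchanged. Correction is multiplicative because MS drift is
#' predominantly gain-like. Predictions beyond the first/last QC injection are
#' clamped to the boundary spline values.
#'
#' Features with fewer than 4 non-missing QC intensities in a batch are left
#' uncorrected and flagged in the `"uncorrected"` attribute.
#'
#' @param table A feature table (see [generate_feature_table()] for the dialect).
#' @param min_qc Minimum non-missing QC points per batch to attempt a fit.
#' @return The corrected feature table; attributes `"uncorrected"` (character
#'   vector of skipped feature/batch combinations) and `"qc_corrected"` flag.
#' @export
qc_spline_correct <- function(table, min_qc = 4) {
  table <- as_tibble(table)
  stopifnot(all(.meta_cols %in% names(table)))
  feats <- feature_cols(table)
  out <- table
  skipped <- character()
  for (b in unique(table$batch)) {
    in_b <- table$batch == b
    qc_b <- in_b & table$sample_type == "QC"
    if (sum(qc_b) < min_qc) {
      warn(sprintf("batch %s has fewer than %d QC injections; batch left uncorrected", b, min_qc))
      skipped <- c(skipped, paste0(b, ":*"))
      next
    }
    ord_all <- table$injection_order[in_b]
    ord_qc <- table$injection_order[qc_b]
    for (f in feats) {
      yq <- table[[f]][qc_b]
      ok <- !is.na(yq)
      if (sum(ok) < min_qc) {
        skipped <- c(skipped, paste0(b, ":", f))
        next
      }
      sp <- tryCatch(
        stats::smooth.spline(ord_qc[ok], yq[ok], cv = TRUE,
                             control.spar = list(low = 0.2, high = 1.5)),
        error = function(e) NULL)
      if (is.null(sp)) { skipped <- c(skipped, paste0(b, ":", f)); next }
      # clamp to QC support, guard against non-positive spline values
      x_eval <- pmin(pmax(ord_all, min(ord_qc[ok])), max(ord_qc[ok]))
      pred <- stats::predict(sp, x_eval)$y
      med_qc <- stats::median(yq[ok])
      pred <- pmax(pred, 0.05 * med_qc)
      corrected <- table[[f]][in_b] / pred
      # rescale so the corrected QC median equals the original QC median
      ratio_qc <- corrected[table$sample_type[in_b] == "QC"]
      s <- med_qc / stats::median(ratio_qc, na.rm = TRUE)
      out[[f]][in_b] <- corrected * s
    }
  }
  attr(out, "uncorrected") <- unique(skipped)
  attr(out, "qc_corrected") <- TRUE
  out
}

#' Per-feature QC relative standard deviation
#'
#' @param table A feature table with QC rows.
#' @return Tibble `(feature, rsd_pct)`; `NA` where the QC mean is zero or
#'   fewer than two QC values exist.
#' @export
qc_rsd <- function(table) {
  qc <- table[table$sample_type == "QC", feature_cols(table), drop = FALSE]
  tibble(feature = names(qc),
         rsd_pct = unname(vapply(qc, rsd_pct, numeric(1))))
}

#' Filter features by QC relative standard deviation
#'
#' Removes every feature whose QC RSD exceeds `threshold_pct` (the
#' conventional untargeted-metabolomics cutoff is 20%). Features whose QC
#' mean is zero or undefined are removed and flagged. A removal report is
#' attached as attribute `"removal_report"`.
#'
#' @param table A (preferably drift-corrected) feature table with QC rows.
#' @param threshold_pct RSD threshold in percent; a feature at exactly the
#'   threshold is retained.
#' @return The filtered feature table.
#' @export
rsd_filter <- function(table, threshold_pct = 20) {
  rsd <- qc_rsd(table)
  drop_na <- is.na(rsd$rsd_pct)
  drop_hi <- !drop_na & rsd$rsd_pct > threshold_pct
  report <- tibble(
    feature = rsd$feature[drop_na | drop_hi],
    rsd_pct = rsd$rsd_pct[drop_na | drop_hi],
    reason = ifelse(is.na(rsd$rsd_pct[drop_na | drop_hi]),
                    "undefined QC RSD", sprintf("RSD > %g%%", threshold_pct))
  )
  keep <- rsd$feature[!(drop_na | drop_hi)]
  out <- table[c(.meta_cols, keep)]
  attr(out, "removal_report") <- report
  attr(out, "qc_corrected") <- attr(table, "qc_corrected")
  out
}

#' Log2-transform feature intensities
#'
#' Missing values stay missing; zeros are replaced by half the smallest
#' positive value of that feature before transforming (a common metabolomics
#' convention). Applying the transform twice is an error, guarded by a table
#' attribute.
#'
#' @param table A feature table.
#' @return The transformed table with attribute `"log2"` set.
#' @export
log2_transform <- function(table) {
  if (isTRUE(attr(table, "log2"))) abort("table is already log2-transformed")
  feats <- feature_cols(table)
  out <- table
  for (f in feats) {
    v <- table[[f]]
    if (any(v < 0, na.rm = TRUE)) abort(sprintf("negative intensity in feature %s", f))
    zero <- !is.na(v) & v == 0
    if (any(zero)) {
      minpos <- suppressWarnings(min(v[v > 0], na.rm = TRUE))
      if (!is.finite(minpos)) minpos <- 1
      v[zero] <- minpos / 2
    }
    out[[f]] <- log2(v)
  }
  attr(out, "log2") <- TRUE
  attr(out, "qc_corrected") <- attr(table, "qc_corrected")
  attr(out, "removal_report") <- attr(table, "removal_report")
  out
}

#' Z-score (autoscale) numeric columns
#'
#' Each numeric column is standardised to mean 0, sample SD 1 over its
#' non-missing entries. Zero-variance columns are returned as zeros and
#' flagged in attribute `"constant_columns"`.
#'
#' @param data A tibble; non-numeric columns pass through untouched.
#' @return The standardised tibble.
#' @export
zscore <- function(data) {
  data <- as_tibble(data)
  flagged <- character()
  out <- data
  for (nm in names(data)) {
    v <- data[[nm]]
    if (!is.numeric(v)) next
    n_ok <- sum(!is.na(v))
    if (n_ok < 2) { flagged <- c(flagged, nm); out[[nm]] <- ifelse(is.na(v), NA_real_, 0); next }
    s <- stats::sd(v, na.rm = TRUE)
    if (s == 0) { flagged <- c(flagged, nm); out[[nm]] <- ifelse(is.na(v), NA_real_, 0); next }
    out[[nm]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  attr(out, "constant_columns") <- flagged
  out
}

#' Seeded multiple imputation by chained equations
#'
#' Missing entries of each numeric variable are imputed by regressing it on
#' all other numeric variables (chained equations, iterated to stability)
#' with a predictive-mean-matching draw: each missing cell receives the
#' observed value of one of the `k` donors whose predicted means are closest.
#' Several completed tables are produced under sub-seeds derived from `seed`,
#' and the pooled table is the per-cell mean across imputations. Identical
#' seeds give identical output.
#'
#' @param data Tibble with an optional `subject_id` column and numeric
#'   biomarker columns; each variable must be < 50% missing and no variable
#'   all-missing.
#' @param n_imputations Number of completed tables (default 5).
#' @param n_iter Chained-equation sweeps per imputation (default 10).
#' @param k Number of predictive-mean-matching donors.
#' @param seed Integer seed.
#' @return The pooled tibble, with the list of completed tables in attribute
#'   `"imputations"`.
#' @export
impute_missing <- function(data, n_imputations = 5, n_iter = 10, k = 5, seed = 1L) {
  data <- as_tibble(data)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num) < 2) abort("need at least 2 numeric variables")
  X <- as.matrix(data[num])
  miss_frac <- colMeans(is.na(X))
  if (any(miss_frac >= 1)) abort(sprintf("variable '%s' is entirely missing", num[which(miss_frac >= 1)[1]]))
  if (any(miss_frac >= 0.5)) abort(sprintf("variable '%s' is >= 50%% missing", num[which(miss_frac >= 0.5)[1]]))
  miss <- is.na(X)
  if (!any(miss)) return(data)

  complete_one <- function(sub_seed) {
    set.seed(sub_seed)
    Z <- X
    for (j in seq_along(num)) if (any(miss[, j])) Z[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
    for (it in seq_len(n_iter)) {
      for (j in seq_along(num)) {
        mj <- miss[, j]
        if (!any(mj)) next
        fit <- stats::lm.fit(cbind(1, Z[!mj, -j, drop = FALSE]), X[!mj, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred_obs <- cbind(1, Z[!mj, -j, drop = FALSE]) %*% beta
        pred_mis <- cbind(1, Z[mj, -j, drop = FALSE]) %*% beta
        obs_vals <- X[!mj, j]
        # predictive mean matching: sample one of the k nearest donors
        for (i in seq_along(pred_mis)) {
          d <- abs(pred_obs - pred_mis[i])
          donors <- order(d)[seq_len(min(k, length(d)))]
          Z[which(mj)[i], j] <- obs_vals[sample(donors, 1)]
        }
      }
    }
    Z
  }

  imps <- lapply(seq_len(n_imputations), function(m) {
    complete_one(derive_seed(seed, 100L + m))
  })
  pooled <- Reduce(`+`, imps) / n_imputations
  out <- data
  for (j in seq_along(num)) out[[num[j]]] <- pooled[, j]
  attr(out, "imputations") <- lapply(imps, function(Z) {
    d <- data
    for (j in seq_along(num)) d[[num[j]]] <- Z[, j]
    d
  })
  out
}

#' Pearson correlation panel of biomarkers against the frailty index
#'
#' @param biomarkers Tibble of numeric biomarker columns (non-numeric columns
#'   are ignored).
#' @param fi Numeric FI vector aligned with the rows of `biomarkers`.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble `(biomarker, n, r, p, significant)`; constant biomarkers get
#'   `NA` correlation and are flagged `FALSE`.
#' @export
pearson_panel <- function(biomarkers, fi, alpha = 0.05) {
  biomarkers <- as_tibble(biomarkers)
  num <- names(biomarkers)[vapply(biomarkers, is.numeric, logical(1))]
  rows <- lapply(num, function(nm) {
    v <- biomarkers[[nm]]
    ok <- stats::complete.cases(v, fi)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(fi[ok]) == 0) {
      return(tibble(biomarker = nm, n = sum(ok), r = NA_real_, p = NA_real_,
                    significant = FALSE))
    }
    ct <- stats::cor.test(v[ok], fi[ok], method = "pearson")
    tibble(biomarker = nm, n = sum(ok), r = unname(ct$estimate),
           p = ct$p.value, significant = ct$p.value < alpha)
  })
  bind_rows(rows)
}
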