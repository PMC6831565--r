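# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_lgl map2 imap
NULL

# Columns of a feature table that are sample metadata, not features.
.meta_cols <- c("sample_id", "injection_order", "batch", "sample_type")

#' Feature (intensity) column names of a feature table
#' @param table A feature table.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), .meta_cols)
}

#' Parse feature identities from a feature table
#'
#' Feature columns are named `mz_<m/z>_rt_<seconds>`; this extracts the
#' numeric m/z and retention time for every feature column.
#'
#' @param table A feature table as produced by [generate_feature_table()].
#' @return A tibble with columns `feature`, `mz`, `rt`.
#' @export
feature_info <- function(table) {
  fc <- feature_cols(table)
  m <- stringr::str_match(fc, "^mz_([0-9.]+)_rt_([0-9.]+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("feature columns must be named 'mz_<value>_rt_<value>'; offending: ",
                 paste(utils::head(fc[is.na(m[, 1])], 3), collapse = ", ")))
  }
  tibble(feature = fc, mz = as.numeric(m[, 2]), rt = as.numeric(m[, 3]))
}

# Adjusted Fisher-Pearson sample skewness.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Relative standard deviation in percent; NA when the mean is zero or
# fewer than 2 values are available.
rsd_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  mu <- mean(x)
  if (mu == 0) return(NA_real_)
  100 * stats::sd(x) / mu
}

# Stratified fold assignment; guarantees each fold sees each class when
# every class has >= k members, otherwise aborts.
make_stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  if (any(table(y) < k)) {
    abort(sprintf("every class needs at least %d members for %d folds", k, k))
  }
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, closed_right = FALSE) {
  hi_ok <- if (closed_right) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in [0, 1%s", name,
                  if (closed_right) "]" else ")"))
  }
  x
}

# Derive a stream-specific 31-bit seed from a base seed, so that the
# generators consume independent streams under one user-facing seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + stream * 7919) %% 2147483647L
}
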