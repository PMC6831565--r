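#' Compute the deficit-accumulation frailty index
#'
#' The frailty index (FI) of a subject is the sum of their non-missing deficit
#' values divided by the number of items they answered. Subjects answering
#' fewer than `min_items` items are excluded from the result (the standard
#' inclusion rule is at least half of a 60-item panel) and reported via the
#' `"excluded"` attribute.
#'
#' @param deficits Tibble with `subject_id` and one column per deficit item;
#'   values in \[0, 1\] or `NA` for unanswered.
#' @param min_items Minimum number of answered items for inclusion.
#' @param edges Class bin edges passed on to [stratify_fi()].
#' @return Tibble `(subject_id, fi, n_answered, fi_class)` for included
#'   subjects, with attribute `"excluded"` listing the rest.
#' @export
compute_fi <- function(deficits, min_items = 30, edges = c(0.1, 0.2, 0.3)) {
  min_items <- check_count(min_items, "min_items")
  deficits <- as_tibble(deficits)
  if (!"subject_id" %in% names(deficits)) abort("`deficits` needs a subject_id column")
  items <- setdiff(names(deficits), "subject_id")
  if (length(items) == 0) abort("no deficit item columns found")
  vals <- as.matrix(deficits[items])
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("deficit value outside [0, 1] for subject '%s', item '%s'",
                  deficits$subject_id[bad[1, 1]], items[bad[1, 2]]))
  }
  n_answered <- rowSums(!is.na(vals))
  fi <- rowSums(vals, na.rm = TRUE) / pmax(n_answered, 1)
  res <- tibble(subject_id = deficits$subject_id, fi = fi, n_answered = n_answered)
  keep <- res$n_answered >= min_items
  out <- res[keep, ]
  out$fi_class <- stratify_fi(out$fi, edges = edges)
  attr(out, "excluded") <- res[!keep, ]
  out
}

#' Stratify frailty-index values into ordinal classes
#'
#' Bins are left-closed and right-open except the last: with the default
#' edges the classes are \[0, 0.1), \[0.1, 0.2), \[0.2, 0.3), \[0.3, 1\].
#' A value equal to an edge therefore falls in the higher class.
#'
#' @param fi Numeric FI values in \[0, 1\].
#' @param edges Strictly increasing cut points inside (0, 1); `k` edges give
#'   `k + 1` classes.
#' @return Integer class labels `1..k+1`.
#' @export
stratify_fi <- function(fi, edges = c(0.1, 0.2, 0.3)) {
  if (any(is.na(fi)) || any(fi < 0 | fi > 1)) abort("fi values must be in [0, 1]")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0 | edges >= 1)) {
    abort("`edges` must be strictly increasing and inside (0, 1)")
  }
  findInterval(fi, edges) + 1L
}

#' Robust linear regression of frailty index on age
#'
#' Fits FI ~ age by Huber M-estimation (tuning constant 1.345 times the MAD
#' residual scale, via iteratively reweighted least squares), so that a few
#' extreme subjects do not dominate the age trend. The fit statistics SSE and
#' R-squared are computed unweighted over all observations
#' (R^2 = 1 - SSE/SST), which makes the pair well-defined irrespective of the
#' robustness weights.
#'
#' @param data Tibble containing the regression variables.
#' @param age,fi Column names (strings) of the predictor and response.
#' @return An object of class `fi_fit` with elements `slope`, `intercept`,
#'   `sse`, `r_squared`, `weights`, and the underlying `rlm` fit.
#' @export
fit_fi_regression <- function(data, age = "age", fi = "fi") {
  data <- as_tibble(data)
  x <- data[[age]]; y <- data[[fi]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0) abort("degenerate design: age is constant")
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 100)
  resid <- y - stats::fitted(fit)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sse = sse,
    r_squared = 1 - sse / sst,
    weights = fit$w,
    n = length(x),
    fit = fit,
    data = tibble(age = x, fi = y)
  ), class = "fi_fit")
}

#' @export
print.fi_fit <- function(x, ...) {
  cat("Robust FI ~ age regression (Huber M-estimation)\n")
  cat(sprintf("  slope      %.6f FI/year\n", x$slope))
  cat(sprintf("  intercept  %.6f\n", x$intercept))
  cat(sprintf("  SSE        %.4f\n  R-squared  %.4f  (n = %d)\n",
              x$sse, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fi_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "age"),
         estimate = c(x$intercept, x$slope),
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"])
}

#' @export
glance.fi_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sse = x$sse, nobs = x$n,
         min.weight = min(x$weights))
}

#' Summarise a frailty-index distribution
#'
#' @param fi Numeric FI values.
#' @param edges Class edges for per-class proportions.
#' @return One-row tibble with `n`, `min`, `max`, `mean`, `skewness` and one
#'   `prop_class*` column per class; proportions sum to 1.
#' @export
fi_distribution_summary <- function(fi, edges = c(0.1, 0.2, 0.3)) {
  if (length(fi) == 0) abort("`fi` must be nonempty")
  cls <- stratify_fi(fi, edges)
  props <- tabulate(cls, nbins = length(edges) + 1) / length(fi)
  names(props) <- paste0("prop_class", seq_along(props))
  bind_cols(
    tibble(n = length(fi), min = min(fi), max = max(fi), mean = mean(fi),
           skewness = sample_skewness(fi)),
    as_tibble(as.list(props))
  )
}

#' Plot a frailty-index distribution with class boundaries
#' @param fi Numeric FI values.
#' @param edges Class edges drawn as dashed lines.
#' @param bins Histogram bin count.
#' @export
plot_fi_distribution <- function(fi, edges = c(0.1, 0.2, 0.3), bins = 40) {
  ggplot2::ggplot(tibble(fi = fi), ggplot2::aes(x = .data$fi)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = edges, linetype = "dashed") +
    ggplot2::labs(x = "Frailty index", y = "Subjects") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fi_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$fi)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "Age (years)", y = "Frailty index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
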