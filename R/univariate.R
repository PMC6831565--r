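#' Mann-Whitney panel across a frail / non-frail split
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between the
#' two groups, typically samples below vs at-or-above 0.2 on the frailty
#' index. The exact null distribution is enumerated when both groups have at
#' most 8 untied observations; otherwise the normal approximation with tie
#' correction (no continuity correction) is used. Benjamini-Hochberg
#' q-values are appended. The `direction` column is the sign of
#' (group-2 mean minus group-1 mean) on the supplied (log2) scale.
#'
#' @param X Tibble/matrix of samples x features (log2 intensities).
#' @param group Two-level factor or logical, `TRUE`/second level = frail.
#' @return Tibble `(feature, statistic, p, q, direction, tested)`.
#' @export
mann_whitney_panel <- function(X, group) {
  X <- as_tibble(X)
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("`group` must have exactly 2 levels")
  lv <- levels(g)
  rows <- lapply(names(X), function(f) {
    v <- X[[f]]
    a <- v[g == lv[1] & !is.na(v)]
    b <- v[g == lv[2] & !is.na(v)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(feature = f, statistic = NA_real_, p = NA_real_,
                    direction = NA_real_, tested = FALSE))
    }
    if (length(unique(c(a, b))) == 1) {
      # fully tied data carry no rank information
      return(tibble(feature = f, statistic = length(a) * length(b) / 2,
                    p = 1, direction = 0, tested = TRUE))
    }
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(b, a, exact = exact, correct = FALSE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1
    tibble(feature = f, statistic = unname(wt$statistic), p = min(p, 1),
           direction = sign(mean(b) - mean(a)), tested = TRUE)
  })
  out <- bind_rows(rows)
  out$q <- NA_real_
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  out[c("feature", "statistic", "p", "q", "direction", "tested")]
}

#' Kruskal-Wallis panel across frailty classes
#'
#' Tie-corrected H statistic per feature with a chi-square reference on
#' (classes - 1) degrees of freedom, plus Benjamini-Hochberg q-values.
#' Direction is the sign of the difference between the top-class and
#' bottom-class means.
#'
#' @param X Tibble/matrix of samples x features.
#' @param classes Ordinal class labels; >= 2 classes with >= 2 members each.
#' @return Tibble `(feature, statistic, p, q, direction, tested)`.
#' @export
kruskal_panel <- function(X, classes) {
  X <- as_tibble(X)
  g <- droplevels(as.factor(classes))
  if (nlevels(g) < 2) abort("need at least 2 classes")
  lv <- levels(g)
  rows <- lapply(names(X), function(f) {
    v <- X[[f]]
    ok <- !is.na(v)
    gg <- droplevels(g[ok])
    if (nlevels(gg) < 2 || any(table(gg) < 2)) {
      return(tibble(feature = f, statistic = NA_real_, p = NA_real_,
                    direction = NA_real_, tested = FALSE))
    }
    kt <- stats::kruskal.test(v[ok], gg)
    lo <- v[ok][gg == levels(gg)[1]]
    hi <- v[ok][gg == levels(gg)[nlevels(gg)]]
    tibble(feature = f,
           statistic = if (is.nan(kt$statistic)) 0 else unname(kt$statistic),
           p = if (is.nan(kt$p.value)) 1 else kt$p.value,
           direction = sign(mean(hi) - mean(lo)), tested = TRUE)
  })
  out <- bind_rows(rows)
  out$q <- NA_real_
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  out[c("feature", "statistic", "p", "q", "direction", "tested")]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_(i) = min_(j>=i) m p_(j) / j`, clipped at 1 and
#' returned in input order.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise feature correlation with hierarchical leaf ordering
#'
#' Pairwise (default Spearman) correlations between features, plus an
#' average-linkage hierarchical clustering on distance `1 - r` whose leaf
#' order groups co-varying metabolites for heatmap display. Constant
#' features get zero correlation and are flagged.
#'
#' @param X Samples x features.
#' @param method `"spearman"` or `"pearson"`.
#' @return A `correlation_heatmap` object: `cor` (matrix), `leaf_order`,
#'   `constant`, `method`.
#' @export
correlation_heatmap <- function(X, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  X <- as_tibble(X)
  if (nrow(X) < 3) abort("need at least 3 samples")
  constant <- names(X)[vapply(X, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                                sum(!is.na(v)) < 2, logical(1))]
  cm <- suppressWarnings(stats::cor(as.matrix(X), method = method,
                                    use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  structure(list(cor = cm, leaf_order = colnames(cm)[hc$order],
                 constant = constant, method = method, hclust = hc),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat(sprintf("%s correlation over %d features; leaf order: %s ...\n",
              x$method, ncol(x$cor),
              paste(utils::head(x$leaf_order, 3), collapse = ", ")))
  invisible(x)
}

#' @export
autoplot.correlation_heatmap <- function(object, ...) {
  ord <- object$leaf_order
  df <- as.data.frame(as.table(object$cor[ord, ord]))
  names(df) <- c("f1", "f2", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$f2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = object$method) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
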