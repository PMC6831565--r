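#' Rank-based area under the ROC curve
#'
#' Equal to the normalised Mann-Whitney U statistic; tied score pairs count
#' one half.
#'
#' @param scores Numeric classification scores (higher = more positive).
#' @param labels Logical or two-level factor; `TRUE`/second level = positive.
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PLS-DA with VIP feature ranking
#'
#' Partial least squares (NIPALS, single 0/1 response) on the autoscaled
#' matrix. Features are ranked by Variable Importance in Projection (VIP),
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' whose squared mean over features is 1 by construction. Ties are broken by
#' feature index. Components whose score variance collapses are dropped with
#' a warning (n_lv reduced).
#'
#' @param X Samples x features.
#' @param y Two-level labels (second level / `TRUE` = positive class).
#' @param n_lv Number of latent variables (default 7, the conventional
#'   choice for serum metabolomics classifiers).
#' @param autoscale Autoscale features before fitting.
#' @return A `pls_model` with `vip`, `ranking`, weights/loadings/scores and
#'   regression vector for prediction.
#' @export
plsda_rank <- function(X, y, n_lv = 7, autoscale = TRUE) {
  X <- as.matrix(as_tibble(X))
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.numeric(y)
  if (length(unique(y)) != 2) abort("`y` must have two levels")
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- if (autoscale) apply(X, 2, stats::sd) else rep(1, p)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y_mean <- mean(y)
  u <- y - y_mean
  E <- Xs; f <- u
  W <- P <- matrix(0, p, 0); Tm <- matrix(0, n, 0); qv <- numeric(0)
  a_max <- min(n_lv, n - 1, p)
  for (a in seq_len(a_max)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pv <- crossprod(E, t_) / tt
    q <- sum(f * t_) / tt
    E <- E - t_ %*% t(pv)
    f <- f - q * t_
    W <- cbind(W, w); P <- cbind(P, pv); Tm <- cbind(Tm, t_); qv <- c(qv, q)
  }
  if (ncol(W) < n_lv) {
    warn(sprintf("latent variables reduced from %d to %d (rank limit)",
                 n_lv, ncol(W)))
  }
  ssy <- qv^2 * colSums(Tm^2)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  vip <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  ranking <- order(-vip, seq_len(p))
  beta <- W %*% solve(crossprod(P, W), qv)
  structure(list(
    n_lv = ncol(W), weights = W, loadings = P, scores = Tm, q = qv,
    vip = vip, ranking = ranking, feature_names = colnames(X),
    center = ctr, scale = scl, y_mean = y_mean, beta = beta
  ), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(as_tibble(newdata))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.numeric(Xs %*% object$beta + object$y_mean)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d latent variables, %d features\n",
              x$n_lv, length(x$vip)))
  cat("top features by VIP:",
      paste(utils::head(x$feature_names[x$ranking], 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(feature = x$feature_names %||% as.character(seq_along(x$vip)),
         vip = x$vip, rank = match(seq_along(x$vip), x$ranking))
}

#' Multivariate ROC via Monte-Carlo cross-validation
#'
#' Each repetition balances the groups by undersampling the majority class to
#' the minority count, splits the balanced set 2/3 train : 1/3 test
#' (stratified), ranks features on the training part by PLS-DA VIP, refits a
#' PLS-DA model on the `top_k` features and scores the held-out third. The
#' mean ROC curve is the vertical average of per-repetition curves on a
#' 101-point FPR grid; the AUC confidence interval is the 2.5/97.5 percentile
#' of repetition AUCs (or, with `ci_method = "bootstrap"`, of bootstrap means
#' of the repetition AUCs).
#'
#' @param X Samples x features.
#' @param y Two-level labels (second level = positive/frail).
#' @param top_k Features carried into the classifier (default 12).
#' @param reps Monte-Carlo repetitions (default 500).
#' @param train_frac Training fraction (default 2/3).
#' @param n_lv Latent variables for both ranking and classification.
#' @param ci_method `"percentile"` or `"bootstrap"`.
#' @param n_boot Bootstrap draws when `ci_method = "bootstrap"`.
#' @param seed Integer seed.
#' @return An `mroc_result`: `auc`, `auc_ci`, `rep_aucs`, `mean_curve`
#'   (tibble: fpr, tpr), `selection_freq` (tibble: feature, freq).
#' @export
mccv_roc <- function(X, y, top_k = 12, reps = 500, train_frac = 2 / 3,
                     n_lv = 7, ci_method = c("percentile", "bootstrap"),
                     n_boot = 1000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  X <- as.matrix(as_tibble(X))
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.logical(y)
  if (sum(y) < 4 || sum(!y) < 4) abort("both classes need at least 4 members")
  if (top_k > ncol(X)) abort("`top_k` exceeds the number of features")
  set.seed(derive_seed(seed, 12L))
  grid <- seq(0, 1, length.out = 101)
  curves <- matrix(NA_real_, reps, length(grid))
  rep_aucs <- numeric(reps)
  sel_count <- integer(ncol(X))
  max_redraw <- 20L
  for (r in seq_len(reps)) {
    redraw <- 0L
    repeat {
      # balance by undersampling the majority class
      pos <- which(y); neg <- which(!y)
      m <- min(length(pos), length(neg))
      pos <- if (length(pos) > m) sample(pos, m) else pos
      neg <- if (length(neg) > m) sample(neg, m) else neg
      idx <- c(pos, neg)
      tr <- c(sample(pos, round(train_frac * m)), sample(neg, round(train_frac * m)))
      te <- setdiff(idx, tr)
      ok <- length(unique(y[te])) == 2 && length(unique(y[tr])) == 2
      if (ok || redraw >= max_redraw) break
      redraw <- redraw + 1L
    }
    # a repetition may not support all n_lv components; the reduction
    # inside plsda_rank is routine here, so its warning is muffled
    quiet_lv <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        if (grepl("latent variables reduced", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    }
    rank_fit <- quiet_lv(plsda_rank(X[tr, , drop = FALSE], y[tr],
                                    n_lv = min(n_lv, length(tr) - 1)))
    top <- rank_fit$ranking[seq_len(top_k)]
    sel_count[top] <- sel_count[top] + 1L
    fit <- quiet_lv(plsda_rank(X[tr, top, drop = FALSE], y[tr],
                               n_lv = min(n_lv, top_k, length(tr) - 1)))
    sc <- predict(fit, X[te, top, drop = FALSE])
    rep_aucs[r] <- auc(sc, y[te])
    curves[r, ] <- .tpr_at_fpr(sc, y[te], grid)
  }
  mean_auc <- mean(rep_aucs)
  ci <- if (ci_method == "percentile") {
    stats::quantile(rep_aucs, c(0.025, 0.975), names = FALSE)
  } else {
    bm <- vapply(seq_len(n_boot), function(b) {
      mean(sample(rep_aucs, reps, replace = TRUE))
    }, numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  fn <- colnames(X) %||% as.character(seq_len(ncol(X)))
  structure(list(
    auc = mean_auc, auc_ci = ci, rep_aucs = rep_aucs,
    mean_curve = tibble(fpr = grid, tpr = colMeans(curves)),
    selection_freq = tibble(feature = fn, freq = sel_count / reps) |>
      arrange(desc(.data$freq)),
    top_k = top_k, reps = reps, ci_method = ci_method
  ), class = "mroc_result")
}

# TPR at fixed FPR values by linear interpolation of the empirical ROC.
.tpr_at_fpr <- function(scores, labels, grid) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  tpr <- c(0, tp / sum(labels)); fpr <- c(0, fp / sum(!labels))
  stats::approx(fpr, tpr, xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

#' @export
print.mroc_result <- function(x, ...) {
  cat(sprintf("mROC (%d MCCV repetitions, top %d features): AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$reps, x$top_k, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
glance.mroc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$auc_ci[1], ci_high = x$auc_ci[2],
         reps = x$reps, top_k = x$top_k)
}

#' @export
autoplot.mroc_result <- function(object, ...) {
  ggplot2::ggplot(object$mean_curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::annotate("text", x = 0.7, y = 0.15,
                      label = sprintf("AUC = %.3f (%.3f-%.3f)", object$auc,
                                      object$auc_ci[1], object$auc_ci[2])) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
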