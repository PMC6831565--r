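#' Principal-component discriminant-function analysis (PC-DFA)
#'
#' PCA (by singular value decomposition of the centred, optionally autoscaled
#' matrix) reduces the feature space to `pc_count` components; Fisher
#' canonical discriminant analysis is then performed on the component scores:
#' discriminant directions are the leading eigenvectors of
#' \eqn{W^{-1} B}, where `W` and `B` are the within- and between-class
#' scatter matrices of the scores. Discriminant functions are ordered by
#' decreasing between/within variance ratio; at most `n_classes - 1` are
#' returned. A singular within-scatter matrix is ridge-regularised
#' (1e-8 x trace/dim on the diagonal) and the event is recorded.
#'
#' @param X Numeric matrix or tibble of samples x features.
#' @param y Class labels (coercible to factor); every class needs >= 2 members.
#' @param pc_count Retained components; default: smallest number explaining
#'   >= 95% of variance, capped at 50.
#' @param autoscale Scale features to unit variance before PCA.
#' @return A `pc_dfa` object with `scores` (tibble: `sample`, `class`,
#'   `DF1..`), `pc_loadings`, `df_weights`, `class_means`, `eigenvalues`.
#' @export
pc_dfa <- function(X, y, pc_count = NULL, autoscale = FALSE) {
  X <- as.matrix(as_tibble(X))
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("need at least 2 classes")
  if (any(table(y) < 2)) abort("every class needs at least 2 members")
  if (nrow(X) != length(y)) abort("X rows and y length differ")

  pca <- stats::prcomp(X, center = TRUE, scale. = autoscale)
  if (is.null(pc_count)) {
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    pc_count <- min(which(cum >= 0.95), 50L)
  }
  pc_count <- min(pc_count, ncol(pca$x), nrow(X) - 1L)
  Tm <- pca$x[, seq_len(pc_count), drop = FALSE]

  g <- nlevels(y)
  mu <- colMeans(Tm)
  W <- matrix(0, pc_count, pc_count)
  B <- matrix(0, pc_count, pc_count)
  for (cl in levels(y)) {
    idx <- y == cl
    mc <- colMeans(Tm[idx, , drop = FALSE])
    Xc <- sweep(Tm[idx, , drop = FALSE], 2, mc)
    W <- W + crossprod(Xc)
    B <- B + sum(idx) * tcrossprod(mc - mu)
  }
  regularised <- FALSE
  rc <- rcond(W)
  if (!is.finite(rc) || rc < 1e-12) {
    # ridge floor handles the fully degenerate case (zero within-scatter)
    W <- W + diag(max(1e-8 * sum(diag(W)) / pc_count, 1e-10), pc_count)
    regularised <- TRUE
    inform("within-class scatter was singular; ridge regularisation applied")
  }
  eg <- eigen(solve(W, B))
  keep <- seq_len(min(g - 1L, pc_count))
  evals <- Re(eg$values)[keep]
  A <- Re(eg$vectors)[, keep, drop = FALSE]
  # fix sign: largest-magnitude loading positive, for reproducible output
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  S <- Tm %*% A
  colnames(S) <- paste0("DF", seq_len(ncol(S)))
  cm <- stats::aggregate(S, list(class = y), mean)
  structure(list(
    scores = bind_cols(tibble(sample = seq_len(nrow(S)), class = y), as_tibble(S)),
    pc_loadings = pca$rotation[, seq_len(pc_count), drop = FALSE],
    pc_count = pc_count,
    df_weights = A,
    eigenvalues = evals,
    class_means = as_tibble(cm),
    center = pca$center,
    scale = if (autoscale) pca$scale else NULL,
    regularised = regularised,
    y = y
  ), class = "pc_dfa")
}

#' @export
print.pc_dfa <- function(x, ...) {
  cat(sprintf("PC-DFA: %d PCs, %d discriminant functions, %d classes\n",
              x$pc_count, length(x$eigenvalues), nlevels(x$y)))
  cat("between/within eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

# Project new samples through a fitted PC-DFA model.
project_pc_dfa <- function(model, X) {
  X <- as.matrix(as_tibble(X))
  Xc <- sweep(X, 2, model$center)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  S <- (Xc %*% model$pc_loadings) %*% model$df_weights
  colnames(S) <- paste0("DF", seq_len(ncol(S)))
  S
}

#' @export
autoplot.pc_dfa <- function(object, ...) {
  sc <- object$scores
  if (!"DF2" %in% names(sc)) sc$DF2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$DF1, y = .data$DF2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = "DF1", y = "DF2", colour = "FI class") +
    ggplot2::theme_minimal()
}

#' Bootstrap validation of a PC-DFA ordination
#'
#' Refits the model on stratified bootstrap resamples (drawn with replacement
#' within each class, preserving the supervisory design), projects the
#' held-out (out-of-bag) samples through each refit, and summarises the
#' dispersion of per-class centroids. Discriminant axes of each refit are
#' sign-aligned to the full-data model. Degenerate resamples are redrawn
#' (count reported).
#'
#' @inheritParams pc_dfa
#' @param n_boot Number of bootstrap resamples (>= 100; population studies
#'   conventionally use 10,000, reduce for interactive work).
#' @param seed Integer seed.
#' @return A `pc_dfa_boot` object: `centroids` (tibble: `boot`, `class`,
#'   `DF*`), `dispersion` (per-class centroid SD), `model` (full-data fit),
#'   `redraws`.
#' @export
bootstrap_pc_dfa <- function(X, y, n_boot = 1000, pc_count = NULL,
                             autoscale = FALSE, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  X <- as.matrix(as_tibble(X))
  y <- droplevels(as.factor(y))
  full <- pc_dfa(X, y, pc_count = pc_count, autoscale = autoscale)
  full_scores <- as.matrix(full$scores[paste0("DF", seq_along(full$eigenvalues))])
  set.seed(derive_seed(seed, 4L))
  n <- nrow(X)
  redraws <- 0L
  cents <- vector("list", n_boot)
  class_idx <- split(seq_len(n), y)
  for (b in seq_len(n_boot)) {
    repeat {
      # stratified bootstrap: resample within class, preserving the design
      idx <- unlist(lapply(class_idx, function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      if (nlevels(droplevels(y[idx])) == nlevels(y) &&
          all(table(y[idx]) >= 2)) break
      redraws <- redraws + 1L
    }
    fit_b <- pc_dfa(X[idx, , drop = FALSE], y[idx],
                    pc_count = full$pc_count, autoscale = autoscale)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < nlevels(y)) oob <- seq_len(n)   # degenerate resample
    S <- project_pc_dfa(fit_b, X)
    # sign-align each axis to the full-data model
    kk <- min(ncol(S), ncol(full_scores))
    for (j in seq_len(kk)) {
      if (stats::cor(S[, j], full_scores[, j]) < 0) S[, j] <- -S[, j]
    }
    So <- S[oob, , drop = FALSE]
    cm <- stats::aggregate(So, list(class = droplevels(y[oob])), mean)
    cm$boot <- b
    cents[[b]] <- as_tibble(cm)
  }
  centroids <- bind_rows(cents)
  disp <- centroids |>
    group_by(.data$class) |>
    summarise(across(starts_with("DF"), \(v) stats::sd(v), .names = "sd_{.col}"),
              .groups = "drop")
  structure(list(centroids = centroids, dispersion = disp, model = full,
                 redraws = redraws, n_boot = n_boot),
            class = "pc_dfa_boot")
}

#' @export
print.pc_dfa_boot <- function(x, ...) {
  cat(sprintf("PC-DFA bootstrap: %d resamples (%d redrawn)\n", x$n_boot, x$redraws))
  print(x$dispersion)
  invisible(x)
}

# ---- RUSBoost ---------------------------------------------------------------

# Class-probability matrix from an rpart fit, columns in `classes` order.
.rpart_prob <- function(tree, newdata, classes) {
  pr <- stats::predict(tree, newdata = newdata, type = "prob")
  out <- matrix(0, nrow(newdata), length(classes), dimnames = list(NULL, classes))
  out[, colnames(pr)] <- pr
  out
}

#' Train a RUSBoost ensemble of CART trees
#'
#' Boosting for class-imbalanced data: each round draws a random undersample
#' of the majority classes down to the minority-class count (sampling
#' probability proportional to current example weight), fits a depth-limited
#' CART, and updates weights by the AdaBoost.M2 pseudo-loss scheme. The final
#' prediction is the class with the largest sum of `log(1/beta_t)`-weighted
#' probability votes. A round whose pseudo-loss reaches 0.5 is discarded and
#' redrawn (bounded retries); training stops early if retries are exhausted.
#'
#' @param X Samples x features (matrix or tibble).
#' @param y Class labels; minority class needs >= 2 members.
#' @param n_learners Boosting rounds.
#' @param tree_depth Maximum CART depth.
#' @param learn_rate Shrinkage applied to the weight updates and votes.
#' @param undersample Set `FALSE` to disable undersampling (plain AdaBoost.M2).
#' @param seed Integer seed.
#' @return A `rusboost` object.
#' @export
rusboost_train <- function(X, y, n_learners = 50, tree_depth = 3,
                           learn_rate = 0.1, undersample = TRUE, seed = 1L) {
  X <- as_tibble(X)
  names(X) <- make.names(names(X))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("need at least 2 classes")
  if (min(table(y)) < 2) abort("minority class needs at least 2 members")
  set.seed(derive_seed(seed, 5L))
  n <- nrow(X); classes <- levels(y); K <- length(classes)
  df <- X; df$.y <- y
  D <- matrix(1 / (n * (K - 1)), n, K, dimnames = list(NULL, classes))
  for (i in seq_len(n)) D[i, as.character(y[i])] <- 0   # mislabel distribution
  m_min <- min(table(y))
  trees <- list(); betas <- numeric()
  ctl <- rpart::rpart.control(maxdepth = tree_depth, cp = 0, minsplit = 2,
                              minbucket = 1, xval = 0, maxsurrogate = 0,
                              maxcompete = 0)
  t <- 0L
  while (t < n_learners) {
    ok <- FALSE
    for (try in 1:5) {
      w <- rowSums(D)
      if (undersample) {
        sel <- integer()
        for (cl in classes) {
          idx <- which(y == cl)
          if (length(idx) <= m_min) sel <- c(sel, idx)
          else {
            pr <- w[idx]
            if (sum(pr) <= 0) pr <- rep(1, length(idx))
            sel <- c(sel, sample(idx, m_min, prob = pr))
          }
        }
      } else sel <- seq_len(n)
      wsel <- w[sel]
      if (sum(wsel) <= 0) wsel <- rep(1, length(sel))
      tree <- rpart::rpart(.y ~ ., data = df[sel, , drop = FALSE],
                           weights = wsel / mean(wsel), method = "class",
                           control = ctl)
      h <- .rpart_prob(tree, df, classes)
      h_true <- h[cbind(seq_len(n), match(as.character(y), classes))]
      eps <- 0.5 * sum(D * (1 - h_true + h))
      if (eps < 0.5) { ok <- TRUE; break }
    }
    if (!ok) break
    eps <- max(eps, 1e-10)
    beta <- eps / (1 - eps)
    expo <- 0.5 * (1 + h_true - h)         # n x K
    D <- D * beta^(learn_rate * expo)
    D <- D / sum(D)
    t <- t + 1L
    trees[[t]] <- tree
    betas[t] <- beta
  }
  if (t == 0L) abort("no usable boosting round (pseudo-loss >= 0.5 throughout)")
  structure(list(trees = trees, betas = betas, classes = classes,
                 learn_rate = learn_rate, feature_names = names(X)),
            class = "rusboost")
}

#' Predict classes (or vote matrix) from a RUSBoost ensemble
#' @param object A [rusboost_train()] fit.
#' @param newdata Samples x features.
#' @param type `"class"` or `"votes"`.
#' @param ... Unused.
#' @export
predict.rusboost <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  newdata <- as_tibble(newdata)
  names(newdata) <- make.names(names(newdata))
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (t in seq_along(object$trees)) {
    w <- object$learn_rate * log(1 / object$betas[t])
    votes <- votes + w * .rpart_prob(object$trees[[t]], newdata, object$classes)
  }
  if (type == "votes") return(votes)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

#' Classification report from true and predicted labels
#' @param truth,pred Factors over the same class set.
#' @return A `classification_report` with `confusion`, `correct_rate`,
#'   `per_class_recall`.
#' @export
classification_report <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, predicted = pred)
  structure(list(
    confusion = cm,
    correct_rate = sum(diag(cm)) / sum(cm),
    per_class_recall = diag(cm) / pmax(rowSums(cm), 1)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Correct classification rate: %.3f\n", x$correct_rate))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  as_tibble(as.data.frame(x$confusion))
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble(correct_rate = x$correct_rate, n = sum(x$confusion),
         n_classes = nrow(x$confusion))
}

#' @export
autoplot.classification_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "firebrick") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count") +
    ggplot2::theme_minimal()
}

#' Double cross-validated RUSBoost classification
#'
#' Outer stratified folds provide unbiased predictions; inner folds on each
#' outer-training set select the ensemble size and tree depth from `grid`.
#' The confusion matrix is assembled from outer-fold predictions only.
#' Optionally, bootstrap refits on the outer-training folds estimate the
#' stability of the correct-classification rate.
#'
#' @inheritParams rusboost_train
#' @param outer_folds,inner_folds Fold counts (>= 2).
#' @param grid Tibble of candidate `(n_learners, tree_depth)` rows.
#' @param n_boot Bootstrap refits per outer fold for stability (0 = skip).
#' @param seed Integer seed.
#' @return A `classification_report` with extra elements `chosen` (per-fold
#'   selected parameters) and `boot_rates` if requested.
#' @export
rusboost_2cv <- function(X, y, outer_folds = 3, inner_folds = 2,
                         grid = tibble(n_learners = c(20, 50), tree_depth = c(2, 3)),
                         learn_rate = 0.1, n_boot = 0, seed = 1L) {
  X <- as_tibble(X)
  y <- droplevels(as.factor(y))
  grid <- as_tibble(grid)
  folds <- make_stratified_folds(y, outer_folds, seed = derive_seed(seed, 6L))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  chosen <- list(); boot_rates <- numeric()
  for (fo in seq_len(outer_folds)) {
    tr <- folds != fo
    inner <- make_stratified_folds(y[tr], inner_folds,
                                   seed = derive_seed(seed, 60L + fo))
    inner_rate <- vapply(seq_len(nrow(grid)), function(gi) {
      rates <- vapply(seq_len(inner_folds), function(fi) {
        itr <- inner != fi
        fit <- rusboost_train(X[tr, ][itr, ], y[tr][itr],
                              n_learners = grid$n_learners[gi],
                              tree_depth = grid$tree_depth[gi],
                              learn_rate = learn_rate,
                              seed = derive_seed(seed, 600L + 10L * fo + fi))
        mean(predict(fit, X[tr, ][!itr, ]) == y[tr][!itr])
      }, numeric(1))
      mean(rates)
    }, numeric(1))
    best <- which.max(inner_rate)
    chosen[[fo]] <- tibble(fold = fo, n_learners = grid$n_learners[best],
                           tree_depth = grid$tree_depth[best],
                           inner_rate = inner_rate[best])
    fit <- rusboost_train(X[tr, ], y[tr],
                          n_learners = grid$n_learners[best],
                          tree_depth = grid$tree_depth[best],
                          learn_rate = learn_rate,
                          seed = derive_seed(seed, 6000L + fo))
    pred[!tr] <- predict(fit, X[!tr, ])
    if (n_boot > 0) {
      set.seed(derive_seed(seed, 7000L + fo))
      idx_tr <- which(tr)
      for (b in seq_len(n_boot)) {
        repeat {
          bs <- sample(idx_tr, length(idx_tr), replace = TRUE)
          if (all(table(y[bs]) >= 2) &&
              nlevels(droplevels(y[bs])) == nlevels(y)) break
        }
        fb <- rusboost_train(X[bs, ], y[bs],
                             n_learners = grid$n_learners[best],
                             tree_depth = grid$tree_depth[best],
                             learn_rate = learn_rate,
                             seed = derive_seed(seed, 8000L + 100L * fo + b))
        boot_rates <- c(boot_rates, mean(predict(fb, X[!tr, ]) == y[!tr]))
      }
    }
  }
  rep_ <- classification_report(y, pred)
  rep_$chosen <- bind_rows(chosen)
  if (n_boot > 0) rep_$boot_rates <- boot_rates
  rep_
}

#' Permutation null distribution for a classification statistic
#'
#' Recomputes the correct-classification rate under `n_perm` random label
#' permutations using the same cross-validated procedure as the observed
#' statistic, and reports the permutation p-value
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param X Samples x features.
#' @param y Class labels.
#' @param stat_fun Function `(X, y, seed) -> numeric` returning the
#'   classification statistic. The default runs a reduced double-CV RUSBoost
#'   (2 outer / 2 inner folds, one grid point).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A `null_distribution` with `observed`, `null`, `p_value`.
#' @export
permutation_null <- function(X, y, stat_fun = NULL, n_perm = 99, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 99L)
  if (is.null(stat_fun)) {
    stat_fun <- function(X, y, seed) {
      rusboost_2cv(X, y, outer_folds = 2, inner_folds = 2,
                   grid = tibble(n_learners = 10, tree_depth = 2),
                   seed = seed)$correct_rate
    }
  }
  observed <- stat_fun(X, y, derive_seed(seed, 9L))
  set.seed(derive_seed(seed, 10L))
  perm_seeds <- sample.int(2147483646L, n_perm)
  null <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    stat_fun(X, yp, perm_seeds[b])
  }, numeric(1))
  structure(list(
    observed = observed, null = null,
    p_value = (1 + sum(null >= observed)) / (n_perm + 1),
    n_perm = n_perm
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %.3f, null mean = %.3f, p = %.4f (%d permutations)\n",
              x$observed, mean(x$null), x$p_value, x$n_perm))
  invisible(x)
}

#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble(rate = object$null), ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = 20, fill = "firebrick", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "blue",
                        linewidth = 1) +
    ggplot2::labs(x = "Correct classification rate (null)", y = "Frequency") +
    ggplot2::theme_minimal()
}
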