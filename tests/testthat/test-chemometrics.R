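test_that("PC-DFA separates well-separated Gaussian classes along DF1", {
  toy <- two_class_toy(n = 60, sep = 5, seed = 2)
  fit <- pc_dfa(toy$X, toy$y, pc_count = 2)
  cm <- fit$class_means
  expect_equal(sign(cm$DF1[1]) * sign(cm$DF1[2]), -1)
  # standardised separation along DF1 exceeds 3
  s1 <- fit$scores$DF1[fit$scores$class == "a"]
  s2 <- fit$scores$DF1[fit$scores$class == "b"]
  pooled_sd <- sqrt((stats::var(s1) + stats::var(s2)) / 2)
  expect_gt(abs(mean(s1) - mean(s2)) / pooled_sd, 3)
  expect_error(pc_dfa(toy$X, rep("a", 60)), "classes")
  expect_error(pc_dfa(toy$X, c("b", rep("a", 59))), "2 members")
})

test_that("full-rank PC-DFA equals the direct Fisher LDA eigen-solution", {
  set.seed(31)
  n <- 30; p <- 5
  y <- factor(rep(c("a", "b", "c"), each = 10))
  X <- matrix(stats::rnorm(n * p), n, p)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "c", 2] <- X[y == "c", 2] + 2
  colnames(X) <- paste0("f", 1:p)

  # independent textbook LDA oracle on raw X: eigenvectors of W^-1 B
  Xc <- scale(X, scale = FALSE)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (cl in levels(y)) {
    Z <- Xc[y == cl, , drop = FALSE]
    mc <- colMeans(Z)
    W <- W + crossprod(sweep(Z, 2, mc))
    B <- B + nrow(Z) * tcrossprod(mc)
  }
  eg <- eigen(solve(W) %*% B)
  oracle_scores <- Xc %*% Re(eg$vectors[, 1:2])

  fit <- pc_dfa(tibble::as_tibble(X), y, pc_count = p)
  for (j in 1:2) {
    r <- abs(stats::cor(fit$scores[[paste0("DF", j)]], oracle_scores[, j]))
    expect_equal(r, 1, tolerance = 1e-8)
  }
  # eigenvalue ordering: decreasing between/within ratio
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("PC-DFA with autoscaling is invariant to feature rescaling", {
  toy <- two_class_toy(n = 40, sep = 2, seed = 5)
  f1 <- pc_dfa(toy$X, toy$y, pc_count = 2, autoscale = TRUE)
  X2 <- dplyr::mutate(toy$X, f1 = .data$f1 * 1000, f2 = .data$f2 / 50)
  f2 <- pc_dfa(X2, toy$y, pc_count = 2, autoscale = TRUE)
  expect_equal(abs(stats::cor(f1$scores$DF1, f2$scores$DF1)), 1,
               tolerance = 1e-10)
})

test_that("bootstrap PC-DFA is seeded and separates extreme planted classes", {
  toy <- two_class_toy(n = 40, sep = 6, seed = 3)
  b1 <- bootstrap_pc_dfa(toy$X, toy$y, n_boot = 100, pc_count = 2, seed = 4)
  b2 <- bootstrap_pc_dfa(toy$X, toy$y, n_boot = 100, pc_count = 2, seed = 4)
  expect_identical(b1$centroids, b2$centroids)

  # duplicated identical data: centroid dispersion collapses
  Xd <- tibble::tibble(f1 = rep(c(0, 0, 10, 10), 10), f2 = 0)
  yd <- factor(rep(c("a", "a", "b", "b"), 10))
  bd <- bootstrap_pc_dfa(Xd, yd, n_boot = 100, pc_count = 1, seed = 5)
  expect_true(all(bd$dispersion$sd_DF1 < 1e-8))

  # default synthetic run: class 1 and 4 centroid clouds disjoint on DF1
  run <- default_run()
  bs <- bootstrap_pc_dfa(run$Ximp, run$cls, n_boot = 500, seed = 6)
  c1 <- bs$centroids$DF1[bs$centroids$class == 1]
  c4 <- bs$centroids$DF1[bs$centroids$class == 4]
  expect_true(max(min(c1), min(c4)) > min(max(c1), max(c4)) ||
                (stats::quantile(c1, 0.999) < stats::quantile(c4, 0.001) ||
                   stats::quantile(c4, 0.999) < stats::quantile(c1, 0.001)))
})

test_that("RUSBoost drives training error to zero on separable data", {
  set.seed(7)
  X <- tibble::tibble(f1 = c(seq(-2, -1, length.out = 20),
                             seq(1, 2, length.out = 20)),
                      f2 = stats::rnorm(40))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- rusboost_train(X, y, n_learners = 10, tree_depth = 2, seed = 1)
  expect_equal(mean(predict(fit, X) == y), 1)
})

test_that("a single-round ensemble on balanced data equals one CART", {
  set.seed(9)
  X <- tibble::tibble(a = stats::rnorm(60), b = stats::rnorm(60))
  y <- factor(rep(c("x", "y"), each = 30))
  X$a[y == "y"] <- X$a[y == "y"] + 1.2
  rb <- rusboost_train(X, y, n_learners = 1, tree_depth = 2, seed = 4)
  ct <- rpart::rpart(y ~ ., data = cbind(X, y = y), method = "class",
                     control = rpart::rpart.control(maxdepth = 2, cp = 0,
                                                    minsplit = 2, minbucket = 1,
                                                    xval = 0, maxsurrogate = 0,
                                                    maxcompete = 0))
  cart_pred <- levels(y)[max.col(stats::predict(ct, X))]
  expect_equal(as.character(predict(rb, X)), cart_pred)
})

test_that("undersampled boosting lifts minority recall over a single CART", {
  minority_recall <- function(pred, y, minority) {
    mean(pred[y == minority] == minority)
  }
  set.seed(15)
  res <- vapply(1:50, function(i) {
    n_maj <- 90; n_min <- 10
    y <- factor(c(rep("maj", n_maj), rep("min", n_min)))
    X <- tibble::tibble(f = stats::rnorm(n_maj + n_min) +
                          ifelse(y == "min", 1.5, 0),
                        g = stats::rnorm(n_maj + n_min))
    rb <- rusboost_train(X, y, n_learners = 20, tree_depth = 2, seed = i)
    ct <- rpart::rpart(y ~ ., data = cbind(X, y = y), method = "class",
                       control = rpart::rpart.control(maxdepth = 2, cp = 0, xval = 0))
    pc <- factor(levels(y)[max.col(stats::predict(ct, X))], levels = levels(y))
    c(rus = minority_recall(predict(rb, X), y, "min"),
      cart = minority_recall(pc, y, "min"))
  }, numeric(2))
  expect_gt(mean(res["rus", ]), mean(res["cart", ]))
})

test_that("double CV reports chance-level accuracy on label noise", {
  set.seed(21)
  n <- 80
  X <- tibble::as_tibble(matrix(stats::rnorm(n * 5), n,
                                dimnames = list(NULL, paste0("f", 1:5))))
  y <- factor(rep(1:4, each = n / 4))
  rep_ <- rusboost_2cv(X, y, outer_folds = 2, inner_folds = 2,
                       grid = tibble::tibble(n_learners = 10, tree_depth = 2),
                       seed = 2)
  # binomial noise around 0.25 at n = 80
  expect_lt(abs(rep_$correct_rate - 0.25), 3.5 * sqrt(0.25 * 0.75 / n))
  # bookkeeping: confusion row sums are per-class counts
  expect_equal(as.integer(rowSums(rep_$confusion)), as.integer(table(y)))
  expect_equal(sum(rep_$confusion), n)
})

test_that("double CV detects a planted multiclass signal above chance", {
  set.seed(22)
  n <- 120
  y <- factor(rep(1:4, each = n / 4))
  X <- tibble::as_tibble(matrix(stats::rnorm(n * 10), n,
                                dimnames = list(NULL, paste0("f", 1:10))))
  X$f1 <- X$f1 + as.numeric(y) * 1.2
  rep_ <- rusboost_2cv(X, y, outer_folds = 3, inner_folds = 2,
                       grid = tibble::tibble(n_learners = 20, tree_depth = 2),
                       seed = 3)
  expect_gt(rep_$correct_rate, 0.25 + 3 * sqrt(0.25 * 0.75 / n))
})

test_that("permutation p-values follow the add-one formula and order", {
  set.seed(23)
  toy <- two_class_toy(n = 24, sep = 6, seed = 11)
  stat_fast <- function(X, y, seed) {
    # 2-fold nearest-centroid correct rate: cheap, deterministic given seed
    set.seed(seed)
    fold <- make_stratified_folds(y, 2)
    pred <- character(length(y))
    for (f in 1:2) {
      tr <- fold != f
      cen <- stats::aggregate(as.matrix(X[tr, ]), list(cls = y[tr]), mean)
      d <- as.matrix(dist(rbind(as.matrix(cen[, -1]), as.matrix(X[!tr, ]))))
      d <- d[-(1:nrow(cen)), 1:nrow(cen), drop = FALSE]
      pred[!tr] <- as.character(cen$cls[max.col(-d)])
    }
    mean(pred == as.character(y))
  }
  nd <- permutation_null(toy$X, toy$y, stat_fun = stat_fast, n_perm = 99, seed = 1)
  # perfectly separable observed statistic beats every permutation
  expect_equal(nd$observed, 1)
  expect_equal(nd$p_value, (1 + sum(nd$null >= 1)) / 100)
  expect_lte(nd$p_value, 0.05)
  # p is monotone non-increasing in the observed statistic, by construction
  p_at <- function(obs) (1 + sum(nd$null >= obs)) / (nd$n_perm + 1)
  obs_grid <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(obs_grid, p_at, numeric(1))) <= 0))
})
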