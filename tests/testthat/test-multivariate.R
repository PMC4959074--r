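# PCA, PLS-DA, venetian-blinds CV, permutation testing, VIP and forward
# selection.

sep_data <- function(n_per = 6, noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- cbind(c(rep(0, n_per), rep(5, n_per)) + stats::rnorm(2 * n_per, 0, noise),
             matrix(stats::rnorm(2 * n_per * 4), 2 * n_per, 5 - 1))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

test_that("PCA puts all variance on a single axis for rank-1 data", {
  t_ <- seq(-2, 2, length.out = 8)
  X <- cbind(3 * t_, -2 * t_, t_)
  p <- fit_pca(X)
  expect_equal(p$var_explained[1], 1)
})

test_that("duplicated samples receive identical PCA scores", {
  set.seed(2)
  X <- matrix(stats::rnorm(40), 8, 5)
  X[5, ] <- X[1, ]
  p <- fit_pca(X)
  expect_equal(p$scores[5, ], p$scores[1, ])
})

test_that("PCA explained variances match a direct eigendecomposition", {
  X <- rbind(c(0, 0), c(2, 1), c(3, -1))
  p <- fit_pca(X)
  ev <- eigen(stats::cov(X))$values
  expect_equal(p$var_explained, ev / sum(ev), tolerance = 1e-12)
  # full reconstruction is exact
  rec <- p$scores %*% t(p$loadings) + rep(p$center, each = 3)
  expect_equal(rec, X, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a separating variable yields zero training error at A = 1", {
  d <- sep_data()
  fit <- fit_plsda(d$X, d$y, A = 1)
  expect_equal(as.character(predict(fit, d$X)), d$y)
})

test_that("duplicating a column does not change predictions", {
  set.seed(3)
  x1 <- c(stats::rnorm(5, 0), stats::rnorm(5, 3))
  y <- rep(c("a", "b"), each = 5)
  f1 <- fit_plsda(cbind(x1), y, A = 1)
  f2 <- fit_plsda(cbind(x1, x1), y, A = 1)
  new1 <- cbind(seq(-1, 4, length.out = 7))
  new2 <- cbind(new1, new1)
  expect_identical(predict(f1, new1), predict(f2, new2))
})

test_that("PLS at full rank reproduces least-squares predictions of Y", {
  set.seed(4)
  X <- matrix(stats::rnorm(18), 6, 3)
  y <- factor(rep(c("a", "b"), 3))
  fit <- suppressWarnings(fit_plsda(X, y, A = 3))
  Y <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  ls <- stats::lm.fit(cbind(1, X), Y)
  pred_ls <- cbind(1, X) %*% ls$coefficients
  pred_pls <- predict(fit, X, type = "response")
  expect_equal(unname(pred_pls), unname(pred_ls), tolerance = 1e-8)
})

test_that("requesting more LVs than the rank truncates with a warning", {
  X <- cbind(c(0, 0, 1, 1, 2, 2))
  y <- rep(c("a", "b"), each = 3)
  expect_warning(fit <- fit_plsda(cbind(X, X), y, A = 3), "rank")
  expect_lt(fit$A, 3)
})

test_that("first-component geometry agrees with an independent PLS-DA", {
  d <- sep_data(n_per = 8, noise = 1, seed = 9)
  fit <- fit_plsda(d$X, d$y, A = 2)
  ref <- mixOmics::plsda(d$X, factor(d$y), ncomp = 2, scale = FALSE)
  w_ref <- ref$loadings$X[, 1]
  expect_gt(abs(stats::cor(fit$W[, 1], w_ref)), 0.999)
  expect_gt(abs(stats::cor(fit$scores[, 1], ref$variates$X[, 1])), 0.999)
})

test_that("venetian blinds assign folds by position modulo the fold count", {
  X <- matrix(stats::rnorm(12), 6, 2)
  y <- rep(c("a", "b"), each = 3)
  cv <- suppressWarnings(venetian_cv(X, y, folds = 3, A_max = 1))
  expect_equal(cv$fold, c(0L, 1L, 2L, 0L, 1L, 2L))
  expect_equal(sort(unique(cv$fold)), 0:2)
  expect_equal(tabulate(cv$fold + 1L), c(2L, 2L, 2L)) # partition
})

test_that("separable groups give zero CV error at one latent variable", {
  d <- sep_data(n_per = 6)
  cv <- venetian_cv(d$X, d$y, folds = 3, A_max = 3)
  expect_equal(cv$error, 0)
  expect_equal(cv$A, 1L)
  expect_equal(as.character(cv$predictions), d$y)
})

test_that("held-out error on shuffled labels is near chance", {
  set.seed(11)
  X <- matrix(stats::rnorm(18 * 30), 18, 30)
  y <- sample(rep(c("a", "b", "c"), each = 6))
  cv <- suppressWarnings(venetian_cv(X, y, folds = 3, A_max = 3))
  expect_gt(cv$error, 0.4) # chance is 2/3
})

test_that("permutation p attains its lower bound on separable data", {
  d <- sep_data(n_per = 8, noise = 0.05)
  set.seed(5)
  pt <- permutation_test(d$X, d$y, B = 99, folds = 3)
  expect_equal(pt$observed, 0)
  # no permutation re-creates the separating labels here, so p sits at its
  # lower bound 1 / (B + 1)
  expect_equal(pt$p, 1 / 100)
})

test_that("the permutation p estimator matches its defining formula", {
  set.seed(6)
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  y <- rep(c("a", "b"), 6)
  pt <- suppressWarnings(permutation_test(X, y, B = 19, folds = 3))
  expect_equal(pt$p, (1 + sum(pt$permuted <= pt$observed)) / 20)
  expect_gte(pt$p, 1 / 20)
  expect_lte(pt$p, 1)
  # degenerate B = 1
  set.seed(6)
  pt1 <- suppressWarnings(permutation_test(X, y, B = 1, folds = 3))
  expect_true(pt1$p %in% c(0.5, 1))
  expect_equal(pt1$p, (1 + sum(pt1$permuted <= pt1$observed)) / 2)
})

test_that("permutation p is invariant to relabeling the classes", {
  d <- sep_data(n_per = 5, noise = 2, seed = 12)
  set.seed(7)
  p1 <- permutation_test(d$X, d$y, B = 49)$p
  set.seed(7)
  y2 <- ifelse(d$y == "a", "group-one", "group-two")
  p2 <- permutation_test(d$X, y2, B = 49)$p
  expect_equal(p1, p2)
})

test_that("VIP matches its closed form on a one-LV model", {
  X <- cbind(c(1, 2, 3, 4) - 2.5, c(1, -1, -1, 1))
  y <- c("a", "a", "b", "b")
  fit <- fit_plsda(X, y, A = 1)
  vip <- variable_importance(fit)
  expect_equal(as.numeric(vip), c(sqrt(2), 0), tolerance = 1e-10)
})

test_that("equal weights give unit VIP everywhere", {
  x1 <- c(0, 0, 0, 5, 5, 5)
  fit <- fit_plsda(cbind(x1, x1), rep(c("a", "b"), each = 3), A = 1)
  vip <- variable_importance(fit)
  expect_equal(as.numeric(vip), c(1, 1))
})

test_that("mean squared VIP is 1 for any model", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(stats::rnorm(14 * 20), 14, 20)
    y <- rep(c("a", "b"), 7)
    fit <- suppressWarnings(fit_plsda(X, y, A = 3))
    vip <- variable_importance(fit)
    expect_equal(mean(vip^2), 1, tolerance = 1e-10)
  }
})

test_that("forward selection stops at a single sufficient variable", {
  d <- sep_data(n_per = 6, noise = 0.05)
  fit <- fit_plsda(d$X, d$y, A = 1)
  fs <- forward_select(d$X, d$y, variable_importance(fit), folds = 3, A_max = 2)
  expect_equal(fs$k, 1L)
  expect_equal(fs$subset, 1L)
  expect_equal(fs$cv_error, 0)
})

test_that("forward selection on pure noise stays near chance", {
  set.seed(13)
  X <- matrix(stats::rnorm(16 * 40), 16, 40)
  y <- rep(c("a", "b"), each = 8)
  fit <- suppressWarnings(fit_plsda(X, y, A = 2))
  fs <- suppressWarnings(
    forward_select(X, y, variable_importance(fit), folds = 3, A_max = 2)
  )
  expect_gt(fs$cv_error, 0.15) # chance is 0.5 before selection optimism
})

test_that("reversing the importance ranking cannot help separable data", {
  d <- sep_data(n_per = 6, noise = 0.05)
  fit <- fit_plsda(d$X, d$y, A = 1)
  vip <- variable_importance(fit)
  good <- forward_select(d$X, d$y, vip, folds = 3, A_max = 2)
  rev_rank <- rev(attr(vip, "ranking"))
  bad <- forward_select(d$X, d$y,
                        structure(vip, ranking = rev_rank),
                        folds = 3, A_max = 2)
  expect_gte(bad$cv_error, good$cv_error)
})
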