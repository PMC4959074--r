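# PLS-DA (NIPALS PLS2 on one-hot class coding) with venetian-blinds
# cross-validation, permutation testing, VIP importance and forward
# selection.

.one_hot <- function(y) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 on the mean-centered data matrix against mean-centered
#' one-hot class coding.  Class prediction is the argmax of the predicted
#' class scores; ties are broken by class (factor level) order.
#'
#' @param X Samples x features matrix (complete; typically glog-transformed).
#' @param y Class labels (coerced to factor).
#' @param A Number of latent variables; truncated with a warning if it
#'   exceeds the effective rank of `X`.
#' @param tol NIPALS convergence tolerance.
#' @return A `plsda` object with X-weights `W` (unit norm per LV), loadings
#'   `P`, scores `T`, Y-loadings `Q`, per-LV explained Y-variance `ssy`,
#'   centers, and the class levels.
#' @export
fit_plsda <- function(X, y, A = 2, tol = 1e-10) {
  X <- as.matrix(X)
  y <- factor(y)
  if (anyNA(X)) stop("X must be complete")
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (A < 1L) stop("A must be >= 1")
  n <- nrow(X)
  stopifnot(n == length(y))
  Y <- .one_hot(y)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2L, x_mean)
  F_ <- sweep(Y, 2L, y_mean)
  ss_x0 <- sum(E^2)

  J <- ncol(X)
  W <- matrix(0, J, A)
  P <- matrix(0, J, A)
  Q <- matrix(0, ncol(Y), A)
  T_ <- matrix(0, n, A)
  ssy <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < tol * n) break
    t_old <- rep(Inf, n)
    t_ <- NULL
    for (it in seq_len(500L)) {
      w <- crossprod(E, u)[, 1L]
      wn <- sqrt(sum(w^2))
      if (wn < 1e-150) break
      w <- w / wn
      t_ <- (E %*% w)[, 1L]
      q <- crossprod(F_, t_)[, 1L] / sum(t_^2)
      u <- (F_ %*% q)[, 1L] / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    tt <- if (is.null(t_)) 0 else sum(t_^2)
    if (!is.finite(tt) || tt < 1e-12 * max(ss_x0, 1)) {
      warning("rank of X reached; truncating at ", a - 1L, " latent variables")
      break
    }
    p <- crossprod(E, t_)[, 1L] / tt
    E <- E - tcrossprod(t_, p)
    F_ <- F_ - tcrossprod(t_, q)
    W[, a] <- w
    P[, a] <- p
    Q[, a] <- q
    T_[, a] <- t_
    ssy[a] <- tt * sum(q^2)
    a_eff <- a
  }
  if (a_eff == 0L) stop("no latent variable could be extracted")
  keep <- seq_len(a_eff)
  structure(list(
    A = a_eff, W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
    Q = Q[, keep, drop = FALSE], scores = T_[, keep, drop = FALSE],
    ssy = ssy[keep], x_mean = x_mean, y_mean = y_mean,
    levels = levels(y), y = y
  ), class = "plsda")
}

#' Predict classes (or Y-scores) from a PLS-DA model
#'
#' @param object A `plsda` model.
#' @param newdata Samples x features matrix.
#' @param A Number of latent variables to use (default: all fitted).
#' @param type `"class"` or `"response"` (predicted one-hot scores).
#' @param ... Unused.
#' @return Factor of predicted classes, or a score matrix.
#' @export
predict.plsda <- function(object, newdata, A = object$A,
                          type = c("class", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  A <- min(A, object$A)
  E <- sweep(newdata, 2L, object$x_mean)
  Yhat <- matrix(rep(object$y_mean, each = nrow(newdata)), nrow(newdata))
  colnames(Yhat) <- object$levels
  for (a in seq_len(A)) {
    t_ <- (E %*% object$W[, a])[, 1L]
    E <- E - tcrossprod(t_, object$P[, a])
    Yhat <- Yhat + tcrossprod(t_, object$Q[, a])
  }
  if (type == "response") return(Yhat)
  factor(object$levels[max.col(Yhat, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$A, "latent variable(s),",
      length(x$levels), "classes (", paste(x$levels, collapse = ", "), ")\n")
  cat("  explained Y-variance per LV:",
      paste(sprintf("%.3g", x$ssy / sum(x$ssy)), collapse = ", "), "\n")
  invisible(x)
}

#' Venetian-blinds cross-validation
#'
#' Samples are ordered by (class, position); fold `f` takes every sample
#' whose 0-based position modulo `folds` equals `f`.  For each number of
#' latent variables up to `A_max` the held-out misclassification rate is
#' computed; the returned model size minimizes CV error (ties favour the
#' smallest A).
#'
#' @param X Samples x features matrix.
#' @param y Class labels.
#' @param folds Number of blinds (default 3).
#' @param A_max Largest model size scanned (default `min(10, n - 2)`).
#' @return A `cv_result` list: `error`, `A`, `errors_by_A`, `fold` (fold id
#'   per sample), `predictions` (per sample at the chosen A).
#' @export
venetian_cv <- function(X, y, folds = 3, A_max = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (is.null(A_max)) A_max <- max(1L, min(10L, n - 2L))
  if (folds > min(table(y))) {
    warning("more folds than the smallest class; some folds may lack a class")
  }
  ord <- order(y, seq_len(n))
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% folds
  err_by_a <- matrix(NA_real_, folds, A_max)
  pred_by_a <- matrix(NA_character_, n, A_max)
  for (f in seq_len(folds) - 1L) {
    test <- fold == f
    if (nlevels(droplevels(factor(y[!test]))) < 2L) next
    fit <- suppressWarnings(fit_plsda(X[!test, , drop = FALSE], y[!test],
                                      A = A_max))
    for (a in seq_len(A_max)) {
      pr <- predict(fit, X[test, , drop = FALSE], A = min(a, fit$A))
      pred_by_a[test, a] <- as.character(pr)
      err_by_a[f + 1L, a] <- mean(pr != y[test])
    }
  }
  n_test <- tabulate(fold + 1L, nbins = folds)
  errors <- colSums(err_by_a * n_test, na.rm = TRUE) / sum(n_test)
  A_best <- which.min(errors) # ties -> smallest A
  structure(list(
    error = errors[A_best], A = A_best, errors_by_A = errors, fold = fold,
    predictions = factor(pred_by_a[, A_best], levels = levels(y))
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Venetian-blinds CV: error %.3f at A = %d\n", x$error, x$A))
  invisible(x)
}

#' Permutation test of a PLS-DA model
#'
#' The test statistic is the venetian-blinds CV misclassification error at
#' the model size chosen on the observed labels; labels are permuted
#' uniformly at random `B` times and
#' `p = (1 + #\{permuted error <= observed\}) / (B + 1)`.
#'
#' @param X Samples x features matrix.
#' @param y Class labels.
#' @param B Number of permutations (default 1000).
#' @param folds,A_max Passed to [venetian_cv()] for the observed statistic.
#' @return A `permutation_result` list: `p`, `observed` (CV error), `A`,
#'   `permuted` (vector of permuted-label errors).
#' @export
permutation_test <- function(X, y, B = 1000, folds = 3, A_max = NULL) {
  stopifnot(B >= 1)
  X <- as.matrix(X)
  y <- factor(y)
  obs <- venetian_cv(X, y, folds = folds, A_max = A_max)
  perm <- vapply(seq_len(B), function(b) {
    yb <- sample(y)
    suppressWarnings(
      venetian_cv(X, yb, folds = folds, A_max = obs$A)$error
    )
  }, numeric(1))
  p <- (1 + sum(perm <= obs$error)) / (B + 1)
  structure(list(p = p, observed = obs$error, A = obs$A, permuted = perm,
                 B = B), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed CV error %.3f, p = %.4g (B = %d)\n",
              x$observed, x$p, x$B))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(J * sum_a ssy_a w_aj^2 / sum_a ssy_a)` with unit-norm
#' weights; the mean of squared VIP scores is 1 for any model.
#'
#' @param model A fitted `plsda` model.
#' @return Numeric vector of VIP scores with attribute `ranking` (feature
#'   indices in decreasing importance).
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "plsda"))
  J <- nrow(model$W)
  w2 <- model$W^2
  vip <- sqrt(J * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
  attr(vip, "ranking") <- order(vip, decreasing = TRUE)
  vip
}

#' Forward selection over a variable-importance ranking
#'
#' Refits PLS-DA on the top-k variables for subset sizes on a logarithmic
#' grid (1, 2, 5, 10, ... up to all variables), recording the
#' venetian-blinds CV error for each; returns the smallest subset achieving
#' the minimum CV error and the model refitted on it.
#'
#' @param X Samples x features matrix.
#' @param y Class labels.
#' @param importance VIP scores or any ranking vector (larger = better), or
#'   an explicit integer ranking via `attr(., "ranking")`.
#' @param folds,A_max Passed to [venetian_cv()].
#' @param grid Optional explicit subset sizes.
#' @return A `forward_selection` list: `subset` (column indices), `k`,
#'   `cv_error`, `path` (data frame of k vs error), `model`.
#' @export
forward_select <- function(X, y, importance, folds = 3, A_max = NULL,
                           grid = NULL) {
  X <- as.matrix(X)
  J <- ncol(X)
  ranking <- attr(importance, "ranking")
  if (is.null(ranking)) ranking <- order(importance, decreasing = TRUE)
  stopifnot(length(ranking) == J)
  if (is.null(grid)) {
    pow <- if (J >= 10) as.integer(10^seq(1, log10(J), by = 1 / 3)) else integer(0)
    grid <- sort(unique(pmin(c(1L, 2L, 5L, pow, J), J)))
  }
  errs <- vapply(grid, function(k) {
    suppressWarnings(
      venetian_cv(X[, ranking[seq_len(k)], drop = FALSE], y,
                  folds = folds, A_max = A_max)$error
    )
  }, numeric(1))
  k_best <- grid[which.min(errs)] # smallest k at the minimum
  subset <- ranking[seq_len(k_best)]
  model <- suppressWarnings(fit_plsda(X[, subset, drop = FALSE], y,
                                      A = if (is.null(A_max)) 2 else A_max))
  structure(list(subset = subset, k = k_best, cv_error = min(errs),
                 path = data.frame(k = grid, cv_error = errs), model = model),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("Forward selection: k = %d variables, CV error %.3f\n",
              x$k, x$cv_error))
  invisible(x)
}
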