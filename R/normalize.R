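# Probabilistic quotient normalization, feature-space KNN imputation, and the
# QC-calibrated generalized-log transform.

#' Probabilistic quotient normalization
#'
#' The reference spectrum is the per-feature median over biological samples
#' (missing values ignored).  For each sample the dilution factor is the
#' median of the quotients `x_ij / r_j` over features observed in both the
#' sample and the reference; the sample's row is divided by its factor.  QC
#' and biological samples are normalized against the same reference.
#'
#' @param fm A `feature_matrix`, or a plain features x samples matrix.
#' @param reference `"biological"` (default) or `"qc"`: which samples define
#'   the reference spectrum.  For a plain matrix all columns are used.
#' @return A `pqn_result` list: `fm` (normalized), `dilution` (named factors,
#'   all > 0), `reference` (reference spectrum).
#' @examples
#' m <- rbind(c(2, 1), c(4, 2), c(8, 2))
#' pqn_normalize(m)$dilution
#' @export
pqn_normalize <- function(fm, reference = c("biological", "qc")) {
  reference <- match.arg(reference)
  is_fm <- inherits(fm, "feature_matrix")
  x <- if (is_fm) fm$intensity else as.matrix(fm)
  if (ncol(x) < 2L) stop("PQN needs at least 2 samples")
  ref_cols <- if (is_fm) {
    role <- fm$samples$role
    if (reference == "qc") role == "QC" else role == "biological"
  } else {
    rep(TRUE, ncol(x))
  }
  if (!any(ref_cols)) stop("no samples available for the PQN reference")
  r <- apply(x[, ref_cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  d <- vapply(seq_len(ncol(x)), function(i) {
    q <- x[, i] / r
    q <- q[is.finite(q) & !is.na(q)]
    if (!length(q)) {
      warning("sample ", colnames(x)[i],
              " shares no observed features with the reference; factor 1")
      return(1)
    }
    stats::median(q)
  }, numeric(1))
  names(d) <- colnames(x)
  out <- sweep(x, 2L, d, "/")
  if (is_fm) {
    fm$intensity <- out
    fm$log <- c(fm$log, sprintf("pqn_normalize: reference=%s median", reference))
  } else {
    fm <- out
  }
  structure(list(fm = fm, dilution = d, reference = r), class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat("PQN normalization: dilution factors\n")
  print(summary(x$dilution))
  invisible(x)
}

#' K-nearest-neighbour imputation of missing values
#'
#' Neighbours are features (rows), not samples: for a missing cell
#' (feature j, sample i) the k features nearest to j — by Euclidean distance
#' over samples where both features are observed, scaled by the number of
#' co-observed samples — vote with weights `1 / (distance + eps)` using their
#' values in sample i.  Neighbours themselves missing at i are skipped; if
#' all k are, the feature's observed mean is used.  Observed cells are never
#' changed.
#'
#' @param fm A `feature_matrix` or plain matrix (features x rows).
#' @param k Number of neighbouring features (default 5).
#' @param eps Weight regularizer.
#' @return Object of the same type with no missing values.
#' @export
knn_impute <- function(fm, k = 5, eps = 1e-9) {
  is_fm <- inherits(fm, "feature_matrix")
  x <- if (is_fm) fm$intensity else as.matrix(fm)
  if (!anyNA(x)) {
    if (is_fm) { fm$intensity <- x; return(fm) }
    return(x)
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("feature(s) with no observed values cannot be imputed")
  }
  need <- which(rowSums(is.na(x)) > 0L)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # squared distances over co-observed samples, scaled by co-observation count
  a0 <- x0[need, , drop = FALSE]
  wa <- obs[need, , drop = FALSE] * 1
  d2 <- (a0^2 %*% t(obs)) + (wa %*% t(x0^2)) - 2 * (a0 %*% t(x0))
  cnt <- wa %*% t(obs * 1)
  dist <- sqrt(pmax(d2, 0) / cnt) # NaN when no co-observed samples
  dist[cnt == 0] <- Inf
  dist[cbind(seq_along(need), need)] <- Inf # exclude self
  row_mean <- rowMeans(x, na.rm = TRUE)
  out <- x
  for (ii in seq_along(need)) {
    j <- need[ii]
    dj <- dist[ii, ]
    nb <- order(dj)[seq_len(min(k, length(dj) - 1L))]
    nb <- nb[is.finite(dj[nb])]
    for (i in which(is.na(x[j, ]))) {
      vals <- x[nb, i]
      ok <- !is.na(vals)
      out[j, i] <- if (any(ok)) {
        stats::weighted.mean(vals[ok], 1 / (dj[nb][ok] + eps))
      } else {
        row_mean[j]
      }
    }
  }
  if (is_fm) {
    fm$intensity <- out
    fm$log <- c(fm$log, sprintf("knn_impute: k=%d, %d cells imputed",
                                k, sum(is.na(x))))
    fm
  } else {
    out
  }
}

#' Generalized-log transform
#'
#' `y = ln((x + sqrt(x^2 + lambda)) / 2)`.  With `lambda = 0` this is the
#' natural log; the transform is strictly increasing in `x` for any
#' `lambda >= 0`.
#'
#' @param x Numeric vector/matrix of non-negative intensities (no missing).
#' @param lambda Offset parameter (intensity^2 units), `>= 0`.
#' @return Transformed values, same shape as `x`.
#' @examples
#' glog_transform(3, lambda = 16) # log(4)
#' @export
glog_transform <- function(x, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop("lambda must be a single non-negative number")
  }
  log((x + sqrt(x^2 + lambda)) / 2)
}

#' Calibrate the glog offset on QC technical replicates
#'
#' Searches `lambda` for the value that best flattens the variance-mean
#' relationship of the QC replicates: the objective is the spread, across
#' features, of the per-feature SD of the glog-transformed QC values, made
#' scale-free by dividing by its mean (otherwise the objective degenerates
#' as `lambda -> Inf`, where the transform collapses to a constant).  A
#' log-spaced grid over `[0, max(x)^2]` is scanned and the best cell refined
#' by golden-section search.
#'
#' @param qc A features x QC-replicates matrix (>= 3 columns, no missing).
#' @return A `glog_params` list: `lambda`, `objective`, `base = "e"`.
#' @export
estimate_glog_lambda <- function(qc) {
  qc <- as.matrix(qc)
  if (ncol(qc) < 3L) {
    stop("need >= 3 QC samples to calibrate lambda; set a fixed lambda instead")
  }
  if (anyNA(qc)) stop("QC matrix must be imputed before calibration")
  n <- ncol(qc)
  objective <- function(lambda) {
    g <- glog_transform(qc, lambda)
    rsd <- sqrt(pmax(rowSums(g^2) - n * rowMeans(g)^2, 0) / (n - 1))
    if (mean(rsd) == 0) return(0) # identical replicates
    stats::sd(rsd) / mean(rsd)
  }
  top <- max(qc)^2
  grid <- c(0, 10^seq(log10(top) - 12, log10(top), length.out = 40))
  vals <- vapply(grid, objective, numeric(1))
  best <- which.min(vals)
  if (!is.finite(vals[best]) || max(vals) - min(vals) < 1e-12) {
    # degenerate (e.g. identical replicates): smallest grid lambda
    return(structure(list(lambda = grid[1L], objective = vals[1L],
                          base = "e"), class = "glog_params"))
  }
  lo <- grid[max(best - 1L, 1L)]
  hi <- grid[min(best + 1L, length(grid))]
  opt <- stats::optimize(objective, lower = lo, upper = hi)
  if (opt$objective <= vals[best]) {
    lambda <- opt$minimum
    obj <- opt$objective
  } else {
    lambda <- grid[best]
    obj <- vals[best]
  }
  structure(list(lambda = lambda, objective = obj, base = "e"),
            class = "glog_params")
}

#' @export
print.glog_params <- function(x, ...) {
  cat(sprintf("glog calibration: lambda = %.6g (objective %.6g, base e)\n",
              x$lambda, x$objective))
  invisible(x)
}
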