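# PCA on the glog-transformed matrix (thin wrapper over stats::prcomp).

#' Principal component analysis
#'
#' Mean-centered (unscaled) PCA of a samples x features matrix; the
#' decomposition is exact, so reconstruction with all components reproduces
#' the centered data.
#'
#' @param X Samples x features matrix with no missing values.
#' @return A `pca_model` list: `center`, `loadings` (features x PCs),
#'   `scores` (samples x PCs), `var_explained` (non-increasing fractions
#'   summing to <= 1), `sdev`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  if (anyNA(X)) stop("X must be complete")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, loadings = pc$rotation,
                 scores = pc$x, var_explained = ve, sdev = pc$sdev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5L, length(x$var_explained))
  cat("PCA:", ncol(x$scores), "components;",
      "variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Scores scatter plot
#'
#' @param x A `pca_model` or `plsda` object.
#' @param groups Optional group labels for colouring.
#' @param comps Which two components to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pca_model <- function(x, groups = NULL, comps = c(1, 2), ...) {
  s <- x$scores[, comps, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(s, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                100 * x$var_explained[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                100 * x$var_explained[comps[2]]), ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))), pch = 19)
  }
  invisible(x)
}
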