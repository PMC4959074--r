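# Per-feature one-way ANOVA with BH-FDR control, signed percent changes and
# per-class roll-ups.

#' One-way ANOVA per feature
#'
#' Vectorized fixed-effects F test across groups for every feature (row) of
#' the normalized, imputed intensity matrix; p-values come from the F
#' distribution with (g - 1, n - g) degrees of freedom.  Features with zero
#' between- and within-group variance get `F = 0`, `p = 1`.
#'
#' @param x Features x samples matrix (complete).
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @return Data frame with `F` and `p` per feature.
#' @export
anova_per_feature <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- ncol(x)
  if (g < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  stopifnot(length(groups) == n, !anyNA(x))
  n_g <- as.numeric(table(groups))
  gsum <- x %*% stats::model.matrix(~ groups - 1)
  gmean <- sweep(gsum, 2L, n_g, "/")
  grand <- rowSums(x) / n
  ssb <- as.numeric(sweep(gmean, 1L, grand)^2 %*% n_g)
  sst <- rowSums(sweep(x, 1L, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- g - 1L
  df2 <- n - g
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  tol <- 1e-12 * pmax(sst, 1)
  zero_both <- ssw <= tol & ssb <= tol
  f_stat[zero_both] <- 0
  p[zero_both] <- 1
  data.frame(F = as.numeric(f_stat), p = as.numeric(p),
             row.names = rownames(x))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1
#' (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values, monotone in `p`, each `>= p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Signed percent change between groups
#'
#' `100 * (mean_A - mean_ref) / mean_ref` per feature, computed on the
#' normalized, imputed, untransformed matrix; negative values mean the
#' signal is lower in the (infected) group A than in the reference.
#'
#' @param x Features x samples matrix.
#' @param groups Group label per sample.
#' @param group Group A (e.g. an infected line).
#' @param reference Reference group (default `"control"`).
#' @return Numeric vector of percent changes (`NA` where the reference mean
#'   is zero).
#' @export
percent_change <- function(x, groups, group, reference = "control") {
  x <- as.matrix(x)
  stopifnot(group %in% groups, reference %in% groups)
  m_a <- rowMeans(x[, groups == group, drop = FALSE])
  m_r <- rowMeans(x[, groups == reference, drop = FALSE])
  pct <- 100 * (m_a - m_r) / m_r
  pct[m_r == 0] <- NA_real_
  pct
}

#' Per-feature differential analysis
#'
#' Combines the three-group ANOVA, BH q-values and the signed percent
#' changes of each infected group versus control into one table, with the
#' five-way direction-pair classification used for class summaries
#' (`-/-`, `+/+`, `-/+`, `+/-`, `none`; `none` iff `q >= q_threshold`).
#'
#' @param fm A normalized, imputed `feature_matrix` (biological columns are
#'   used), or a plain matrix plus `groups`.
#' @param groups Group labels (only needed for a plain matrix).
#' @param reference Reference group name.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return A `differential_result` data frame: `feature`, `mz`, `F`, `p`,
#'   `q`, one `pct_<group>` column per non-reference group, `significant`,
#'   `direction`.
#' @export
differential_analysis <- function(fm, groups = NULL, reference = "control",
                                  q_threshold = 0.05) {
  if (inherits(fm, "feature_matrix")) {
    bio <- fm$samples$role == "biological"
    x <- fm$intensity[, bio, drop = FALSE]
    groups <- fm$samples$group[bio]
    mz <- fm$mz
  } else {
    x <- as.matrix(fm)
    if (is.null(groups)) stop("groups required for a plain matrix")
    mz <- rep(NA_real_, nrow(x))
  }
  av <- anova_per_feature(x, groups)
  q <- bh_fdr(av$p)
  others <- setdiff(unique(groups), reference)
  out <- data.frame(feature = rownames(x) %||% sprintf("F%05d", seq_len(nrow(x))),
                    mz = mz, F = av$F, p = av$p, q = q,
                    stringsAsFactors = FALSE)
  for (g in others) {
    out[[paste0("pct_", g)]] <- percent_change(x, groups, g, reference)
  }
  out$significant <- out$q < q_threshold
  if (length(others) == 2L) {
    s1 <- sign(out[[paste0("pct_", others[1])]])
    s2 <- sign(out[[paste0("pct_", others[2])]])
    dir <- paste0(ifelse(s1 >= 0, "+", "-"), "/", ifelse(s2 >= 0, "+", "-"))
    out$direction <- ifelse(out$significant, dir, "none")
  } else {
    out$direction <- ifelse(out$significant,
                            ifelse(out[[paste0("pct_", others[1])]] >= 0,
                                   "+", "-"),
                            "none")
  }
  class(out) <- c("differential_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class roll-up of differential results
#'
#' Each annotated species is counted once through its class's primary ion
#' (smallest |ppm error| among non-isotopologue, singly charged candidates of
#' the primary adduct).  Per class the mean percent change per infected
#' group (over all annotated species) and the five-way direction-pair counts
#' are reported; direction counts always sum to the species count.
#'
#' @param diff A `differential_result` table.
#' @param annotations An annotation table from [annotate_features()].
#' @param classes Optional subset of classes (default: all annotated classes
#'   except the background).
#' @param significant_only If `TRUE`, class means average significant species
#'   only.
#' @return A `class_summary` list: `classes` (per-class table) and `species`
#'   (per-species table with feature, pct and direction columns).
#' @export
class_summary <- function(diff, annotations, classes = NULL,
                          significant_only = FALSE) {
  ann <- annotations
  prim <- ann[!is.na(ann$class_name) &
                ann$adduct == ann$primary_adduct &
                ann$iso == 0L & abs(ann$charge) == 1L &
                !ann$flagged_isotope, , drop = FALSE]
  # one feature per species: smallest |ppm|
  prim <- prim[order(prim$species_id, abs(prim$ppm)), , drop = FALSE]
  prim <- prim[!duplicated(prim$species_id), , drop = FALSE]
  sp <- merge(prim, diff, by = "feature", sort = FALSE)
  if (is.null(classes)) {
    classes <- setdiff(sort(unique(sp$class_name)), "FA-background")
  }
  sp <- sp[sp$class_name %in% classes, , drop = FALSE]
  pct_cols <- grep("^pct_", names(diff), value = TRUE)
  cls <- lapply(split(sp, sp$class_name), function(d) {
    use <- if (significant_only) d$significant else rep(TRUE, nrow(d))
    dirs <- c("-/-", "+/+", "-/+", "+/-", "none")
    cnt <- table(factor(d$direction, levels = dirs))
    out <- data.frame(class_name = d$class_name[1], n_species = nrow(d),
                      as.list(cnt), check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (pc in pct_cols) {
      out[[paste0("mean_", pc)]] <- mean(d[[pc]][use], na.rm = TRUE)
    }
    out
  })
  cls <- do.call(rbind, c(cls, list(make.row.names = FALSE)))
  structure(list(classes = cls, species = sp), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  print(x$classes, digits = 3)
  invisible(x)
}
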