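# SIMStitch-style preprocessing: window stitching, technical-replicate
# merging, cross-sample alignment and the blank / sample occupancy filters.

#' Filter configuration
#'
#' @param replicate_min Minimum technical replicates a peak must appear in
#'   (default 2 of 3).
#' @param blank_factor Biological/blank mean intensity ratio required to keep
#'   a feature (default 2).
#' @param sample_fraction Fraction of samples of a group in which a feature
#'   must be observed (default 0.75).
#' @param sample_filter_mode `"group"` keeps a feature observed in >=
#'   `sample_fraction` of at least one group's biological samples; `"overall"`
#'   applies the fraction across all biological samples.
#' @param mz_tolerance m/z matching tolerance in ppm (default 2).
#' @param rt_tolerance Retention-time co-elution window in seconds (LC).
#' @return A `filter_config` list.
#' @export
filter_config <- function(replicate_min = 2, blank_factor = 2,
                          sample_fraction = 0.75,
                          sample_filter_mode = c("group", "overall"),
                          mz_tolerance = 2, rt_tolerance = 10) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1, blank_factor >= 1,
            mz_tolerance > 0, replicate_min >= 1)
  structure(list(replicate_min = replicate_min, blank_factor = blank_factor,
                 sample_fraction = sample_fraction,
                 sample_filter_mode = match.arg(sample_filter_mode),
                 mz_tolerance = mz_tolerance, rt_tolerance = rt_tolerance),
            class = "filter_config")
}

# Gap-based single-linkage clustering of sorted m/z values: a new cluster
# starts whenever the gap to the previous value exceeds `tol_ppm` (relative
# to the lower m/z of the pair).  Clusters holding two peaks of the same
# source farther apart than the tolerance are split at their largest
# internal gap.  Returns a cluster id per input element (input order).
.cluster_mz <- function(mz, source = NULL, tol_ppm = 2) {
  n <- length(mz)
  if (n == 0L) return(integer(0))
  ord <- order(mz)
  mzs <- mz[ord]
  gap <- diff(mzs)
  newc <- c(TRUE, gap > tol_ppm * 1e-6 * mzs[-n])
  cl <- cumsum(newc)

  if (!is.null(source)) {
    sf <- as.integer(factor(source[ord]))
    pair <- (cl - 1) * max(sf) + sf
    dup_cl <- unique(cl[duplicated(pair)])
    if (length(dup_cl)) {
      split_cluster <- function(idx) { # contiguous indices in sorted order
        if (length(idx) < 2L) return(list(idx))
        span_bad <- any(vapply(split(mzs[idx], sf[idx]), function(v) {
          length(v) > 1L && (max(v) - min(v)) > tol_ppm * 1e-6 * min(v)
        }, logical(1)))
        if (!span_bad) return(list(idx))
        cut <- which.max(diff(mzs[idx]))
        c(split_cluster(idx[seq_len(cut)]),
          split_cluster(idx[(cut + 1L):length(idx)]))
      }
      idxs <- split(seq_len(n), cl)
      nxt <- max(cl)
      for (c0 in dup_cl) {
        parts <- split_cluster(idxs[[c0]])
        if (length(parts) > 1L) {
          for (k in 2:length(parts)) {
            nxt <- nxt + 1L
            cl[parts[[k]]] <- nxt
          }
        }
      }
    }
  }
  out <- integer(n)
  out[ord] <- cl
  # renumber in m/z order
  match(out, unique(out[order(mz)]))
}

#' Stitch SIM window peak lists into one spectrum
#'
#' Windows are processed left to right.  Each window's intensities are
#' rescaled by the median intensity ratio of peaks it shares (within
#' `mz_tolerance`) with the already-stitched spectrum in the overlap region;
#' if an overlap holds no shared peaks the scale is 1 and a warning is
#' raised.  Duplicate peaks are then merged by intensity-weighted mean m/z
#' and mean scaled intensity.
#'
#' @param window_lists List of peak data frames (`mz`, `intensity`), one per
#'   window, ordered as in `windows`.
#' @param windows Data frame of window `start`/`end` boundaries
#'   (see [sim_windows()]).
#' @param mz_tolerance Match tolerance in ppm.
#' @return A single peak data frame sorted by m/z.
#' @export
stitch_sim_windows <- function(window_lists, windows, mz_tolerance = 2) {
  stopifnot(length(window_lists) == nrow(windows))
  if (length(window_lists) == 1L) {
    out <- window_lists[[1L]]
    return(out[order(out$mz), , drop = FALSE])
  }
  if (any(windows$start[-1] >= windows$end[-nrow(windows)])) {
    stop("window tiling leaves gaps between adjacent SIM windows")
  }
  scaled <- window_lists
  for (w in 2:length(window_lists)) {
    lo <- windows$start[w]
    hi <- windows$end[w - 1L]
    prev <- scaled[[w - 1L]]
    cur <- scaled[[w]]
    pov <- prev[prev$mz >= lo & prev$mz <= hi, , drop = FALSE]
    cov <- cur[cur$mz >= lo & cur$mz <= hi, , drop = FALSE]
    scale <- 1
    if (nrow(pov) && nrow(cov)) {
      i <- findInterval(cov$mz, pov$mz)
      lo_i <- pmax(i, 1L)
      hi_i <- pmin(i + 1L, nrow(pov))
      d_lo <- abs(cov$mz - pov$mz[lo_i])
      d_hi <- abs(cov$mz - pov$mz[hi_i])
      near <- ifelse(d_lo <= d_hi, lo_i, hi_i)
      dist <- pmin(d_lo, d_hi)
      ok <- dist <= mz_tolerance * 1e-6 * cov$mz
      if (any(ok)) {
        scale <- stats::median(pov$intensity[near[ok]] / cov$intensity[ok])
      }
    }
    if (identical(scale, 1) && !(nrow(pov) && nrow(cov))) {
      warning("no shared peaks in overlap of windows ", w - 1L, "/", w,
              "; scale factor 1 used")
    }
    scaled[[w]]$intensity <- scaled[[w]]$intensity * scale
  }
  all <- do.call(rbind, Map(function(df, w) {
    if (nrow(df)) cbind(df, .win = w) else NULL
  }, scaled, seq_along(scaled)))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  cl <- .cluster_mz(all$mz, source = all$.win, tol_ppm = mz_tolerance)
  wsum <- rowsum(all$intensity, cl)
  mz <- rowsum(all$mz * all$intensity, cl) / wsum
  # per-window sum, then mean over the windows contributing to the cluster,
  # so unresolved same-window peaks keep their summed intensity
  n_win <- length(window_lists)
  pair <- (cl - 1L) * n_win + all$.win
  win_count <- tabulate(cl[!duplicated(pair)], nbins = max(cl))
  int <- wsum / win_count[as.integer(rownames(wsum))]
  out <- data.frame(mz = as.numeric(mz), intensity = as.numeric(int))
  out[order(out$mz), , drop = FALSE]
}

#' Merge technical replicate peak lists
#'
#' Peaks are clustered across replicates within `mz_tolerance`; clusters
#' observed in at least `replicate_min` replicates are kept with
#' intensity-weighted mean m/z and the mean intensity over contributing
#' replicates; all other peaks are dropped.
#'
#' @param replicate_lists List of peak data frames (`mz`, `intensity`), one
#'   per technical replicate.
#' @param config A [filter_config()].
#' @return A merged peak data frame sorted by m/z.
#' @export
merge_replicates <- function(replicate_lists, config = filter_config()) {
  stopifnot(length(replicate_lists) >= 1L)
  nrows <- vapply(replicate_lists, nrow, integer(1))
  if (all(nrows == 0L)) {
    warning("all replicate peak lists are empty")
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  rep_min <- min(config$replicate_min, length(replicate_lists))
  all <- do.call(rbind, Map(function(df, r) {
    if (nrow(df)) cbind(df[c("mz", "intensity")], .rep = r) else NULL
  }, replicate_lists, seq_along(replicate_lists)))
  cl <- .cluster_mz(all$mz, source = all$.rep, tol_ppm = config$mz_tolerance)
  # distinct replicates contributing to each cluster
  n_rep <- length(replicate_lists)
  pair <- (cl - 1L) * n_rep + all$.rep
  uniq <- !duplicated(pair)
  rep_count <- tabulate(cl[uniq], nbins = max(cl))
  wsum <- rowsum(all$intensity, cl)
  clev <- as.integer(rownames(wsum))
  mz <- rowsum(all$mz * all$intensity, cl) / wsum
  # mean over contributing replicates of the per-replicate summed intensity
  int <- wsum / rep_count[clev]
  keep <- rep_count[clev] >= rep_min
  out <- data.frame(mz = as.numeric(mz)[keep], intensity = as.numeric(int)[keep])
  out[order(out$mz), , drop = FALSE]
}

#' Align per-sample peak lists into a feature matrix
#'
#' Single-linkage clustering of m/z across samples, breaking whenever the gap
#' between adjacent sorted m/z values exceeds the ppm tolerance; each cluster
#' becomes one feature whose per-sample value is the summed intensity of that
#' sample's peaks in the cluster (absent samples are missing).  For LC data
#' (`rt` column present) clusters are additionally split at retention-time
#' gaps larger than `rt_tolerance`.
#'
#' @param sample_lists Named list of peak data frames, one per sample.
#' @param sample_info Data frame with `sample_id`, `role`, `group` matching
#'   `names(sample_lists)`.
#' @param config A [filter_config()].
#' @return A `feature_matrix` object: consensus `mz` (strictly increasing),
#'   intensity matrix (features x samples, `NA` = missing), `samples`, and a
#'   provenance `log`.
#' @export
align_samples <- function(sample_lists, sample_info, config = filter_config()) {
  stopifnot(all(names(sample_lists) == sample_info$sample_id))
  has_rt <- all(vapply(sample_lists, function(x) "rt" %in% names(x), logical(1)))
  all <- do.call(rbind, Map(function(df, s) {
    if (nrow(df)) {
      cols <- c("mz", "intensity", if (has_rt) "rt")
      cbind(df[cols], .sample = s)
    } else NULL
  }, sample_lists, names(sample_lists)))
  cl <- .cluster_mz(all$mz, source = all$.sample, tol_ppm = config$mz_tolerance)
  if (has_rt) {
    # split m/z clusters at retention-time gaps wider than the rt window
    key <- character(nrow(all))
    for (i in split(seq_len(nrow(all)), cl)) {
      o <- i[order(all$rt[i])]
      sub <- cumsum(c(1L, diff(all$rt[o]) > config$rt_tolerance))
      key[o] <- paste(cl[i[1L]], sub, sep = ".")
    }
    cl <- match(key, unique(key))
  }
  wsum <- rowsum(all$intensity, cl)
  clev <- as.integer(rownames(wsum))
  mz_cl <- as.numeric(rowsum(all$mz * all$intensity, cl) / wsum)
  ord <- order(mz_cl)
  n_feat <- length(clev)
  rank <- integer(max(clev))
  rank[clev[ord]] <- seq_len(n_feat)
  feat <- rank[cl]
  n_samp <- nrow(sample_info)
  samp <- match(all$.sample, sample_info$sample_id)
  mat <- matrix(NA_real_, n_feat, n_samp,
                dimnames = list(sprintf("F%05d", seq_len(n_feat)),
                                sample_info$sample_id))
  cell <- rowsum(all$intensity, (feat - 1L) * n_samp + samp)
  key <- as.integer(rownames(cell))
  mat[cbind((key - 1L) %/% n_samp + 1L, (key - 1L) %% n_samp + 1L)] <-
    as.numeric(cell)
  fm <- feature_matrix(
    mz = mz_cl[ord], intensity = mat, samples = sample_info,
    rt = if (has_rt) {
      as.numeric(rowsum(all$rt * all$intensity, cl) / wsum)[ord]
    } else NULL
  )
  fm$log <- sprintf("align_samples: %d features from %d samples (%.3g ppm)",
                    n_feat, nrow(sample_info), config$mz_tolerance)
  fm
}

#' Construct a feature matrix
#'
#' @param mz Consensus m/z per feature (strictly increasing).
#' @param intensity Features x samples intensity matrix (`NA` missing).
#' @param samples Data frame with `sample_id`, `role`, `group`.
#' @param rt Optional consensus retention times.
#' @param log Provenance log (character vector).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(mz, intensity, samples, rt = NULL, log = character(0)) {
  stopifnot(length(mz) == nrow(intensity),
            ncol(intensity) == nrow(samples),
            !is.unsorted(mz, strictly = FALSE))
  structure(list(mz = mz, intensity = intensity, samples = samples, rt = rt,
                 log = log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$intensity), "features x",
      ncol(x$intensity), "samples (",
      sprintf("%.1f%% missing", 100 * mean(is.na(x$intensity))), ")\n")
  cat("  roles:", paste(names(table(x$samples$role)),
                        table(x$samples$role), sep = "=", collapse = ", "), "\n")
  for (l in x$log) cat("  -", l, "\n")
  invisible(x)
}

#' Blank filter
#'
#' A feature is retained iff its mean intensity over biological samples is at
#' least `blank_factor` times its mean over blanks (missing values count as
#' 0 in both means); features absent from every blank are always retained.
#' Blank columns are removed afterwards.
#'
#' @param fm A `feature_matrix` containing blank-role samples.
#' @param config A [filter_config()].
#' @return The filtered `feature_matrix` without blank columns.
#' @export
blank_filter <- function(fm, config = filter_config()) {
  is_blank <- fm$samples$role == "blank"
  if (!any(is_blank)) {
    warning("no blank samples present; blank filter skipped")
    fm$log <- c(fm$log, "blank_filter: skipped (no blanks)")
    return(fm)
  }
  is_bio <- fm$samples$role == "biological"
  zero <- function(m) { m[is.na(m)] <- 0; m }
  bio_mean <- rowMeans(zero(fm$intensity[, is_bio, drop = FALSE]))
  blank_obs <- fm$intensity[, is_blank, drop = FALSE]
  blank_mean <- rowMeans(zero(blank_obs))
  all_absent <- apply(is.na(blank_obs), 1L, all)
  keep <- all_absent | bio_mean >= config$blank_factor * blank_mean
  fm2 <- feature_matrix(
    mz = fm$mz[keep],
    intensity = fm$intensity[keep, !is_blank, drop = FALSE],
    samples = fm$samples[!is_blank, , drop = FALSE],
    rt = fm$rt[keep],
    log = c(fm$log, sprintf("blank_filter: %d -> %d features (factor %g)",
                            length(keep), sum(keep), config$blank_factor))
  )
  fm2
}

#' Sample occupancy filter
#'
#' A feature is retained iff it is observed (non-missing) in at least
#' `sample_fraction` of the biological samples of at least one group
#' (`"group"` mode) or of all biological samples (`"overall"` mode).
#' QC columns are carried through unchanged.
#'
#' @param fm A `feature_matrix`.
#' @param config A [filter_config()].
#' @return The filtered `feature_matrix`.
#' @export
sample_filter <- function(fm, config = filter_config()) {
  is_bio <- fm$samples$role == "biological"
  obs <- !is.na(fm$intensity[, is_bio, drop = FALSE])
  if (config$sample_filter_mode == "overall") {
    keep <- rowMeans(obs) >= config$sample_fraction
  } else {
    groups <- fm$samples$group[is_bio]
    frac <- vapply(unique(groups), function(g) {
      rowMeans(obs[, groups == g, drop = FALSE])
    }, numeric(nrow(obs)))
    keep <- apply(frac >= config$sample_fraction, 1L, any)
  }
  feature_matrix(
    mz = fm$mz[keep],
    intensity = fm$intensity[keep, , drop = FALSE],
    samples = fm$samples,
    rt = fm$rt[keep],
    log = c(fm$log, sprintf(
      "sample_filter: %d -> %d features (>=%g%%, %s mode)",
      length(keep), sum(keep), 100 * config$sample_fraction,
      config$sample_filter_mode))
  )
}

#' Preprocess a study into a filtered feature matrix
#'
#' Runs the full chain: SIM-window stitching per acquisition (DIMS),
#' technical-replicate merging per sample, cross-sample alignment, blank
#' filtering and the sample occupancy filter.
#'
#' @param study A `lipid_study` (or the result of [read_study()]).
#' @param config A [filter_config()].
#' @return A filtered `feature_matrix` (biological + QC columns).
#' @export
preprocess_study <- function(study, config = filter_config()) {
  man <- study$manifest
  merged <- list()
  sample_ids <- unique(man$sample_id)
  for (sid in sample_ids) {
    rows <- man[man$sample_id == sid, , drop = FALSE]
    reps <- sort(unique(rows$replicate))
    rep_lists <- lapply(reps, function(r) {
      rrows <- rows[rows$replicate == r, , drop = FALSE]
      if (study$design$mode == "DIMS" && study$design$n_windows > 1) {
        wl <- lapply(order(rrows$window), function(i) {
          study$peaks[[rrows$acquisition_id[i]]]
        })
        stitch_sim_windows(wl, study$design$windows[rrows$window[order(rrows$window)], ],
                           mz_tolerance = config$mz_tolerance)
      } else {
        study$peaks[[rrows$acquisition_id[1L]]]
      }
    })
    merged[[sid]] <- if (length(rep_lists) > 1L) {
      merge_replicates(rep_lists, config)
    } else {
      rep_lists[[1L]]
    }
  }
  info <- unique(man[, c("sample_id", "role", "group")])
  info <- info[match(sample_ids, info$sample_id), , drop = FALSE]
  rownames(info) <- NULL
  fm <- align_samples(merged, info, config)
  fm <- blank_filter(fm, config)
  sample_filter(fm, config)
}
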